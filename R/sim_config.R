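#' Simulation configuration for a synthetic developmental cohort
#'
#' Bundles every parameter of the synthetic-cohort generator. Age-dependent
#' parameters (`mixing`, `repertoire_size`, `long_range_pref`) are given as
#' length-2 vectors holding the value at the youngest and oldest age of
#' `age_range`; intermediate ages are linearly interpolated, so equal entries
#' mean "no planted effect" for that parameter.
#'
#' @param n_regions number of cortical regions in the parcellation.
#' @param n_systems number of functional systems (at most 7; labels are drawn
#'   from the canonical VIS, SM, DA, VA, LIM, FP, DM set).
#' @param n_frames number of fMRI frames per subject (before the initial-frame
#'   drop applied downstream).
#' @param n_subjects cohort size.
#' @param tr_seconds repetition time of the simulated acquisition, seconds.
#' @param density edge probability of the Erdos-Renyi structural template.
#' @param mixing probability that a propagation step of a planted coactivation
#'   event crosses a functional-system boundary, at `age_range[1]` and
#'   `age_range[2]`.
#' @param repertoire_size size of the per-subject dictionary of recurring
#'   activation patterns at `age_range[1]` and `age_range[2]` (rounded to an
#'   integer per subject; 0 disables pattern reuse entirely). Dictionaries
#'   are nested prefixes of the cohort-level canonical pattern pool of
#'   [make_pattern_pool()], whose size is `max(repertoire_size)`, so smaller
#'   repertoires concentrate on the pool's integrative core.
#' @param long_range_pref probability that a propagation step prefers a long
#'   (> `long_thr_mm`) structural edge, at the two ends of `age_range`.
#' @param reuse_prob ceiling of the pattern-reuse probability. The effective
#'   reuse probability of a subject is
#'   `reuse_prob * (1 - K / (pool_size + 1))` with `K` the subject's
#'   dictionary size: a small consolidated repertoire is exploited
#'   habitually, a large immature one rarely (novel patterns dominate).
#' @param event_rate expected number of planted coactivation events per frame.
#' @param event_mean_len mean number of propagation steps per event (the step
#'   count is geometric).
#' @param amp_z additive amplitude of an event activation, in units of
#'   `noise_sd` (must be >= 3 so events survive the z > 2 threshold).
#' @param long_thr_mm length above which a structural edge counts as "long"
#'   for the propagation preference, mm.
#' @param motion_spike_rate per-frame probability of a motion spike
#'   (FD > 0.4 mm and DVARS > 25 at spike frames).
#' @param noise_sd standard deviation of the baseline Gaussian BOLD noise.
#' @param age_range ages (years) spanned by the cohort; ages are drawn
#'   uniformly on this interval.
#' @param adult_cut age (years) at and above which a subject is labelled
#'   "adults"; below it, "children".
#' @param seed master RNG seed; all per-stage and per-subject seeds are
#'   derived from it deterministically.
#' @param effects if `FALSE`, the three age-dependent parameters are replaced
#'   by their midpoint constants and the pattern dictionary is emptied, giving
#'   a null cohort whose pooled connected components are exchangeable across
#'   groups (used for type-I calibration).
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_regions = 100, n_systems = 7, n_frames = 200,
                       n_subjects = 40, tr_seconds = 2.4, density = 0.06,
                       mixing = c(0.05, 0.70),
                       repertoire_size = c(24, 5),
                       long_range_pref = c(0.05, 0.65),
                       reuse_prob = 0.9, event_rate = 0.2,
                       event_mean_len = 8, amp_z = 4, long_thr_mm = 42,
                       motion_spike_rate = 0.02, noise_sd = 1,
                       age_range = c(6, 33), adult_cut = 18, seed = 1L,
                       effects = TRUE) {
  if (!isTRUE(effects)) {
    mixing <- rep(mean(mixing), 2)
    long_range_pref <- rep(mean(long_range_pref), 2)
    repertoire_size <- c(0, 0)
  }
  cfg <- list(
    n_regions = as.integer(n_regions), n_systems = as.integer(n_systems),
    n_frames = as.integer(n_frames), n_subjects = as.integer(n_subjects),
    tr_seconds = tr_seconds, density = density, mixing = mixing,
    repertoire_size = repertoire_size, long_range_pref = long_range_pref,
    reuse_prob = reuse_prob, event_rate = event_rate,
    event_mean_len = event_mean_len, amp_z = amp_z,
    long_thr_mm = long_thr_mm, motion_spike_rate = motion_spike_rate,
    noise_sd = noise_sd, age_range = age_range, adult_cut = adult_cut,
    seed = as.integer(seed), effects = isTRUE(effects)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_regions >= 1, cfg$n_frames >= 1, cfg$n_subjects >= 1)
  if (cfg$n_systems > cfg$n_regions || cfg$n_systems < 1 || cfg$n_systems > 7)
    stop("invalid configuration: need 1 <= n_systems <= min(n_regions, 7)")
  probs <- c(cfg$density, cfg$mixing, cfg$long_range_pref, cfg$reuse_prob,
             cfg$motion_spike_rate)
  if (any(probs < 0 | probs > 1))
    stop("invalid configuration: all probabilities must lie in [0, 1]")
  if (cfg$density <= 0)
    stop("invalid configuration: density must be in (0, 1]")
  if (any(cfg$repertoire_size < 0))
    stop("invalid configuration: repertoire_size must be >= 0")
  if (cfg$amp_z < 3)
    stop("invalid configuration: amp_z must be >= 3 (threshold survival)")
  if (cfg$noise_sd <= 0)
    stop("invalid configuration: noise_sd must be > 0")
  if (diff(cfg$age_range) <= 0)
    stop("invalid configuration: age_range must be increasing")
  invisible(cfg)
}

# Linear interpolation of an age-dependent parameter over age_range,
# clipped at the range ends.
age_value <- function(pair, age, age_range) {
  w <- (age - age_range[1]) / (age_range[2] - age_range[1])
  w <- min(max(w, 0), 1)
  pair[1] + w * (pair[2] - pair[1])
}

# Deterministic seed derivation so each stage / subject gets an independent,
# reproducible stream. Stays below 2^31 - 1.
derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 1103515245 + 12345 * as.numeric(salt)) %%
               2147483647)
}
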