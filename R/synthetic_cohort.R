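#' @importFrom stats rnorm runif rgeom rpois rexp dist sd cor
NULL

SYSTEM_LABELS <- c("VIS", "SM", "DA", "VA", "LIM", "FP", "DM")

#' Generate a synthetic cortical parcellation
#'
#' Assigns each region to one of the canonical seven functional systems and
#' gives it a 3D centroid. Systems are spatially clustered (regions scattered
#' around a per-system centre), so short structural edges are predominantly
#' intra-system, reproducing the short-range/intra-system confound of real
#' cortex.
#'
#' @param config a [sim_config()].
#' @return a `parcellation`: data.frame with columns `region_id`, `system`,
#'   `x`, `y`, `z`; attribute `systems` holds the system labels in use.
#' @export
make_parcellation <- function(config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, 1))
  n <- config$n_regions
  k <- config$n_systems
  labels <- SYSTEM_LABELS[seq_len(k)]
  # balanced assignment, shuffled: every system non-empty, sizes differ by <= 1
  sys_idx <- sample(rep_len(seq_len(k), n))
  sys_centres <- matrix(runif(3 * k, 0, 60), nrow = k)
  xyz <- sys_centres[sys_idx, , drop = FALSE] +
    matrix(rnorm(3 * n, sd = 8), nrow = n)
  out <- data.frame(
    region_id = seq_len(n),
    system = labels[sys_idx],
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE
  )
  structure(out, systems = labels, class = c("parcellation", "data.frame"))
}

#' Generate a random structural-connectivity template
#'
#' Samples a symmetric adjacency whose edge probability decays exponentially
#' with inter-centroid distance (length scale 30 mm), rescaled so the mean
#' edge probability equals the configured density — the distance dependence
#' of real white-matter connectivity, and the reason short edges are
#' predominantly intra-system given the spatially clustered parcellation.
#' Resamples (up to 100 attempts) until the graph is connected. Edge lengths
#' are Euclidean distances between region centroids, in mm.
#'
#' @param parcellation a [make_parcellation()] result.
#' @param config a [sim_config()].
#' @return a `structural_template`: list with `adjacency` (binary symmetric
#'   matrix, zero diagonal), `length_mm` (matrix, 0 off-edges), `n_regions`.
#' @export
make_structural_template <- function(parcellation, config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, 2))
  n <- nrow(parcellation)
  dmat <- as.matrix(dist(as.matrix(parcellation[, c("x", "y", "z")])))
  up <- upper.tri(dmat)
  decay <- exp(-dmat[up] / 30)
  # ~density * decay/mean(decay) at low density; exactly 1 when density = 1
  p_edge <- 1 - (1 - config$density)^(decay / mean(decay))
  for (attempt in seq_len(100)) {
    adj <- matrix(0L, n, n)
    adj[up] <- as.integer(runif(sum(up)) < p_edge)
    adj <- adj + t(adj)
    if (n == 1 || is_connected_adj(adj)) {
      len <- dmat * (adj == 1)
      dimnames(len) <- NULL
      return(structure(
        list(adjacency = adj, length_mm = len, n_regions = n),
        class = "structural_template"
      ))
    }
  }
  stop("template generation error: density too low to obtain a connected ",
       "graph after 100 attempts")
}

# Connectivity check by BFS over the adjacency matrix.
is_connected_adj <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    nb <- which(adj[v, ] == 1L & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

# Neighbour lookup tables used by the event walks.
neighbour_tables <- function(template, parcellation) {
  n <- template$n_regions
  sys <- parcellation$system
  lapply(seq_len(n), function(r) {
    nb <- which(template$adjacency[r, ] == 1L)
    list(nb = nb,
         len = template$length_mm[r, nb],
         cross = sys[nb] != sys[r])
  })
}

#' Cohort-level pool of canonical coactivation patterns
#'
#' Recurring activation patterns are shared across subjects, mirroring the
#' canonical resting-state coactivation patterns of real cohorts. The pool is
#' ranked: pattern 1 is generated with the parameter values of the oldest age
#' (most integrative, most long-range), the last pattern with those of the
#' youngest. A subject's dictionary is the first `repertoire_size(age)`
#' patterns, so maturation prunes the repertoire toward the integrative core.
#'
#' @param parcellation,template cohort scaffolds.
#' @param config a [sim_config()].
#' @return list of patterns (each as returned by the internal event walk);
#'   empty when `max(repertoire_size)` is 0.
#' @export
make_pattern_pool <- function(parcellation, template, config) {
  pool_size <- as.integer(round(max(config$repertoire_size)))
  if (pool_size == 0L) return(list())
  set.seed(derive_seed(config$seed, 4))
  nbrs <- neighbour_tables(template, parcellation)
  ages <- if (pool_size == 1L) {
    config$age_range[2]
  } else {
    seq(config$age_range[2], config$age_range[1], length.out = pool_size)
  }
  # canonical patterns get a fixed step count (the recurrent assemblies are
  # the large ones); fresh walks keep the geometric length
  lapply(ages, function(a)
    walk_event(nbrs, config$n_regions,
               age_value(config$mixing, a, config$age_range),
               age_value(config$long_range_pref, a, config$age_range),
               config$long_thr_mm, config$event_mean_len,
               n_steps = config$event_mean_len))
}

# One random-walk coactivation event: a sequence of (region, frame-offset)
# cells, consecutive cells joined by a structural edge, frame offset advancing
# by 0 or 1 per step. Returns cells plus the number of cross-system steps.
walk_event <- function(nbrs, n_regions, mixing_p, long_p, long_thr,
                       mean_len, n_steps = NULL) {
  r <- sample.int(n_regions, 1L)
  if (is.null(n_steps))
    n_steps <- rgeom(1L, prob = 1 / max(mean_len, 1))
  cells <- matrix(c(r, 0L), ncol = 2)
  n_cross <- 0L
  dt <- 0L
  for (s in seq_len(n_steps)) {
    info <- nbrs[[r]]
    if (!length(info$nb)) break
    want_cross <- runif(1) < mixing_p
    pool <- if (want_cross && any(info$cross)) {
      which(info$cross)
    } else if (!want_cross && any(!info$cross)) {
      which(!info$cross)
    } else {
      seq_along(info$nb)
    }
    if (runif(1) < long_p) {
      longs <- pool[info$len[pool] > long_thr]
      if (length(longs)) pool <- longs
    } else {
      shorts <- pool[info$len[pool] <= long_thr]
      if (length(shorts)) pool <- shorts
    }
    nxt <- pool[sample.int(length(pool), 1L)]
    if (info$cross[nxt]) n_cross <- n_cross + 1L
    r <- info$nb[nxt]
    dt <- dt + as.integer(runif(1) < 0.5)
    cells <- rbind(cells, c(r, dt))
  }
  list(cells = cells, n_cross = n_cross, n_steps = as.integer(n_steps))
}

#' Simulate one subject: BOLD matrix, motion trace, ground truth
#'
#' The BOLD signal is baseline Gaussian noise plus planted coactivation
#' events. Each event seeds a region at a random frame and propagates for a
#' geometric number of steps along structural edges; a step crosses system
#' boundaries with probability `mixing(age)` and prefers long (> 42 mm) edges
#' with probability `long_range_pref(age)`. With probability `reuse_prob` an
#' event re-uses a pattern from the subject's dictionary (of age-dependent
#' size) instead of taking a fresh walk. Event cells receive an additive
#' amplitude of `amp_z` noise-SD units so they survive the downstream z > 2
#' threshold. Motion spikes (FD > 0.4 mm, DVARS > 25) are inserted at rate
#' `motion_spike_rate`.
#'
#' @param parcellation,template cohort-level scaffolds.
#' @param age subject age in years (>= 0).
#' @param config a [sim_config()].
#' @param seed RNG seed for this subject (default derived from the master
#'   seed).
#' @param pattern_pool cohort-level [make_pattern_pool()] result; generated
#'   from the config when not supplied, so a standalone call sees the same
#'   pool as the cohort.
#' @param events optional list of hand-specified events, each a two-column
#'   matrix of (region, frame) cells; when given, random event generation is
#'   skipped and these cells are planted verbatim.
#' @return list with `bold` (regions x frames matrix), `motion` (data.frame
#'   `frame`, `fd`, `dvars`), `record` (age, seed), and `ground_truth` (list
#'   of events, each with `cells`, `n_cross`, `n_steps`, `reused`).
#' @export
simulate_subject <- function(parcellation, template, age, config,
                             seed = derive_seed(config$seed, 1000 + round(age * 100)),
                             pattern_pool = NULL, events = NULL) {
  validate_sim_config(config)
  if (age < 0) stop("age must be >= 0")
  if (config$n_frames < 5)
    stop("n_frames must be >= 5 (the initial four-frame drop would empty ",
         "the series)")
  if (is.null(pattern_pool))
    pattern_pool <- make_pattern_pool(parcellation, template, config)
  set.seed(seed)
  n <- config$n_regions
  tt <- config$n_frames
  bold <- matrix(rnorm(n * tt, 0, config$noise_sd), n, tt)

  mixing_p <- age_value(config$mixing, age, config$age_range)
  long_p <- age_value(config$long_range_pref, age, config$age_range)
  rep_k <- as.integer(round(age_value(config$repertoire_size, age,
                                      config$age_range)))
  nbrs <- neighbour_tables(template, parcellation)

  ground_truth <- list()
  if (is.null(events)) {
    dict <- pattern_pool[seq_len(min(rep_k, length(pattern_pool)))]
    # reuse probability is tied to repertoire consolidation: a small, mature
    # dictionary is exploited habitually, a large immature one rarely
    reuse_eff <- if (length(dict)) {
      config$reuse_prob * (1 - length(dict) / (length(pattern_pool) + 1))
    } else {
      0
    }
    n_events <- rpois(1L, config$event_rate * tt)
    for (e in seq_len(n_events)) {
      reused <- length(dict) > 0 && runif(1) < reuse_eff
      ev <- if (reused) {
        dict[[sample.int(length(dict), 1L)]]
      } else {
        walk_event(nbrs, n, mixing_p, long_p, config$long_thr_mm,
                   config$event_mean_len)
      }
      t0 <- sample.int(tt, 1L)
      cells <- cbind(ev$cells[, 1], t0 + ev$cells[, 2])
      cells <- cells[cells[, 2] >= 1 & cells[, 2] <= tt, , drop = FALSE]
      if (!nrow(cells)) next
      ground_truth[[length(ground_truth) + 1L]] <-
        list(cells = cells, n_cross = ev$n_cross, n_steps = ev$n_steps,
             reused = reused)
    }
  } else {
    ground_truth <- lapply(events, function(cells)
      list(cells = as.matrix(cells), n_cross = NA_integer_,
           n_steps = nrow(cells) - 1L, reused = FALSE))
  }
  for (ev in ground_truth) {
    cells <- unique(ev$cells)
    bold[cells] <- bold[cells] + config$amp_z * config$noise_sd
  }

  spikes <- runif(tt) < config$motion_spike_rate
  fd <- pmin(abs(rnorm(tt, 0.08, 0.05)), 0.35)
  fd[1] <- 0
  dvars <- pmin(abs(rnorm(tt, 10, 3)), 24)
  fd[spikes] <- 0.45 + rexp(sum(spikes), rate = 4)
  dvars[spikes] <- 27 + rexp(sum(spikes), rate = 0.5)

  list(
    bold = bold,
    motion = data.frame(frame = seq_len(tt), fd = fd, dvars = dvars),
    record = list(age = age, seed = seed),
    ground_truth = ground_truth
  )
}

#' Simulate a full developmental cohort
#'
#' Ages are drawn uniformly on `config$age_range`; subjects below
#' `config$adult_cut` are labelled "children", the rest "adults". Per-subject
#' seeds are derived deterministically from the master seed, so the whole
#' cohort is reproducible bit-for-bit.
#'
#' @param config a [sim_config()].
#' @return a `synthetic_cohort`: list with `config`, `parcellation`,
#'   `template`, `subjects` (named list of [simulate_subject()] results) and
#'   `participants` (data.frame `subject_id`, `age`, `group`).
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  if (config$n_subjects < 2) stop("n_subjects must be >= 2")
  parcellation <- make_parcellation(config)
  template <- make_structural_template(parcellation, config)
  pool <- make_pattern_pool(parcellation, template, config)
  set.seed(derive_seed(config$seed, 3))
  ages <- runif(config$n_subjects, config$age_range[1], config$age_range[2])
  sub_seeds <- sample.int(2147483646L, config$n_subjects)
  ids <- sprintf("sub-%03d", seq_len(config$n_subjects))
  subjects <- vector("list", config$n_subjects)
  names(subjects) <- ids
  for (i in seq_len(config$n_subjects)) {
    subjects[[i]] <- simulate_subject(parcellation, template, ages[i],
                                      config, seed = sub_seeds[i],
                                      pattern_pool = pool)
  }
  participants <- data.frame(
    subject_id = ids,
    age = ages,
    group = ifelse(ages < config$adult_cut, "children", "adults"),
    stringsAsFactors = FALSE
  )
  structure(
    list(config = config, parcellation = parcellation, template = template,
         subjects = subjects, participants = participants),
    class = "synthetic_cohort"
  )
}
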