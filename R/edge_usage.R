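#' Consensus structural template over subjects
#'
#' Keeps an edge when it is present in at least `min_fraction` of the
#' subjects (inclusive at the boundary); its length is the mean length over
#' the subjects possessing it (median by flag).
#'
#' @param adjacencies list of binary adjacency matrices, one per subject.
#' @param lengths list of matching length matrices, mm.
#' @param min_fraction consensus threshold (default 0.5).
#' @param length_stat `"mean"` (default) or `"median"`.
#' @return a `structural_template`.
#' @export
consensus_template <- function(adjacencies, lengths, min_fraction = 0.5,
                               length_stat = c("mean", "median")) {
  length_stat <- match.arg(length_stat)
  if (!length(adjacencies)) stop("need at least one subject")
  dims <- vapply(adjacencies, function(a) dim(as.matrix(a)), integer(2))
  if (length(unique(c(dims))) != 1)
    stop("dimension mismatch across subject adjacencies")
  n <- dims[1, 1]
  count <- Reduce(`+`, lapply(adjacencies, function(a) as.matrix(a) != 0))
  keep <- (count / length(adjacencies)) >= min_fraction & count > 0
  len <- matrix(0, n, n)
  if (any(keep)) {
    stacked <- vapply(seq_along(adjacencies), function(i) {
      a <- as.matrix(adjacencies[[i]]) != 0
      l <- as.matrix(lengths[[i]])
      l[!a] <- NA_real_
      l
    }, matrix(0, n, n))
    agg <- apply(stacked, c(1, 2), function(v)
      if (all(is.na(v))) 0 else if (length_stat == "mean") {
        mean(v, na.rm = TRUE)
      } else {
        stats::median(v, na.rm = TRUE)
      })
    len[keep] <- agg[keep]
  }
  structure(list(adjacency = matrix(as.integer(keep), n, n),
                 length_mm = len, n_regions = n),
            class = "structural_template")
}

#' Classify multilayer edge instances by length and system membership
#'
#' Labels every inter-regional edge instance of the given components:
#' `short` if its template length is strictly below `short_thr`, `long` if
#' strictly above `long_thr`, `mid` otherwise; `intra` when both endpoint
#' regions share a functional-system label, `inter` otherwise. Same-region
#' temporal continuity edges carry no physical length and are excluded.
#'
#' @param ccs list of components (their `edges` tables are pooled), or a
#'   single edge data.frame with columns `r1`, `r2`, `type`.
#' @param template the structural template supplying edge lengths.
#' @param parcellation parcellation data.frame with system labels.
#' @param short_thr,long_thr length thresholds, mm (defaults 20 and 42).
#' @return data.frame of edge instances with `r1`, `r2`, `type`,
#'   `length_mm`, `length_class`, `system_class`.
#' @export
classify_edges <- function(ccs, template, parcellation, short_thr = 20,
                           long_thr = 42) {
  if (short_thr <= 0 || short_thr > long_thr)
    stop("need 0 < short_thr <= long_thr")
  edges <- if (is.data.frame(ccs)) {
    ccs
  } else {
    do.call(rbind, c(lapply(ccs, function(cc) cc$edges),
                     make.row.names = FALSE))
  }
  if (is.null(edges) || !nrow(edges))
    return(data.frame(r1 = integer(), r2 = integer(), type = character(),
                      length_mm = numeric(), length_class = character(),
                      system_class = character()))
  edges <- edges[edges$type != "self", , drop = FALSE]
  if (!nrow(edges)) {
    return(data.frame(r1 = integer(), r2 = integer(), type = character(),
                      length_mm = numeric(), length_class = character(),
                      system_class = character()))
  }
  if (any(template$adjacency[cbind(edges$r1, edges$r2)] != 1L))
    stop("internal consistency error: edge not present in the template")
  len <- template$length_mm[cbind(edges$r1, edges$r2)]
  out <- data.frame(
    r1 = edges$r1, r2 = edges$r2, type = edges$type, length_mm = len,
    length_class = ifelse(len < short_thr, "short",
                          ifelse(len > long_thr, "long", "mid")),
    system_class = ifelse(parcellation$system[edges$r1] ==
                            parcellation$system[edges$r2], "intra", "inter"),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Per-subject relative edge usage
#'
#' Counts every classified edge instance across the subject's kept
#' components and reports relative usage: fractions of short / mid / long
#' and intra / inter edges (each family sums to 1).
#'
#' @param classified a [classify_edges()] result for one subject.
#' @param subject_id subject label.
#' @param age subject age, years.
#' @param mean_fd subject mean framewise displacement, mm.
#' @return one-row data.frame: counts, fractions, `age`, `mean_fd`.
#' @export
subject_usage <- function(classified, subject_id = NA_character_,
                          age = NA_real_, mean_fd = NA_real_) {
  n <- nrow(classified)
  if (!n) stop("subject has no counted edges; exclude from trend fits")
  data.frame(
    subject_id = subject_id, n_edges_total = n,
    n_short = sum(classified$length_class == "short"),
    n_mid = sum(classified$length_class == "mid"),
    n_long = sum(classified$length_class == "long"),
    n_inter = sum(classified$system_class == "inter"),
    frac_short = mean(classified$length_class == "short"),
    frac_mid = mean(classified$length_class == "mid"),
    frac_long = mean(classified$length_class == "long"),
    frac_intra = mean(classified$system_class == "intra"),
    frac_inter = mean(classified$system_class == "inter"),
    age = age, mean_fd = mean_fd, stringsAsFactors = FALSE
  )
}

# Textbook first-order partial correlation of x and y controlling z,
# with a t-distribution p-value on n - 3 degrees of freedom.
partial_cor <- function(x, y, z) {
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  pr <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  n <- length(x)
  tval <- pr * sqrt((n - 3) / (1 - pr^2))
  list(r = pr, p = 2 * stats::pt(-abs(tval), df = n - 3))
}

#' Age trend of relative edge usage
#'
#' Pearson correlation of a usage fraction with age (two-sided t-test p),
#' the partial correlation controlling mean framewise displacement, and —
#' when per-subject instance tables are supplied — a threshold sweep
#' recomputing r and p at the relevant length threshold shifted by
#' -sweep_halfwidth .. +sweep_halfwidth mm.
#'
#' @param summaries data.frame of [subject_usage()] rows with `age` and
#'   `mean_fd`.
#' @param outcome `"frac_short"`, `"frac_long"`, or `"frac_inter"`.
#' @param instances optional named list of per-subject [classify_edges()]
#'   tables (same order as `summaries`), enabling the sweep.
#' @param short_thr,long_thr the central thresholds, mm.
#' @param sweep_halfwidth sweep half-width, mm (default 5).
#' @return an `age_trend_result`: list with `outcome`, `r`, `p`,
#'   `n_subjects`, `partial_r`, `partial_p`, `sweep` (data.frame or NULL).
#' @export
age_trend <- function(summaries, outcome = c("frac_long", "frac_short",
                                             "frac_inter"),
                      instances = NULL, short_thr = 20, long_thr = 42,
                      sweep_halfwidth = 5) {
  outcome <- match.arg(outcome)
  if (nrow(summaries) < 3) stop("need at least 3 subjects")
  y <- summaries[[outcome]]
  age <- summaries$age
  if (sd(y) == 0) {
    return(structure(list(outcome = outcome, r = NA_real_, p = NA_real_,
                          n_subjects = nrow(summaries),
                          partial_r = NA_real_, partial_p = NA_real_,
                          sweep = NULL, note = "constant outcome"),
                     class = "age_trend_result"))
  }
  ct <- stats::cor.test(y, age)
  pc <- if (all(is.finite(summaries$mean_fd))) {
    partial_cor(y, age, summaries$mean_fd)
  } else {
    list(r = NA_real_, p = NA_real_)
  }
  sweep <- NULL
  if (!is.null(instances) && outcome != "frac_inter") {
    central <- if (outcome == "frac_long") long_thr else short_thr
    rows <- lapply(seq(-sweep_halfwidth, sweep_halfwidth), function(delta) {
      thr <- central + delta
      fr <- vapply(instances, function(tab) {
        if (outcome == "frac_long") mean(tab$length_mm > thr)
        else mean(tab$length_mm < thr)
      }, numeric(1))
      if (sd(fr) == 0)
        return(data.frame(threshold = thr, r = NA_real_, p = NA_real_))
      cs <- stats::cor.test(fr, age)
      data.frame(threshold = thr, r = unname(cs$estimate), p = cs$p.value)
    })
    sweep <- do.call(rbind, rows)
  }
  structure(
    list(outcome = outcome, r = unname(ct$estimate), p = ct$p.value,
         n_subjects = nrow(summaries), partial_r = pc$r, partial_p = pc$p,
         sweep = sweep),
    class = "age_trend_result"
  )
}
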