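# Independent oracles and small fixture builders. Everything here is written
# from first principles (definitions, brute force, closed forms) and never
# calls the package code paths it is used to check.

# --- brute-force BFS over the multilayer definition ------------------------
# Returns the partition of active (region, frame) cells into weakly
# connected components, as a canonical sorted list of "r:t" key vectors.
bfs_cc_oracle <- function(active, adj, temporal_self = TRUE,
                          min_nodes = 2L) {
  cells <- which(active == 1, arr.ind = TRUE)
  m <- nrow(cells)
  if (m == 0) return(list())
  linked <- function(i, j) {
    r1 <- cells[i, 1]; t1 <- cells[i, 2]
    r2 <- cells[j, 1]; t2 <- cells[j, 2]
    dt <- abs(t1 - t2)
    if (dt > 1) return(FALSE)
    if (r1 == r2) return(temporal_self && dt == 1)
    if (adj[r1, r2] != 1) return(FALSE)
    dt <= 1
  }
  comp <- rep(NA_integer_, m)
  next_id <- 0L
  for (s in seq_len(m)) {
    if (!is.na(comp[s])) next
    next_id <- next_id + 1L
    queue <- s
    comp[s] <- next_id
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      for (w in seq_len(m)) {
        if (is.na(comp[w]) && linked(v, w)) {
          comp[w] <- next_id
          queue <- c(queue, w)
        }
      }
    }
  }
  keys <- paste(cells[, 1], cells[, 2], sep = ":")
  parts <- split(keys, comp)
  parts <- Filter(function(p) length(p) >= min_nodes, parts)
  parts <- lapply(parts, sort)
  unname(parts[order(vapply(parts, `[`, character(1), 1))])
}

# Canonical form of the package's component list for comparison.
ccs_to_partition <- function(ccs) {
  parts <- lapply(ccs, function(cc)
    sort(paste(cc$nodes$region, cc$nodes$frame, sep = ":")))
  unname(parts[order(vapply(parts, `[`, character(1), 1))])
}

# --- naive double-loop cosine similarity -----------------------------------
naive_cosine_matrix <- function(vecs) {
  k <- nrow(vecs)
  s <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      s[i, j] <- sum(vecs[i, ] * vecs[j, ]) /
        (sqrt(sum(vecs[i, ]^2)) * sqrt(sum(vecs[j, ]^2)))
    }
  }
  s
}

naive_mean_pair_sim <- function(vecs, idx) {
  tot <- 0
  npair <- 0
  for (i in idx) {
    for (j in idx) {
      if (j > i) {
        tot <- tot + sum(vecs[i, ] * vecs[j, ]) /
          (sqrt(sum(vecs[i, ]^2)) * sqrt(sum(vecs[j, ]^2)))
        npair <- npair + 1
      }
    }
  }
  tot / npair
}

# --- exhaustive permutation test for a mean difference ---------------------
exhaustive_perm_p <- function(values, is_a, tails = "two") {
  k <- length(values)
  n_a <- sum(is_a)
  obs <- mean(values[is_a]) - mean(values[!is_a])
  combs <- utils::combn(k, n_a)
  diffs <- apply(combs, 2, function(ix)
    mean(values[ix]) - mean(values[-ix]))
  extreme <- switch(tails,
    two = abs(diffs) >= abs(obs) - 1e-12,
    one_greater = diffs >= obs - 1e-12,
    one_less = diffs <= obs + 1e-12)
  mean(extreme)
}

# --- hand Benjamini-Hochberg step-up ---------------------------------------
hand_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  running_min <- Inf
  for (i in rev(seq_len(m))) {
    val <- p[ord[i]] * m / i
    running_min <- min(running_min, val, 1)
    q[ord[i]] <- running_min
  }
  q
}

# --- partial correlation by explicit residualization -----------------------
partial_cor_oracle <- function(x, y, z) {
  rx <- stats::residuals(stats::lm(x ~ z))
  ry <- stats::residuals(stats::lm(y ~ z))
  stats::cor(rx, ry)
}

# --- fixture builders ------------------------------------------------------
# Hand-built connected_component object (bypasses graph extraction).
make_cc <- function(regions, frames, cc_id = 1L) {
  nd <- data.frame(region = as.integer(regions), frame = as.integer(frames))
  ord <- order(nd$frame, nd$region)
  nd <- nd[ord, , drop = FALSE]
  rownames(nd) <- NULL
  structure(
    list(cc_id = as.integer(cc_id), nodes = nd,
         frame_span = c(min(nd$frame), max(nd$frame)),
         n_unique_regions = length(unique(nd$region)),
         edges = data.frame(r1 = integer(), t1 = integer(),
                            r2 = integer(), t2 = integer(),
                            type = character())),
    class = "connected_component"
  )
}

# Minimal parcellation with explicit system labels.
make_parc <- function(systems) {
  n <- length(systems)
  out <- data.frame(region_id = seq_len(n), system = systems,
                    x = seq_len(n), y = 0, z = 0, stringsAsFactors = FALSE)
  attr(out, "systems") <- unique(systems)
  class(out) <- c("parcellation", "data.frame")
  out
}

# Template from an explicit symmetric adjacency (+ optional lengths).
make_template <- function(adj, len = NULL) {
  adj <- as.matrix(adj)
  if (is.null(len)) len <- adj * 10
  structure(list(adjacency = adj, length_mm = len, n_regions = nrow(adj)),
            class = "structural_template")
}

# Point process object from an explicit binary matrix.
make_pp <- function(active, retained = seq_len(ncol(active))) {
  structure(list(active = active, z_threshold = 2, tail = "positive",
                 retained_frame_index = retained),
            class = "point_process")
}

# Random small multilayer instance for oracle comparisons.
random_instance <- function(seed) {
  set.seed(seed)
  n <- sample(3:12, 1)
  tt <- sample(2:10, 1)
  adj <- matrix(0L, n, n)
  up <- upper.tri(adj)
  adj[up] <- as.integer(runif(sum(up)) < runif(1, 0.1, 0.5))
  adj <- adj + t(adj)
  active <- matrix(as.integer(runif(n * tt) < runif(1, 0.1, 0.5)), n, tt)
  list(adj = adj, active = active)
}

# Light cohort -> pooled grouped CCs (shared by several test files).
pool_cohort_ccs <- function(cohort, params = pipeline_params()) {
  all_ccs <- list()
  grp <- character()
  subj <- character()
  for (id in names(cohort$subjects)) {
    sub <- cohort$subjects[[id]]
    pp <- to_point_process(drop_initial_frames(sub$bold, params$n_drop),
                           params$z_threshold)
    ccs <- extract_components(build_multilayer(pp, cohort$template),
                              params$min_nodes)
    tr <- flag_frames(sub$motion, params$fd_thr, params$dvars_thr)
    scr <- scrub_components(ccs, map_flags(tr, pp$retained_frame_index))
    all_ccs <- c(all_ccs, scr$kept)
    g <- cohort$participants$group[cohort$participants$subject_id == id]
    grp <- c(grp, rep(g, length(scr$kept)))
    subj <- c(subj, rep(id, length(scr$kept)))
  }
  list(ccs = all_ccs, group = grp, subject = subj)
}
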