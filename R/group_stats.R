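#' Pool connected components across subjects with group labels
#'
#' Caches the per-component System Diversity values and the pairwise
#' cosine-similarity matrix once, so that group statistics and all
#' permutations are computed by indexing — no re-embedding.
#'
#' @param ccs list of components pooled over subjects.
#' @param group character/factor vector, one group label per component.
#' @param parcellation parcellation data.frame.
#' @return a `grouped_ccs`: list with `ccs`, `group` (factor), `sd_values`,
#'   `similarity`, `parcellation`.
#' @export
grouped_ccs <- function(ccs, group, parcellation) {
  if (length(ccs) != length(group))
    stop("one group label per component required")
  group <- as.factor(group)
  if (nlevels(group) != 2)
    stop("exactly two groups required; got levels: ",
         paste(levels(group), collapse = ", "))
  structure(
    list(ccs = ccs, group = group,
         sd_values = vapply(ccs, system_diversity, numeric(1),
                            parcellation = parcellation),
         similarity = pairwise_similarity(ccs, nrow(parcellation)),
         parcellation = parcellation),
    class = "grouped_ccs"
  )
}

# Mean pairwise similarity within each of two index sets given the cached
# similarity matrix; NA when a set has < 2 members.
within_group_sim <- function(s, idx_a, idx_b) {
  one <- function(ix) {
    k <- length(ix)
    if (k < 2) return(NA_real_)
    (sum(s[ix, ix]) - k) / (k * (k - 1))
  }
  c(one(idx_a), one(idx_b))
}

#' Per-group SD or STD statistic
#'
#' SD: unweighted mean of the per-component System Diversity over the
#' group's selected components. STD: the pairwise within-group quantity
#' [std_over_set()] on the group's selected indices (not a mean of
#' per-component values).
#'
#' @param grouped a [grouped_ccs()].
#' @param measure `"SD"` or `"STD"`.
#' @param selector integer indices of the components considered (default:
#'   all, the global scale); see [select_ccs()].
#' @param std_convention `"div"` (default, higher = more heterogeneous) or
#'   `"sim"` for STD.
#' @return named numeric vector, one value per group level.
#' @export
group_statistic <- function(grouped, measure = c("SD", "STD"),
                            selector = seq_along(grouped$ccs),
                            std_convention = c("div", "sim")) {
  measure <- match.arg(measure)
  std_convention <- match.arg(std_convention)
  lv <- levels(grouped$group)
  idx <- lapply(lv, function(g) selector[grouped$group[selector] == g])
  if (any(vapply(idx, length, integer(1)) == 0))
    stop("empty selection for group ",
         lv[which(vapply(idx, length, integer(1)) == 0)[1]],
         " under the given selector")
  vals <- if (measure == "SD") {
    vapply(idx, function(ix) mean(grouped$sd_values[ix]), numeric(1))
  } else {
    sims <- within_group_sim(grouped$similarity, idx[[1]], idx[[2]])
    if (std_convention == "div") 1 - sims else sims
  }
  names(vals) <- lv
  vals
}

#' CC-reassignment permutation test for a group difference
#'
#' The observed difference (first group level minus second) in the group SD
#' or STD statistic is compared against a null distribution obtained by
#' shuffling group labels over the pooled selected components, preserving
#' group sizes. STD permutations are evaluated by submatrix averaging of the
#' cached similarity matrix. The p-value uses the +1-corrected estimator
#' p = (1 + #extreme) / (1 + n_perm), so it is never zero. When
#' `exact = TRUE` (or `exact = NULL` and the number of distinct
#' reassignments is at most `exact_limit`), all reassignments are enumerated
#' instead and p is the exact fraction of as-or-more-extreme assignments
#' (the identity included).
#'
#' @param grouped a [grouped_ccs()].
#' @param measure `"SD"` or `"STD"`.
#' @param selector component indices considered (default all).
#' @param n_perm number of random permutations (default 1000).
#' @param tails `"two"`, `"one_greater"` (alternative: diff > 0), or
#'   `"one_less"`.
#' @param seed RNG seed for the permutations.
#' @param std_convention STD direction convention, `"div"` default.
#' @param exact force (or with `NULL`, allow) exhaustive enumeration.
#' @param exact_limit maximum number of enumerated reassignments for the
#'   automatic exact mode.
#' @return a `permutation_result`: list with `observed` (per-group values),
#'   `observed_diff`, `null_diffs`, `p_value`, `tails`, `n_perm`, `seed`,
#'   `measure`, `exact`.
#' @export
permutation_test <- function(grouped, measure = c("SD", "STD"),
                             selector = seq_along(grouped$ccs),
                             n_perm = 1000L,
                             tails = c("two", "one_greater", "one_less"),
                             seed = 1L,
                             std_convention = c("div", "sim"),
                             exact = FALSE, exact_limit = 10000) {
  measure <- match.arg(measure)
  tails <- match.arg(tails)
  std_convention <- match.arg(std_convention)
  lv <- levels(grouped$group)
  sel_group <- grouped$group[selector]
  n_a <- sum(sel_group == lv[1])
  n_b <- sum(sel_group == lv[2])
  if (n_a == 0 || n_b == 0)
    stop("both groups must be non-empty after selection")
  if ((measure == "STD") && (n_a < 2 || n_b < 2))
    stop("STD requires at least 2 components per group")

  observed <- group_statistic(grouped, measure, selector, std_convention)
  obs_diff <- unname(observed[1] - observed[2])

  k <- length(selector)
  diff_for <- function(a_mask) {
    ia <- selector[a_mask]
    ib <- selector[!a_mask]
    if (measure == "SD") {
      mean(grouped$sd_values[ia]) - mean(grouped$sd_values[ib])
    } else {
      sims <- within_group_sim(grouped$similarity, ia, ib)
      if (std_convention == "div") sims <- 1 - sims
      sims[1] - sims[2]
    }
  }

  if (is.null(exact)) exact <- choose(k, n_a) <= exact_limit
  if (exact) {
    if (choose(k, n_a) > exact_limit)
      stop("exact enumeration over ", choose(k, n_a),
           " reassignments exceeds exact_limit")
    combs <- utils::combn(k, n_a)
    null_diffs <- apply(combs, 2, function(ix) {
      mask <- logical(k)
      mask[ix] <- TRUE
      diff_for(mask)
    })
    extreme <- switch(tails,
      two = abs(null_diffs) >= abs(obs_diff) - 1e-12,
      one_greater = null_diffs >= obs_diff - 1e-12,
      one_less = null_diffs <= obs_diff + 1e-12)
    p <- mean(extreme)  # identity assignment is among the enumerated ones
    n_used <- ncol(combs)
  } else {
    set.seed(seed)
    if (measure == "SD") {
      v <- grouped$sd_values[selector]
      null_diffs <- vapply(seq_len(n_perm), function(i) {
        ia <- sample.int(k, n_a)
        mean(v[ia]) - mean(v[-ia])
      }, numeric(1))
    } else {
      s <- grouped$similarity[selector, selector, drop = FALSE]
      z <- matrix(0, k, n_perm)
      for (i in seq_len(n_perm)) z[sample.int(k, n_a), i] <- 1
      sz <- s %*% z
      qa <- colSums(z * sz)
      qb <- colSums((1 - z) * sz)            # cross terms
      tot <- sum(s)
      qb <- tot - 2 * qb - qa                # sum over B x B block
      sim_a <- (qa - n_a) / (n_a * (n_a - 1))
      sim_b <- (qb - n_b) / (n_b * (n_b - 1))
      null_diffs <- if (std_convention == "div") {
        (1 - sim_a) - (1 - sim_b)
      } else {
        sim_a - sim_b
      }
    }
    extreme <- switch(tails,
      two = abs(null_diffs) >= abs(obs_diff) - 1e-12,
      one_greater = null_diffs >= obs_diff - 1e-12,
      one_less = null_diffs <= obs_diff + 1e-12)
    p <- (1 + sum(extreme)) / (1 + n_perm)
    n_used <- n_perm
  }
  structure(
    list(observed = observed, observed_diff = obs_diff,
         null_diffs = null_diffs, p_value = p, tails = tails,
         n_perm = n_used, seed = seed, measure = measure, exact = exact),
    class = "permutation_result"
  )
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up q-values over a vector of p-values (one per functional system per
#' measure in the system-scale analysis).
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return q-values, same length and order.
#' @export
fdr_correct <- function(p_values) {
  if (any(p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Nodal SD and STD maps per group
#'
#' For each region and group: the mean per-component SD over that group's
#' components containing the region, and the within-set STD over the same
#' components. Regions touched by fewer than 2 components are marked
#' undefined (`defined = FALSE`, values `NA`).
#'
#' @param grouped a [grouped_ccs()].
#' @param std_convention STD direction convention.
#' @return a `nodal_maps` data.frame: `region`, `group`, `n_cc`, `sd`,
#'   `std`, `defined`.
#' @export
nodal_maps <- function(grouped, std_convention = c("div", "sim")) {
  std_convention <- match.arg(std_convention)
  n <- nrow(grouped$parcellation)
  lv <- levels(grouped$group)
  region_sets <- lapply(grouped$ccs, function(cc) unique(cc$nodes$region))
  cc_by_region <- vector("list", n)
  for (i in seq_along(region_sets))
    for (r in region_sets[[i]])
      cc_by_region[[r]] <- c(cc_by_region[[r]], i)
  rows <- list()
  for (g in lv) {
    in_g <- which(grouped$group == g)
    for (r in seq_len(n)) {
      ix <- intersect(cc_by_region[[r]], in_g)
      k <- length(ix)
      if (k >= 2) {
        sim <- within_group_sim(grouped$similarity, ix, ix)[1]
        rows[[length(rows) + 1L]] <- data.frame(
          region = r, group = g, n_cc = k,
          sd = mean(grouped$sd_values[ix]),
          std = if (std_convention == "div") 1 - sim else sim,
          defined = TRUE, stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          region = r, group = g, n_cc = k, sd = NA_real_, std = NA_real_,
          defined = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("nodal_maps", "data.frame")
  out
}

#' Cross-group agreement of nodal maps
#'
#' Pearson correlation of a nodal measure between two groups over the
#' jointly defined regions.
#'
#' @param maps a [nodal_maps()] result.
#' @param measure `"sd"` or `"std"`.
#' @param groups the two group labels to compare (default: the two levels).
#' @return list with `r`, `n_regions`, and the scatter `data` (region and the
#'   two values).
#' @export
map_agreement <- function(maps, measure = c("std", "sd"), groups = NULL) {
  measure <- match.arg(measure)
  if (is.null(groups)) groups <- unique(maps$group)
  a <- maps[maps$group == groups[1] & maps$defined, c("region", measure)]
  b <- maps[maps$group == groups[2] & maps$defined, c("region", measure)]
  joint <- merge(a, b, by = "region", suffixes = c("_a", "_b"))
  if (nrow(joint) < 3)
    stop("fewer than 3 jointly defined regions")
  list(r = cor(joint[[2]], joint[[3]]), n_regions = nrow(joint),
       data = joint)
}
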