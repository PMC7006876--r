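#' Spatial activation vector of a connected component
#'
#' Entry i counts the frames within the component at which region i is
#' active; the vector is also returned normalized to unit l2-norm, the
#' embedding used by all cosine-similarity computations.
#'
#' @param cc a `connected_component`.
#' @param n_regions total number of regions in the parcellation.
#' @return list with `x` (integer counts, length `n_regions`) and `x_norm`
#'   (unit-length numeric vector).
#' @export
activation_vector <- function(cc, n_regions) {
  if (!nrow(cc$nodes)) stop("empty connected component")
  x <- tabulate(cc$nodes$region, nbins = n_regions)
  list(x = x, x_norm = x / sqrt(sum(x^2)))
}

#' System Diversity of a connected component
#'
#' Entropy of the distribution of the component's unique regions over the
#' functional systems: with p_f the number of unique regions labelled system
#' f and P_f = p_f / sum(p), SD = -sum(P_f log P_f). Zero when all regions
#' belong to one system; log(FS) when the FS systems are recruited equally.
#' Frame durations do not enter — only unique regions count.
#'
#' @param cc a `connected_component`.
#' @param parcellation a parcellation data.frame with `system` per region.
#' @param base logarithm base (default `exp(1)`: nats).
#' @return SD value (non-negative scalar).
#' @export
system_diversity <- function(cc, parcellation, base = exp(1)) {
  regions <- unique(cc$nodes$region)
  if (!length(regions)) stop("empty connected component")
  p <- table(parcellation$system[regions])
  pr <- p / sum(p)
  pr <- pr[pr > 0]
  -sum(pr * log(pr)) / log(base)
}

#' Pairwise cosine-similarity matrix of component activation maps
#'
#' Computed once from the l2-normalized activation vectors and reused by
#' every scale and every permutation (similarities are in [0, 1] because the
#' vectors are non-negative).
#'
#' @param ccs list of components, or a K x N matrix whose rows are already
#'   unit-normalized activation vectors.
#' @param n_regions number of regions (required when `ccs` is a list).
#' @return K x K symmetric similarity matrix with unit diagonal.
#' @export
pairwise_similarity <- function(ccs, n_regions = NULL) {
  xn <- if (is.matrix(ccs)) {
    ccs
  } else {
    if (is.null(n_regions)) stop("n_regions required when ccs is a list")
    t(vapply(ccs, function(cc) activation_vector(cc, n_regions)$x_norm,
             numeric(n_regions)))
  }
  s <- tcrossprod(xn)
  s[s < 0] <- 0
  s[s > 1] <- 1
  diag(s) <- 1
  s
}

#' Spatiotemporal Diversity over a set of components
#'
#' The mean cosine similarity over unordered distinct pairs of the selected
#' components (`convention = "sim"`), or its complement 1 - mean
#' (`convention = "div"`), in which higher values mean a more heterogeneous
#' pattern repertoire. Returns `NA` (with a warning) for fewer than two
#' components.
#'
#' @param s a [pairwise_similarity()] matrix.
#' @param index_set integer indices of the components considered.
#' @param convention `"sim"` (mean similarity, default) or `"div"`
#'   (1 - mean similarity).
#' @return scalar in [0, 1], or `NA_real_` when undefined.
#' @export
std_over_set <- function(s, index_set, convention = c("sim", "div")) {
  convention <- match.arg(convention)
  k <- length(index_set)
  if (k < 2) {
    warning("STD undefined for fewer than 2 components")
    return(NA_real_)
  }
  m <- (sum(s[index_set, index_set]) - k) / (k * (k - 1))
  if (convention == "div") 1 - m else m
}

#' Select components for an investigation scale
#'
#' Global scale: all components. Functional-system scale: components for
#' which at least `threshold` (default 20%, inclusive) of the unique active
#' regions belong to the target system — a component may qualify for several
#' systems. Nodal scale: components whose cells include the target region at
#' any frame.
#'
#' @param ccs list of components.
#' @param parcellation parcellation data.frame.
#' @param scale `"global"`, `"system"`, or `"nodal"`.
#' @param target system label (for `"system"`) or region id (for `"nodal"`).
#' @param threshold system-membership fraction (default 0.20).
#' @return integer vector of selected component indices.
#' @export
select_ccs <- function(ccs, parcellation, scale = c("global", "system",
                                                    "nodal"),
                       target = NULL, threshold = 0.20) {
  scale <- match.arg(scale)
  if (scale == "global") return(seq_along(ccs))
  if (threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]")
  if (scale == "system") {
    if (!target %in% parcellation$system)
      stop("unknown system label: ", target)
    hit <- vapply(ccs, function(cc) {
      regions <- unique(cc$nodes$region)
      mean(parcellation$system[regions] == target) >= threshold
    }, logical(1))
    return(which(hit))
  }
  target <- as.integer(target)
  if (target < 1 || target > nrow(parcellation))
    stop("unknown region id: ", target)
  which(vapply(ccs, function(cc) target %in% cc$nodes$region, logical(1)))
}
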