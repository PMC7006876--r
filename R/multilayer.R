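#' Build the spatiotemporal connectome (multilayer graph)
#'
#' Nodes are the active (region, frame) cells of the point process. Two
#' active cells are joined when the regions are structurally wired and the
#' frames coincide (`spatial` edge) or are successive (`temporal` edge);
#' additionally, the same region active at two successive frames is joined by
#' a `self` continuity edge (without it a region's sustained activation would
#' fragment; disable with `temporal_self = FALSE`). No edge spans more than
#' one frame, and coactivations between structurally unconnected regions are
#' never linked.
#'
#' @param pp a [to_point_process()] result.
#' @param template a `structural_template` (binary symmetric adjacency with
#'   per-edge lengths).
#' @param temporal_self include same-region temporal continuity edges
#'   (default `TRUE`).
#' @return a `multilayer_graph`: list with `nodes` (data.frame `region`,
#'   `frame`), `edges` (data.frame `r1`, `t1`, `r2`, `t2`, `type`),
#'   `n_regions`, `n_frames`, `retained_frame_index`.
#' @export
build_multilayer <- function(pp, template, temporal_self = TRUE) {
  a <- pp$active == 1L
  n <- nrow(a)
  tt <- ncol(a)
  if (n != template$n_regions)
    stop("dimension mismatch: point process has ", n, " regions, template ",
         template$n_regions)

  idx <- which(a, arr.ind = TRUE)
  nodes <- data.frame(region = idx[, 1], frame = idx[, 2])

  eu <- which(upper.tri(template$adjacency) & template$adjacency == 1L,
              arr.ind = TRUE)
  ei <- eu[, 1]
  ej <- eu[, 2]

  edge_parts <- list()
  if (length(ei)) {
    co <- a[ei, , drop = FALSE] & a[ej, , drop = FALSE]
    hit <- which(co, arr.ind = TRUE)
    if (nrow(hit)) {
      edge_parts$spatial <- data.frame(
        r1 = ei[hit[, 1]], t1 = hit[, 2],
        r2 = ej[hit[, 1]], t2 = hit[, 2], type = "spatial")
    }
    if (tt > 1) {
      fwd <- a[ei, -tt, drop = FALSE] & a[ej, -1, drop = FALSE]
      hit <- which(fwd, arr.ind = TRUE)
      if (nrow(hit)) {
        edge_parts$temporal_fwd <- data.frame(
          r1 = ei[hit[, 1]], t1 = hit[, 2],
          r2 = ej[hit[, 1]], t2 = hit[, 2] + 1L, type = "temporal")
      }
      bwd <- a[ej, -tt, drop = FALSE] & a[ei, -1, drop = FALSE]
      hit <- which(bwd, arr.ind = TRUE)
      if (nrow(hit)) {
        edge_parts$temporal_bwd <- data.frame(
          r1 = ej[hit[, 1]], t1 = hit[, 2],
          r2 = ei[hit[, 1]], t2 = hit[, 2] + 1L, type = "temporal")
      }
    }
  }
  if (temporal_self && tt > 1) {
    cont <- a[, -tt, drop = FALSE] & a[, -1, drop = FALSE]
    hit <- which(cont, arr.ind = TRUE)
    if (nrow(hit)) {
      edge_parts$self <- data.frame(
        r1 = hit[, 1], t1 = hit[, 2],
        r2 = hit[, 1], t2 = hit[, 2] + 1L, type = "self")
    }
  }
  edges <- if (length(edge_parts)) {
    do.call(rbind, unname(edge_parts))
  } else {
    data.frame(r1 = integer(), t1 = integer(), r2 = integer(),
               t2 = integer(), type = character())
  }
  rownames(edges) <- NULL
  structure(
    list(nodes = nodes, edges = edges, n_regions = n, n_frames = tt,
         retained_frame_index = pp$retained_frame_index),
    class = "multilayer_graph"
  )
}

#' Extract weakly connected components
#'
#' Partitions the multilayer graph's active cells into (weakly) connected
#' components — the dynamic functional patterns of the analysis. Components
#' are ordered deterministically by (first frame, first region at that
#' frame) and numbered from 1.
#'
#' @param g a [build_multilayer()] result.
#' @param min_nodes minimum component size; the default 2 drops isolated
#'   active cells (a component must contain at least one edge).
#' @return list of `connected_component` objects: `cc_id`, `nodes`
#'   (data.frame `region`, `frame`, sorted by frame then region),
#'   `frame_span` (c(t_min, t_max)), `n_unique_regions`, `edges` (the
#'   component's multilayer edges).
#' @export
extract_components <- function(g, min_nodes = 2L) {
  nodes <- g$nodes
  m <- nrow(nodes)
  if (m == 0L) return(list())
  n <- g$n_regions
  code <- (nodes$frame - 1L) * n + nodes$region
  e_a <- match((g$edges$t1 - 1L) * n + g$edges$r1, code)
  e_b <- match((g$edges$t2 - 1L) * n + g$edges$r2, code)

  ig <- igraph::make_empty_graph(n = m, directed = FALSE)
  if (length(e_a))
    ig <- igraph::add_edges(ig, rbind(e_a, e_b))
  comp <- igraph::components(ig)

  members <- split(seq_len(m), comp$membership)
  edge_comp <- if (length(e_a)) comp$membership[e_a] else integer()
  edges_by_comp <- split(seq_along(e_a), edge_comp)

  ccs <- lapply(members, function(ix) {
    nd <- nodes[ix, , drop = FALSE]
    ord <- order(nd$frame, nd$region)
    nd <- nd[ord, , drop = FALSE]
    rownames(nd) <- NULL
    nd
  })
  keep <- vapply(ccs, nrow, integer(1)) >= min_nodes
  ccs <- ccs[keep]
  comp_ids <- names(members)[keep]
  ord <- order(
    vapply(ccs, function(nd) nd$frame[1], numeric(1)),
    vapply(ccs, function(nd) nd$region[1], numeric(1)),
    -vapply(ccs, nrow, integer(1))
  )
  ccs <- ccs[ord]
  comp_ids <- comp_ids[ord]
  out <- vector("list", length(ccs))
  for (k in seq_along(ccs)) {
    nd <- ccs[[k]]
    eix <- edges_by_comp[[comp_ids[k]]]
    ed <- if (length(eix)) g$edges[eix, , drop = FALSE] else g$edges[0, ]
    rownames(ed) <- NULL
    out[[k]] <- structure(
      list(cc_id = k, nodes = nd,
           frame_span = c(min(nd$frame), max(nd$frame)),
           n_unique_regions = length(unique(nd$region)),
           edges = ed),
      class = "connected_component"
    )
  }
  out
}

#' Scrub motion-implicated components
#'
#' A component is removed when any of its cells sits in a flagged frame —
#' discarding the whole functional pattern, not just the corrupted frame, so
#' activations that spread from a motion artefact several frames away are
#' also excluded.
#'
#' @param ccs list of components from [extract_components()].
#' @param flagged logical vector over retained frames (see [map_flags()]).
#' @return list with `kept` and `removed` component lists.
#' @export
scrub_components <- function(ccs, flagged) {
  bad_frames <- which(flagged)
  hit <- vapply(ccs, function(cc) any(cc$nodes$frame %in% bad_frames),
                logical(1))
  list(kept = ccs[!hit], removed = ccs[hit])
}
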