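#' Framewise displacement from rigid-body motion parameters
#'
#' Power-style FD: the sum of absolute frame-to-frame changes of the three
#' translations (mm) plus the three rotations (radians) converted to arc
#' length on a sphere of `head_radius` mm. The first frame has FD 0.
#'
#' @param motion_params matrix/data.frame with 6 columns: 3 translations in
#'   mm, then 3 rotations in radians.
#' @param head_radius sphere radius for the rotation arc length, mm.
#' @return numeric FD series, one value per frame.
#' @export
framewise_displacement <- function(motion_params, head_radius = 50) {
  mp <- as.matrix(motion_params)
  if (ncol(mp) != 6)
    stop("motion_params must have 6 columns (3 translations, 3 rotations); ",
         "got ", ncol(mp))
  if (nrow(mp) < 2) stop("need at least 2 frames to compute FD")
  d <- abs(diff(mp))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    head_radius * rowSums(d[, 4:6, drop = FALSE])
  c(0, fd)
}

#' Flag motion-corrupted frames
#'
#' A frame is flagged when FD strictly exceeds `fd_thr` or DVARS strictly
#' exceeds `dvars_thr` (values exactly at a threshold are not flagged).
#'
#' @param trace data.frame (or list) with `fd` and `dvars` vectors of equal
#'   length.
#' @param fd_thr FD threshold, mm (default 0.4).
#' @param dvars_thr DVARS threshold (default 25).
#' @return a `motion_trace` data.frame: `frame`, `fd`, `dvars`, `flagged`
#'   (0/1), with attribute `mean_fd`.
#' @export
flag_frames <- function(trace, fd_thr = 0.4, dvars_thr = 25) {
  fd <- trace$fd
  dvars <- trace$dvars
  if (length(fd) != length(dvars))
    stop("fd and dvars must have the same length")
  if (any(fd < 0)) stop("fd must be non-negative")
  out <- data.frame(
    frame = seq_along(fd), fd = fd, dvars = dvars,
    flagged = as.integer(fd > fd_thr | dvars > dvars_thr)
  )
  attr(out, "mean_fd") <- mean(fd)
  class(out) <- c("motion_trace", "data.frame")
  out
}

#' Exclude high-motion subjects
#'
#' A subject is excluded when the fraction of flagged frames over the whole
#' run strictly exceeds `max_flag_fraction` (a subject at exactly the cut is
#' kept).
#'
#' @param traces named list of [flag_frames()] results, one per subject.
#' @param max_flag_fraction maximum tolerated flagged fraction (default 0.10).
#' @return a `qc_report` data.frame: `subject`, `n_frames`, `n_flagged`,
#'   `fraction`, `kept`.
#' @export
exclude_high_motion <- function(traces, max_flag_fraction = 0.10) {
  subjects <- names(traces)
  if (is.null(subjects)) subjects <- sprintf("subject_%d", seq_along(traces))
  rows <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    n <- nrow(tr)
    nf <- sum(tr$flagged)
    data.frame(subject = subjects[i], n_frames = n, n_flagged = nf,
               fraction = nf / n, kept = (nf / n) <= max_flag_fraction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("qc_report", "data.frame")
  out
}

#' Region-level DVARS surrogate
#'
#' Root-mean-square of the frame-to-frame signal differences across regions.
#' DVARS proper is defined on voxel data before parcellation; this
#' region-level surrogate is NOT equivalent (averaging within regions
#' suppresses voxel-scale variance) and is offered only for data sets that
#' ship no motion trace at all. The pipeline itself always expects DVARS
#' precomputed.
#'
#' @param bold regions x frames numeric matrix.
#' @return numeric series, one value per frame (first frame 0).
#' @export
dvars_surrogate <- function(bold) {
  x <- as.matrix(bold)
  if (ncol(x) < 2) stop("need at least 2 frames")
  d <- x[, -1, drop = FALSE] - x[, -ncol(x), drop = FALSE]
  c(0, sqrt(colMeans(d^2)))
}

#' Map original-frame motion flags onto retained frames
#'
#' Scrubbing parameters are computed on the full run, before the initial
#' frame drop; this maps the per-frame flags through the retained-frame index
#' so they align with the point process.
#'
#' @param trace a [flag_frames()] result (flags on original frames).
#' @param retained_frame_index original indices of the retained frames.
#' @return logical vector, one entry per retained frame.
#' @export
map_flags <- function(trace, retained_frame_index) {
  trace$flagged[retained_frame_index] == 1L
}
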