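#' Drop the initial frames of a BOLD matrix
#'
#' The first frames of an fMRI run are discarded to allow signal
#' stabilization (four by default). The original indices of the retained
#' frames are carried along so motion flags, computed on the full run, can be
#' aligned later.
#'
#' @param bold a regions x frames numeric matrix, or a `bold_matrix` as
#'   returned by this function.
#' @param n_drop number of leading frames to remove (default 4).
#' @return a `bold_matrix`: list with `values` (matrix) and
#'   `retained_frame_index` (original column indices of the retained frames).
#' @export
drop_initial_frames <- function(bold, n_drop = 4L) {
  b <- as_bold_matrix(bold)
  n_frames <- ncol(b$values)
  if (n_drop >= n_frames)
    stop("n_drop (", n_drop, ") must be smaller than the number of frames (",
         n_frames, ")")
  if (n_drop > 0) {
    keep <- (n_drop + 1L):n_frames
    b$values <- b$values[, keep, drop = FALSE]
    b$retained_frame_index <- b$retained_frame_index[keep]
  }
  b
}

as_bold_matrix <- function(bold) {
  if (inherits(bold, "bold_matrix")) return(bold)
  values <- as.matrix(bold)
  if (anyNA(values)) stop("BOLD matrix contains missing values")
  structure(list(values = values,
                 retained_frame_index = seq_len(ncol(values))),
            class = "bold_matrix")
}

#' Binarize a BOLD matrix into a point process
#'
#' Each region's series is z-scored over the retained frames and a frame is
#' marked active when the z-score strictly exceeds the threshold. Only the
#' positive tail counts by default — an "event" is a significant peak of BOLD
#' activity, not a deflation; set `tail = "absolute"` for a |z| criterion.
#'
#' @param bold a regions x frames matrix or `bold_matrix` (typically after
#'   [drop_initial_frames()]).
#' @param z_threshold threshold in SD units (default 2).
#' @param tail `"positive"` (default) or `"absolute"`.
#' @return a `point_process`: list with `active` (binary regions x frames
#'   matrix), `z_threshold`, `tail`, `retained_frame_index`.
#' @export
to_point_process <- function(bold, z_threshold = 2, tail = c("positive",
                                                             "absolute")) {
  tail <- match.arg(tail)
  b <- as_bold_matrix(bold)
  x <- b$values
  mu <- rowMeans(x)
  sdv <- apply(x, 1, sd)
  bad <- which(sdv == 0)
  if (length(bad))
    stop("zero-variance region(s): ", paste(bad, collapse = ", "),
         " — cannot z-score a constant series")
  z <- (x - mu) / sdv
  active <- if (tail == "positive") z > z_threshold else abs(z) > z_threshold
  structure(
    list(active = matrix(as.integer(active), nrow(x), ncol(x)),
         z_threshold = z_threshold, tail = tail,
         retained_frame_index = b$retained_frame_index),
    class = "point_process"
  )
}
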