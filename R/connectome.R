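#' Mean ROI timeseries from voxel data
#'
#' @param voxel_ts Frames x V voxel matrix.
#' @param labels Length-V ROI assignment (integer or label per voxel).
#' @return Frames x n matrix, one column per ROI (sorted unique labels), each
#'   the per-frame mean over member voxels.
#' @export
roi_mean_timeseries <- function(voxel_ts, labels) {
  voxel_ts <- as.matrix(voxel_ts)
  if (length(labels) != ncol(voxel_ts)) {
    stop("`labels` length must equal the voxel count")
  }
  ids <- sort(unique(labels))
  empty <- setdiff(ids, labels)
  if (length(empty) > 0L) stop(sprintf("empty ROI: %s", empty[1L]))
  out <- sapply(ids, function(id) {
    rowMeans(voxel_ts[, labels == id, drop = FALSE])
  })
  out <- matrix(out, nrow = nrow(voxel_ts))
  colnames(out) <- as.character(ids)
  out
}

#' Pairwise Pearson correlation over retained frames
#'
#' @param roi_ts Frames x n ROI timeseries.
#' @param mask Optional logical censor mask over frames; correlations use
#'   retained frames only (concatenated across runs).
#' @return Symmetric n x n correlation matrix (diagonal 1).
#' @export
pairwise_correlation <- function(roi_ts, mask = NULL) {
  Y <- as.matrix(roi_ts)
  if (!is.null(mask)) {
    if (length(mask) != nrow(Y)) stop("censor mask length must equal frame count")
    Y <- Y[as.logical(mask), , drop = FALSE]
  }
  if (nrow(Y) < 3L) stop("need at least 3 retained frames for correlation")
  sds <- apply(Y, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(Y)[sds == 0] %||% which(sds == 0)
    stop(sprintf("zero-variance ROI(s): %s",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  r <- stats::cor(Y)
  (r + t(r)) / 2
}

#' Fisher z-transform of a correlation matrix
#'
#' Elementwise \eqn{z = \mathrm{atanh}(r)}; the diagonal is stored as 0 by
#' convention and excluded from every downstream statistic.
#'
#' @param r Symmetric correlation matrix with off-diagonal `|r| < 1`.
#' @return Matrix of Fisher z values, diagonal 0.
#' @export
fisher_z <- function(r) {
  check_symmetric(r, arg = "r")
  off <- r[upper.tri(r)]
  if (any(abs(off) >= 1)) {
    stop("off-diagonal |r| = 1: degenerate ROI pair, cannot Fisher-transform")
  }
  z <- atanh(r)
  diag(z) <- 0
  z
}

#' Build a subject connectivity matrix
#'
#' Bundles the raw-r and Fisher-z matrices with subject metadata (Fig-style
#' C--E stage: extract, correlate, transform).
#'
#' @param roi_ts Frames x n cleaned ROI timeseries.
#' @param mask Optional censor mask.
#' @param subject_id Subject label.
#' @return List of class `connectivity_matrix` with fields `z`, `r`,
#'   `roi_ids`, `subject_id`, `n_frames_used`.
#' @export
build_connectivity <- function(roi_ts, mask = NULL, subject_id = NA_character_) {
  r <- pairwise_correlation(roi_ts, mask)
  roi_ids <- colnames(roi_ts) %||% as.character(seq_len(ncol(roi_ts)))
  dimnames(r) <- list(roi_ids, roi_ids)
  structure(list(
    z = fisher_z(r),
    r = r,
    roi_ids = roi_ids,
    subject_id = subject_id,
    n_frames_used = if (is.null(mask)) nrow(roi_ts) else sum(mask)
  ), class = "connectivity_matrix")
}
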