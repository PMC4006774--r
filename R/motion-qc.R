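#' Construct a rigid-body motion trace
#'
#' A motion trace holds the six rigid-body realignment parameters per frame:
#' three translations in millimetres (`t_x`, `t_y`, `t_z`) and three rotations
#' in radians (`r_pitch`, `r_roll`, `r_yaw`), one row per fMRI frame.
#'
#' @param params Numeric matrix or data frame with >= 2 rows and exactly 6
#'   columns ordered translations (mm) then rotations (radians).
#' @return A numeric matrix of class `motion_trace` with standardized column
#'   names.
#' @export
motion_trace <- function(params) {
  m <- as.matrix(params)
  if (ncol(m) != 6L) {
    stop("a motion trace requires exactly 6 columns (t_x t_y t_z r_pitch r_roll r_yaw)")
  }
  if (nrow(m) < 2L) stop("a motion trace requires at least 2 frames")
  storage.mode(m) <- "double"
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-finite motion parameter at frame %d", bad[1L, 1L]))
  }
  colnames(m) <- c("t_x", "t_y", "t_z", "r_pitch", "r_roll", "r_yaw")
  rownames(m) <- NULL
  class(m) <- c("motion_trace", "matrix", "array")
  m
}

#' Read a 6-column motion parameter file
#'
#' Reads whitespace-delimited realignment parameter files in the `rp_*.txt`
#' dialect: one row per frame, translations in mm followed by rotations in
#' radians, no header.
#'
#' @param path Path to the text file.
#' @return A [motion_trace()].
#' @export
read_motion_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("motion file not found: %s", path))
  m <- as.matrix(utils::read.table(path, header = FALSE))
  motion_trace(m)
}

#' Framewise displacement
#'
#' Framewise displacement (FD) at frame \eqn{t} is the mean absolute backward
#' difference of the three translational (respectively rotational) parameters:
#' \eqn{FD_t = \frac{1}{3}\sum_p |p_t - p_{t-1}|}. The first frame has FD 0 by
#' convention. Translational FD is in mm, rotational FD in radians.
#'
#' @param trace A [motion_trace()].
#' @return A list with numeric vectors `fd_trans` (mm) and `fd_rot` (radians),
#'   each the same length as the trace.
#' @export
framewise_displacement <- function(trace) {
  trace <- motion_trace(trace)
  d <- abs(diff(unclass(trace)))
  fd_trans <- c(0, rowMeans(d[, 1:3, drop = FALSE]))
  fd_rot <- c(0, rowMeans(d[, 4:6, drop = FALSE]))
  list(fd_trans = fd_trans, fd_rot = fd_rot)
}

#' Censor high-movement frames
#'
#' A frame is retained iff its translational framewise displacement is below
#' the threshold (default 1.5 mm, the stability criterion used for fetal
#' scans). Rotational FD is reported by QC but does not drive censoring.
#'
#' @param fd_trans Per-frame translational FD in mm.
#' @param threshold_mm Positive censoring threshold in mm.
#' @return Logical vector, `TRUE` = frame retained.
#' @export
censor_frames <- function(fd_trans, threshold_mm = 1.5) {
  if (!is.numeric(threshold_mm) || length(threshold_mm) != 1L || threshold_mm <= 0) {
    stop("`threshold_mm` must be a positive number")
  }
  if (any(!is.finite(fd_trans))) stop("`fd_trans` contains non-finite values")
  as.logical(fd_trans < threshold_mm)
}

#' Subject-level exclusion rule
#'
#' Subjects retaining fewer than `min_frames` frames (default 90 volumes)
#' after censoring are excluded from all group analyses.
#'
#' @param mask Logical censor mask (`TRUE` = retained).
#' @param min_frames Minimum retained-frame count to keep a subject.
#' @return `TRUE` if the subject is excluded.
#' @export
exclude_subject <- function(mask, min_frames = 90) {
  sum(mask) < min_frames
}

#' Segment a censor mask into contiguous retained runs
#'
#' @param mask Logical censor mask.
#' @return List with `segment_lengths` (maximal runs of retained frames),
#'   `n_interruptions` (censored gaps falling between two retained runs) and
#'   `n_retained`.
#' @export
segment_runs <- function(mask) {
  mask <- as.logical(mask)
  r <- rle(mask)
  seg <- r$lengths[r$values]
  n_seg <- length(seg)
  list(
    segment_lengths = as.integer(seg),
    n_interruptions = max(0L, n_seg - 1L),
    n_retained = as.integer(sum(seg))
  )
}

#' Movement summaries for one subject
#'
#' Mean framewise displacement and RMS per movement class. RMS is computed per
#' parameter about its own mean and then averaged within the translational and
#' rotational classes.
#'
#' @param trace A [motion_trace()].
#' @param mask Optional censor mask; retained/interruption counts are derived
#'   from it (defaults to all-retained).
#' @return One-row data frame with columns `mean_translational_fd`,
#'   `mean_rotational_fd`, `translational_rms`, `rotational_rms`,
#'   `n_frames_total`, `n_frames_retained`, `n_interruptions`.
#' @export
motion_summary <- function(trace, mask = NULL) {
  trace <- motion_trace(trace)
  n <- nrow(trace)
  if (is.null(mask)) mask <- rep(TRUE, n)
  if (length(mask) != n) stop("censor mask length must equal trace length")
  fd <- framewise_displacement(trace)
  rms1 <- function(x) sqrt(mean((x - mean(x))^2))
  seg <- segment_runs(mask)
  data.frame(
    mean_translational_fd = mean(fd$fd_trans),
    mean_rotational_fd = mean(fd$fd_rot),
    translational_rms = mean(apply(trace[, 1:3, drop = FALSE], 2, rms1)),
    rotational_rms = mean(apply(trace[, 4:6, drop = FALSE], 2, rms1)),
    n_frames_total = n,
    n_frames_retained = seg$n_retained,
    n_interruptions = seg$n_interruptions
  )
}

#' Compare movement summaries between two groups
#'
#' Welch two-sample t-tests per movement summary between (typically) younger
#' and older subjects. Parameters significant at `p <= alpha` are flagged as
#' movement covariates for downstream age analyses (entered via partial
#' correlation).
#'
#' @param summaries Data frame of per-subject movement summaries (one row per
#'   subject) containing the four movement columns of [motion_summary()].
#' @param groups Factor or vector with exactly two levels, one entry per row.
#' @param alpha Flagging threshold (default 0.05).
#' @return Data frame with columns `parameter`, `t`, `p`, `flagged`.
#' @export
movement_group_test <- function(summaries, groups, alpha = 0.05) {
  pars <- c(
    "mean_translational_fd", "mean_rotational_fd",
    "translational_rms", "rotational_rms"
  )
  pars <- intersect(pars, names(summaries))
  if (length(pars) == 0L) stop("no movement summary columns found")
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("`groups` must have exactly two levels")
  if (any(table(groups) < 2L)) stop("each group needs at least 2 subjects")
  res <- lapply(pars, function(p) {
    x <- summaries[[p]][groups == levels(groups)[1L]]
    y <- summaries[[p]][groups == levels(groups)[2L]]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      tt <- list(statistic = c(t = 0), p.value = 1)
    } else {
      tt <- stats::t.test(x, y)
    }
    data.frame(
      parameter = p,
      t = unname(tt$statistic),
      p = tt$p.value
    )
  })
  out <- do.call(rbind, res)
  out$flagged <- out$p <= alpha
  out
}
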