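#' Extract principal components of noise-tissue signals
#'
#' aCompCor-style confound estimation: the top-\eqn{k} principal component
#' score series of the (column-centred) white-matter/CSF surrogate
#' timeseries, unit-normalized and ordered by decreasing explained variance.
#'
#' @param noise_ts Frames x m numeric matrix of noise-tissue signals.
#' @param k Number of components, `k <= min(frames - 1, m)` and within the
#'   numerical rank.
#' @return Frames x k matrix with columns `component_1..k`, each scaled to
#'   unit Euclidean norm.
#' @export
extract_noise_components <- function(noise_ts, k) {
  noise_ts <- as.matrix(noise_ts)
  if (!is_count(k)) stop("`k` must be a positive integer")
  if (k > min(nrow(noise_ts) - 1L, ncol(noise_ts))) {
    stop(sprintf("k = %d exceeds min(frames - 1, m) = %d",
                 k, min(nrow(noise_ts) - 1L, ncol(noise_ts))))
  }
  x <- scale(noise_ts, center = TRUE, scale = FALSE)
  pc <- stats::prcomp(x, center = FALSE)
  if (k > sum(pc$sdev > 1e-10 * pc$sdev[1])) {
    stop(sprintf("k = %d exceeds the numerical rank of the noise matrix", k))
  }
  scores <- pc$x[, seq_len(k), drop = FALSE]
  scores <- sweep(scores, 2, sqrt(colSums(scores^2)), "/")
  colnames(scores) <- sprintf("component_%d", seq_len(k))
  scores
}

#' Assemble the nuisance regressor matrix
#'
#' Six rigid-body motion parameters, their six backward-difference temporal
#' derivatives (first frame 0), and the noise-tissue components, all
#' restricted to retained frames and mean-centred. With `k` components the
#' design has `p = k + 12` columns.
#'
#' @param trace A [motion_trace()] covering all frames.
#' @param components Noise components; either full-length (subset internally
#'   by `mask`) or already restricted to retained frames.
#' @param mask Logical censor mask over all frames.
#' @return Retained-frames x p numeric matrix with labelled columns.
#' @export
build_regressors <- function(trace, components, mask = NULL) {
  trace <- motion_trace(trace)
  n <- nrow(trace)
  if (is.null(mask)) mask <- rep(TRUE, n)
  if (length(mask) != n) stop("censor mask length must equal trace length")
  comp <- as.matrix(components)
  deriv <- rbind(0, diff(unclass(trace)))
  colnames(deriv) <- paste0("d_", colnames(trace))
  X <- cbind(unclass(trace), deriv)[mask, , drop = FALSE]
  if (nrow(comp) == n) {
    comp <- comp[mask, , drop = FALSE]
  } else if (nrow(comp) != sum(mask)) {
    stop("`components` rows must match either all frames or retained frames")
  }
  if (is.null(colnames(comp))) {
    colnames(comp) <- sprintf("component_%d", seq_len(ncol(comp)))
  }
  X <- cbind(comp, X)
  scale(X, center = TRUE, scale = FALSE)
}

#' Regress nuisance signals out of ROI timeseries
#'
#' Ordinary least-squares residualization of every ROI column on the nuisance
#' design (intercept included). Residuals are orthogonal to every design
#' column. Collinear design columns are dropped with a warning.
#'
#' @param timeseries Retained-frames x n ROI matrix.
#' @param regressors Retained-frames x p design from [build_regressors()].
#' @return Residual matrix of the same shape as `timeseries`.
#' @export
regress_out <- function(timeseries, regressors) {
  Y <- as.matrix(timeseries)
  X <- as.matrix(regressors)
  if (nrow(Y) != nrow(X)) stop("timeseries and regressors row counts differ")
  if (nrow(X) <= ncol(X) + 1L) {
    stop("need more retained frames than regressors + 1")
  }
  D <- cbind(intercept = 1, X)
  qr_d <- qr(D)
  if (qr_d$rank < ncol(D)) {
    keep <- qr_d$pivot[seq_len(qr_d$rank)]
    dropped <- colnames(D)[setdiff(seq_len(ncol(D)), keep)]
    warning(sprintf("dropped collinear regressor column(s): %s",
                    paste(dropped, collapse = ", ")))
    D <- D[, sort(keep), drop = FALSE]
    qr_d <- qr(D)
  }
  res <- qr.resid(qr_d, Y)
  dimnames(res) <- dimnames(Y)
  res
}
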