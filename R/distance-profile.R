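#' Euclidean distance matrix between ROI centroids
#'
#' @param centroids ROI x 3 matrix of centroid coordinates in mm (or a
#'   `roi_set`, whose centroids are used). Duplicate centroids are allowed
#'   (distance 0) and reported via a message.
#' @return Symmetric n x n distance matrix in mm with zero diagonal.
#' @export
roi_distances <- function(centroids) {
  if (inherits(centroids, "roi_set")) centroids <- centroids$centroids
  centroids <- as.matrix(centroids)
  if (any(!is.finite(centroids))) stop("centroids must be finite")
  D <- as.matrix(stats::dist(centroids))
  dup <- sum(upper_pairs(D) == 0)
  if (dup > 0) message(sprintf("%d ROI pair(s) share identical centroids", dup))
  dimnames(D) <- list(rownames(centroids), rownames(centroids))
  D
}

bin_edges_20 <- seq(-1, 1, by = 0.1)

#' Distance-strength bin table
#'
#' Assigns every unique ROI pair to one of 20 correlation bins of width 0.1
#' over \eqn{r \in [-1, 1]} (left-closed, right-open; the final bin closed at
#' 1) and reports the pair count and mean Euclidean length per bin. Binning
#' uses raw Pearson r, not Fisher z.
#'
#' @param r Symmetric raw correlation matrix.
#' @param distances Matching distance matrix from [roi_distances()].
#' @return Data frame with `bin_low`, `bin_high`, `n_pairs`,
#'   `mean_length_mm` (`NA` for empty bins); counts sum to n(n-1)/2.
#' @export
strength_length_bins <- function(r, distances) {
  check_symmetric(r, arg = "r")
  check_symmetric(distances, arg = "distances")
  rv <- upper_pairs(r)
  dv <- upper_pairs(distances)
  if (any(rv < -1 | rv > 1)) stop("correlation values outside [-1, 1]")
  idx <- findInterval(rv, bin_edges_20, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = 20L)
  means <- vapply(seq_len(20L), function(b) {
    if (counts[b] == 0L) NA_real_ else mean(dv[idx == b])
  }, 0)
  data.frame(
    bin_low = bin_edges_20[1:20],
    bin_high = bin_edges_20[2:21],
    n_pairs = counts,
    mean_length_mm = means
  )
}

#' Strength of the longest and shortest connections
#'
#' Ranks all unique pairs by Euclidean distance and compares the mean raw
#' correlation of the longest `pct`% against the shortest `pct`% (tail size
#' \eqn{\lceil pct\% \cdot n(n-1)/2 \rceil}).
#'
#' @param r Symmetric raw correlation matrix.
#' @param distances Matching distance matrix.
#' @param pct Tail percentage in (0, 50].
#' @return List: `mean_r_longest`, `mean_r_shortest`, `long_cutoff_mm`
#'   (minimum distance in the long tail), `short_cutoff_mm` (maximum distance
#'   in the short tail), `n_tail`.
#' @export
extreme_connection_strength <- function(r, distances, pct = 5) {
  check_symmetric(r, arg = "r")
  check_symmetric(distances, arg = "distances")
  if (!is.numeric(pct) || pct <= 0 || pct > 50) stop("`pct` must be in (0, 50]")
  rv <- upper_pairs(r)
  dv <- upper_pairs(distances)
  m <- ceiling(pct / 100 * length(dv))
  if (m < 1L) stop("fewer than 1 pair in a tail")
  ord <- order(dv)
  short <- ord[seq_len(m)]
  long <- ord[seq(length(dv) - m + 1L, length(dv))]
  list(
    mean_r_longest = mean(rv[long]),
    mean_r_shortest = mean(rv[short]),
    long_cutoff_mm = min(dv[long]),
    short_cutoff_mm = max(dv[short]),
    n_tail = m
  )
}

#' Range and histogram of pairwise correlations
#'
#' @param r Symmetric raw correlation matrix.
#' @return List: `min`, `max`, `range`, and `histogram` (per-bin frequencies
#'   over the 20 standard bins; frequencies sum to the pair count).
#' @export
correlation_range_summary <- function(r) {
  check_symmetric(r, arg = "r")
  rv <- upper_pairs(r)
  idx <- findInterval(rv, bin_edges_20, rightmost.closed = TRUE)
  list(
    min = min(rv),
    max = max(rv),
    range = max(rv) - min(rv),
    histogram = data.frame(
      bin_low = bin_edges_20[1:20],
      bin_high = bin_edges_20[2:21],
      n_pairs = tabulate(idx, nbins = 20L)
    )
  )
}
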