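#' Median gestational-age split
#'
#' @param ga_weeks Gestational ages in weeks.
#' @param cut_weeks Split point (default 31 weeks).
#' @return Factor with levels `younger` (GA < cut) and `older` (GA >= cut).
#' @export
split_median_age <- function(ga_weeks, cut_weeks = 31) {
  if (any(!is.finite(ga_weeks))) stop("gestational age must be present for all subjects")
  factor(ifelse(ga_weeks < cut_weeks, "younger", "older"),
         levels = c("younger", "older"))
}

#' Correlation of a cohort measure with gestational age
#'
#' Plain Pearson correlation with a two-sided test when no covariates are
#' supplied. With covariates (e.g. a flagged movement summary), both the
#' measure and GA are residualized on the covariates and the partial
#' correlation is tested on `n - 2 - k` degrees of freedom.
#'
#' @param values Per-subject measure.
#' @param ga Per-subject gestational age (weeks).
#' @param covariates Optional numeric vector, matrix or data frame of
#'   per-subject covariates.
#' @param effect Label for the result row.
#' @return One-row data frame: `effect`, `estimate` (r), `t`, `p`, `n`,
#'   `covariates`.
#' @export
ga_correlation <- function(values, ga, covariates = NULL, effect = "ga_correlation") {
  n <- length(values)
  if (length(ga) != n) stop("`values` and `ga` lengths differ")
  k <- 0L
  cov_label <- ""
  if (is.null(covariates)) {
    if (stats::sd(values) == 0 || stats::sd(ga) == 0) {
      stop("zero variance in `values` or `ga`")
    }
    ct <- stats::cor.test(values, ga)
    r <- unname(ct$estimate)
    tt <- unname(ct$statistic)
    p <- ct$p.value
  } else {
    X <- as.matrix(as.data.frame(covariates))
    k <- ncol(X)
    if (n < 4 + k) stop("need n >= 4 + number of covariates")
    cov_label <- paste(colnames(X) %||% sprintf("cov%d", seq_len(k)),
                       collapse = ";")
    rv <- stats::resid(stats::lm(values ~ X))
    rg <- stats::resid(stats::lm(ga ~ X))
    if (stats::sd(rv) < 1e-12 || stats::sd(rg) < 1e-12) {
      stop("zero residual variance: partial correlation undefined")
    }
    r <- stats::cor(rv, rg)
    df <- n - 2L - k
    tt <- r * sqrt(df / (1 - r^2))
    p <- 2 * stats::pt(-abs(tt), df)
  }
  data.frame(effect = effect, estimate = r, t = tt, p = p, n = n,
             covariates = cov_label)
}

#' Robust regression of a nodal measure on gestational age
#'
#' Iteratively reweighted least squares with Tukey bisquare weights (tuning
#' constant 4.685), intercept plus GA slope. The reported statistic is the
#' slope t = estimate/SE; its two-sided p uses `n - 2` degrees of freedom.
#' Non-convergence is flagged, not silent.
#'
#' @param values Per-subject nodal measure.
#' @param ga Per-subject gestational age (weeks).
#' @param effect Label for the result row.
#' @return One-row data frame: `effect`, `estimate` (slope), `t`, `p`, `n`,
#'   `converged`.
#' @export
robust_age_regression <- function(values, ga, effect = "robust_age") {
  n <- length(values)
  if (n < 5) stop("robust regression needs n >= 5")
  if (stats::sd(values) == 0) { # constant measure: no age effect estimable
    return(data.frame(effect = effect, estimate = 0, t = 0, p = 1, n = n,
                      converged = TRUE))
  }
  fit <- try(suppressWarnings(MASS::rlm(values ~ ga, psi = MASS::psi.bisquare,
                                        c = 4.685, maxit = 50, acc = 1e-8)),
             silent = TRUE)
  converged <- !inherits(fit, "try-error") && isTRUE(fit$converged)
  if (!inherits(fit, "try-error")) {
    sm <- summary(fit)
    est <- sm$coefficients["ga", "Value"]
    tt <- sm$coefficients["ga", "t value"]
  } else {
    est <- NaN; tt <- NaN
  }
  if (!is.finite(tt)) {
    # Degenerate robust fit (e.g. mostly-constant measure gives a zero MAD
    # scale): fall back to OLS and flag non-convergence.
    sm <- summary(stats::lm(values ~ ga))
    est <- sm$coefficients["ga", "Estimate"]
    tt <- sm$coefficients["ga", "t value"]
    converged <- FALSE
  }
  data.frame(effect = effect, estimate = est, t = tt,
             p = 2 * stats::pt(-abs(tt), n - 2L), n = n,
             converged = converged)
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up BH procedure: rejects the hypotheses with the `k` smallest
#' p-values, where `k` is the largest index with \eqn{p_{(k)} \le k q / m}.
#'
#' @param p P-values in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return List with `q_values` (BH-adjusted) and logical `reject`.
#' @export
fdr_correct <- function(p, q = 0.05) {
  if (length(p) == 0L) return(list(q_values = numeric(0), reject = logical(0)))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  qv <- stats::p.adjust(p, method = "BH")
  list(q_values = qv, reject = qv <= q)
}

#' Welch two-sample comparison
#'
#' @param values_a,values_b Samples for the two groups (>= 2 each).
#' @param alpha Significance level (0.025 for the extreme-connection length
#'   tests, 0.05 elsewhere).
#' @param effect Label for the result row.
#' @return One-row data frame: `effect`, `estimate` (mean difference a - b),
#'   `t`, `p`, `significant`, `n`.
#' @export
group_ttest <- function(values_a, values_b, alpha = 0.05, effect = "group_diff") {
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop("each group needs at least 2 values")
  }
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
    if (mean(values_a) == mean(values_b)) {
      return(data.frame(effect = effect, estimate = 0, t = 0, p = 1,
                        significant = FALSE,
                        n = length(values_a) + length(values_b)))
    }
    stop("degenerate variance in both groups")
  }
  tt <- stats::t.test(values_a, values_b)
  data.frame(
    effect = effect,
    estimate = mean(values_a) - mean(values_b),
    t = unname(tt$statistic),
    p = tt$p.value,
    significant = tt$p.value <= alpha,
    n = length(values_a) + length(values_b)
  )
}

#' Exploratory follow-up of a flagged hub node
#'
#' Restricts to regions assigned to a different module than the hub in every
#' subject, then correlates the hub-region edge weight with GA per region.
#' P-values are nominal (exploratory search, no FDR).
#'
#' @param W_list Per-subject connectivity matrices (same node order).
#' @param memberships Per-subject module assignments (vectors or
#'   `fconn_partition`s).
#' @param hub Hub node index.
#' @param ga Per-subject gestational ages.
#' @return Data frame `region`, `r`, `p` (possibly empty, with a message).
#' @export
pcc_followup <- function(W_list, memberships, hub, ga) {
  stopifnot(length(W_list) == length(memberships),
            length(W_list) == length(ga))
  memb <- lapply(memberships, function(m) {
    if (inherits(m, "fconn_partition")) m$membership else m
  })
  n <- nrow(W_list[[1L]])
  other <- vapply(seq_len(n), function(j) {
    j != hub && all(vapply(memb, function(m) m[j] != m[hub], TRUE))
  }, TRUE)
  regions <- which(other)
  if (length(regions) == 0L) {
    message("no region lies outside the hub's module in every subject")
    return(data.frame(region = integer(0), r = numeric(0), p = numeric(0)))
  }
  res <- lapply(regions, function(j) {
    w <- vapply(W_list, function(W) W[hub, j], 0)
    ct <- stats::cor.test(w, ga)
    data.frame(region = j, r = unname(ct$estimate), p = ct$p.value)
  })
  do.call(rbind, res)
}
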