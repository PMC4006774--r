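# Independent brute-force oracles and fixture builders. Every oracle here is
# a direct transcription of a definition (double loops, enumeration, closed
# form) and shares no code with the implementation it checks.

rand_signed_matrix <- function(n, seed) {
  set.seed(seed)
  A <- matrix(stats::rnorm(n * n), n)
  A <- (A + t(A)) / 2
  diag(A) <- 0
  A
}

planted_block_matrix <- function(n, M, within = 0.4, between = -0.1,
                                 noise_sd = 0.05, seed = 1) {
  set.seed(seed)
  memb <- sort(rep(seq_len(M), length.out = n))
  W <- matrix(between, n, n)
  for (m in seq_len(M)) W[memb == m, memb == m] <- within
  E <- matrix(stats::rnorm(n * n, sd = noise_sd), n)
  W <- W + (E + t(E)) / 2
  diag(W) <- 0
  list(W = W, membership = memb)
}

oracle_q_star <- function(W, m) {
  Wp <- pmax(W, 0); Wn <- -pmin(W, 0)
  vp <- sum(Wp); vn <- sum(Wn)
  sp <- rowSums(Wp); sn <- rowSums(Wn)
  n <- nrow(W); qp <- 0; qn <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (m[i] == m[j]) {
      qp <- qp + Wp[i, j] - sp[i] * sp[j] / vp
      if (vn > 0) qn <- qn + Wn[i, j] - sn[i] * sn[j] / vn
    }
  }
  qp / vp - qn / (vp + vn)
}

# standard weighted Newman modularity (positive weights only)
oracle_newman <- function(W, m) {
  tw <- sum(W)
  k <- rowSums(W)
  n <- nrow(W)
  q <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (m[i] == m[j]) q <- q + W[i, j] - k[i] * k[j] / tw
  }
  q / tw
}

oracle_participation <- function(W, m, sign) {
  Ws <- if (sign == "positive") pmax(W, 0) else -pmin(W, 0)
  diag(Ws) <- 0
  n <- nrow(W)
  vapply(seq_len(n), function(i) {
    k <- sum(Ws[i, ])
    if (k == 0) return(0)
    1 - sum(vapply(unique(m), function(s) sum(Ws[i, m == s])^2, 0) / k^2)
  }, 0)
}

oracle_module_z <- function(W, m, sign, scope) {
  Ws <- if (sign == "positive") pmax(W, 0) else -pmin(W, 0)
  diag(Ws) <- 0
  n <- nrow(W)
  kappa <- vapply(seq_len(n), function(i) {
    inside <- m == m[i]
    inside[i] <- FALSE
    if (scope == "within") sum(Ws[i, inside]) else sum(Ws[i, m != m[i]])
  }, 0)
  z <- numeric(n)
  for (mm in unique(m)) {
    idx <- which(m == mm)
    if (length(idx) < 2 || stats::sd(kappa[idx]) == 0) {
      z[idx] <- 0
    } else {
      z[idx] <- (kappa[idx] - mean(kappa[idx])) / stats::sd(kappa[idx])
    }
  }
  z
}

# Benjamini-Hochberg by the literal step-up definition
oracle_bh_reject <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- suppressWarnings(max(which(ps <= seq_len(m) * q / m)))
  reject <- logical(m)
  if (is.finite(k) && k >= 1) reject[ord[seq_len(k)]] <- TRUE
  reject
}

# partial correlation of x and y given Z via the precision matrix
oracle_partial_r <- function(x, y, Z) {
  R <- stats::cor(cbind(x, y, Z))
  P <- solve(R)
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

# all set partitions of n items as restricted growth strings
all_set_partitions <- function(n) {
  res <- list()
  rec <- function(prefix, maxlab) {
    if (length(prefix) == n) {
      res[[length(res) + 1L]] <<- prefix
      return(invisible())
    }
    for (lab in seq_len(maxlab + 1L)) rec(c(prefix, lab), max(maxlab, lab))
  }
  rec(integer(0), 0L)
  do.call(rbind, res)
}

ari <- mclust::adjustedRandIndex

# --- cohort fixtures --------------------------------------------------------

# reduced cohort used by replicate-heavy checks
small_cfg <- function(seed, ...) {
  cohort_config(
    n_subjects = 16, n_rois = 24, n_modules = 3,
    n_frames_range = c(120L, 180L), longrange_set_size = 5,
    seed = seed, ...
  )
}

null_cfg <- function(seed) {
  small_cfg(
    seed,
    lambda_between_slope_per_week = 0, pcc_neg_slope_per_week = 0,
    longrange_effect = 0, motion_spike_prob_age_slope = 0
  )
}

power_cfg <- function(seed) {
  cohort_config(
    n_subjects = 24, n_rois = 40, n_modules = 4,
    n_frames_range = c(150L, 250L), longrange_set_size = 6, seed = seed
  )
}

# default-condition cohort and analysis, computed once per test run
.fixtures <- new.env(parent = emptyenv())

default_cohort <- function() {
  if (is.null(.fixtures$cohort)) {
    .fixtures$cohort <- generate_cohort(cohort_config(seed = 7))
  }
  .fixtures$cohort
}

default_analysis <- function() {
  if (is.null(.fixtures$analysis)) {
    .fixtures$analysis <- suppressMessages(
      analyze_cohort(default_cohort(), n_consensus = 20, seed = 11)
    )
  }
  .fixtures$analysis
}
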