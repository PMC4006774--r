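#' Signed-weight modularity Q*
#'
#' Asymmetric signed modularity for fully weighted networks with negative
#' edges. With \eqn{w^+ = \max(w, 0)}, \eqn{w^- = -\min(w, 0)},
#' \eqn{s^\pm_i = \sum_j w^\pm_{ij}}, \eqn{v^\pm = \sum_{ij} w^\pm_{ij}} and
#' chance terms \eqn{e^\pm_{ij} = s^\pm_i s^\pm_j / v^\pm},
#' \deqn{Q^* = \frac{1}{v^+}\sum_{ij}(w^+_{ij} - e^+_{ij})\,\delta_{m_i m_j}
#'   - \frac{1}{v^+ + v^-}\sum_{ij}(w^-_{ij} - e^-_{ij})\,\delta_{m_i m_j}.}
#' Positive within-module weight raises Q* at full strength while negative
#' within-module weight lowers it at reduced strength. With no negative
#' weights Q* reduces to standard weighted Newman modularity. The value is
#' invariant to module relabelling.
#'
#' @param W Symmetric signed weight matrix (diagonal 0 by convention).
#' @param membership Integer module assignment, one entry per node.
#' @return The scalar Q* value.
#' @export
q_star <- function(W, membership) {
  check_symmetric(W)
  n <- nrow(W)
  if (length(membership) != n) stop("`membership` must label every node")
  Wp <- pmax(W, 0)
  Wn <- -pmin(W, 0)
  vp <- sum(Wp)
  vn <- sum(Wn)
  if (vp == 0) stop("all-zero positive weights: Q* undefined (v+ = 0)")
  qpart <- function(Ws, v) {
    if (v == 0) return(0)
    s <- rowSums(Ws)
    tot <- 0
    for (m in unique(membership)) {
      idx <- membership == m
      tot <- tot + sum(Ws[idx, idx]) - sum(s[idx])^2 / v
    }
    tot
  }
  qpart(Wp, vp) / vp - qpart(Wn, vn) / (vp + vn)
}

# -- internal Louvain machinery ---------------------------------------------

relabel_membership <- function(memb) {
  match(memb, unique(memb))
}

new_partition <- function(membership, q, n_iterations = 1L, seed = NA_integer_) {
  structure(list(
    membership = relabel_membership(membership),
    q_star = q,
    n_iterations = as.integer(n_iterations),
    seed = seed
  ), class = "fconn_partition")
}

#' @export
print.fconn_partition <- function(x, ...) {
  cat(sprintf("<fconn_partition> %d nodes, %d modules, Q* = %.4f (%d iteration%s)\n",
              length(x$membership), max(x$membership), x$q_star,
              x$n_iterations, if (x$n_iterations == 1L) "" else "s"))
  invisible(x)
}

# One local-move phase: repeated sweeps of best single-node reassignments
# (to existing modules) until a full sweep yields no Q*-increasing move.
# Gains are exact Q* differences derived from the asymmetric signed formula;
# ties break toward the lowest module index. Self-loops (present on
# aggregated graphs) are handled: they travel with the node and cancel in
# the gain.
sweep_moves <- function(Wp, Wn, vp, vn, memb, randomize = TRUE, tol = 1e-12) {
  n <- nrow(Wp)
  sp <- rowSums(Wp)
  sn <- rowSums(Wn)
  Mmax <- max(memb)
  Sp <- numeric(Mmax); Sn <- numeric(Mmax)
  for (m in seq_len(Mmax)) {
    idx <- memb == m
    Sp[m] <- sum(sp[idx]); Sn[m] <- sum(sn[idx])
  }
  csize <- tabulate(memb, nbins = Mmax)
  group_sums <- function(w, self_m, self_w) {
    k <- numeric(Mmax)
    tmp <- rowsum(w, memb, reorder = TRUE)
    k[as.integer(rownames(tmp))] <- tmp
    k[self_m] <- k[self_m] - self_w
    k
  }
  moved_any <- FALSE
  repeat {
    moved <- FALSE
    order_i <- if (randomize) sample.int(n) else seq_len(n)
    for (i in order_i) {
      a <- memb[i]
      # candidate targets: every current module plus one empty module
      # (slot Mmax + 1), so a node can always split out on its own
      kp <- c(group_sums(Wp[i, ], a, Wp[i, i]), 0)
      kn <- c(group_sums(Wn[i, ], a, Wn[i, i]), 0)
      Sp1 <- c(Sp, 0); Sn1 <- c(Sn, 0)
      dpos <- 2 * (kp - kp[a]) -
        2 * sp[i] * (Sp1 - (Sp1[a] - sp[i])) / vp
      dpos[a] <- 0
      gain <- dpos / vp
      if (vn > 0) {
        dneg <- 2 * (kn - kn[a]) -
          2 * sn[i] * (Sn1 - (Sn1[a] - sn[i])) / vn
        dneg[a] <- 0
        gain <- gain - dneg / (vp + vn)
      }
      if (csize[a] == 1L) {
        gain[Mmax + 1L] <- 0 # already alone: a fresh module is no move
      }
      b <- which.max(gain)
      if (b != a && gain[b] > tol) {
        if (b == Mmax + 1L) { # open the empty module
          Mmax <- Mmax + 1L
          Sp <- c(Sp, 0); Sn <- c(Sn, 0); csize <- c(csize, 0L)
        }
        memb[i] <- b
        Sp[a] <- Sp[a] - sp[i]; Sp[b] <- Sp[b] + sp[i]
        Sn[a] <- Sn[a] - sn[i]; Sn[b] <- Sn[b] + sn[i]
        csize[a] <- csize[a] - 1L; csize[b] <- csize[b] + 1L
        moved <- TRUE
        moved_any <- TRUE
      }
    }
    if (!moved) break
  }
  list(membership = memb, moved = moved_any)
}

aggregate_signed <- function(Ws, memb) {
  rowsum(t(rowsum(Ws, memb, reorder = TRUE)), memb, reorder = TRUE)
}

#' Louvain community detection for signed weighted networks
#'
#' Greedy two-phase maximization of [q_star()]: seeded random-order local
#' moves followed by module aggregation (positive and negative weight layers
#' aggregated separately so the objective is preserved exactly), repeated
#' until no further improvement. Deterministic given the seed.
#'
#' @param W Symmetric signed weight matrix with some positive weight.
#' @param seed RNG seed controlling node visit order.
#' @return An `fconn_partition` (membership, Q*, seed).
#' @export
louvain_signed <- function(W, seed = 1) {
  check_symmetric(W)
  Wp <- pmax(W, 0)
  Wn <- -pmin(W, 0)
  vp <- sum(Wp)
  vn <- sum(Wn)
  if (vp == 0) stop("all-zero positive weights: Q* undefined (v+ = 0)")
  n <- nrow(W)
  node2comm <- seq_len(n)
  with_seed(seed, {
    cWp <- Wp; cWn <- Wn
    repeat {
      res <- sweep_moves(cWp, cWn, vp, vn, memb = seq_len(nrow(cWp)))
      memb <- relabel_membership(res$membership)
      node2comm <- memb[node2comm]
      if (!res$moved || max(memb) == nrow(cWp)) break
      cWp <- aggregate_signed(cWp, memb)
      cWn <- aggregate_signed(cWn, memb)
    }
  })
  q <- q_star(W, node2comm)
  if (q < 0) { # never return worse than the trivial single-module partition
    node2comm <- rep(1L, n)
    q <- q_star(W, node2comm)
  }
  new_partition(node2comm, q, n_iterations = 1L, seed = seed)
}

partition_key <- function(memb) paste(relabel_membership(memb), collapse = ",")

#' Consensus partition over repeated Louvain runs
#'
#' Runs [louvain_signed()] under `n_iter` derived seeds and returns the
#' partition most consistently identified across runs. Runs first compete on
#' quality: only partitions whose Q* ties the best run (within 1e-10) are
#' candidates, and among those the medoid under adjusted Rand similarity —
#' the partition maximizing the multiplicity-weighted mean ARI to the other
#' candidates — is returned. Consistency thus arbitrates between co-optimal
#' partitions rather than overruling the modularity objective.
#'
#' @param W Symmetric signed weight matrix.
#' @param n_iter Number of Louvain restarts (default 1000).
#' @param seed Master seed from which the restart seeds derive.
#' @return An `fconn_partition` with `n_iterations = n_iter`.
#' @export
consensus_partition <- function(W, n_iter = 1000, seed = 1) {
  if (!is_count(n_iter)) stop("`n_iter` must be a positive integer")
  seeds <- derive_seeds(seed, n_iter)
  runs <- lapply(seeds, function(s) louvain_signed(W, seed = s))
  q_best <- max(vapply(runs, `[[`, 0, "q_star"))
  runs <- runs[vapply(runs, `[[`, 0, "q_star") >= q_best - 1e-10]
  keys <- vapply(runs, function(p) partition_key(p$membership), "")
  first_idx <- !duplicated(keys)
  uniq <- runs[first_idx]
  counts <- as.vector(table(factor(keys, levels = keys[first_idx])))
  if (length(uniq) == 1L) {
    best <- uniq[[1L]]
  } else {
    k <- length(uniq)
    sim <- diag(1, k)
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      a <- mclust::adjustedRandIndex(uniq[[i]]$membership, uniq[[j]]$membership)
      sim[i, j] <- a; sim[j, i] <- a
    }
    score <- as.vector(sim %*% counts)
    best <- uniq[[which.max(score)]]
  }
  new_partition(best$membership, best$q_star, n_iterations = n_iter, seed = seed)
}

#' Fine-tune a partition by single-node reassignment
#'
#' Deterministic sweeps over nodes accepting only Q*-increasing single-node
#' moves until a full sweep yields no gain. Output Q* is never below the
#' input Q*; termination is guaranteed because Q* is bounded and every
#' accepted move strictly increases it.
#'
#' @param W Symmetric signed weight matrix.
#' @param partition An `fconn_partition` or membership vector.
#' @return The fine-tuned `fconn_partition`.
#' @export
fine_tune <- function(W, partition) {
  memb <- if (inherits(partition, "fconn_partition")) {
    partition$membership
  } else {
    relabel_membership(partition)
  }
  check_symmetric(W)
  if (length(memb) != nrow(W)) stop("partition must cover every node")
  Wp <- pmax(W, 0); Wn <- -pmin(W, 0)
  vp <- sum(Wp); vn <- sum(Wn)
  if (vp == 0) stop("all-zero positive weights: Q* undefined (v+ = 0)")
  res <- sweep_moves(Wp, Wn, vp, vn, memb = memb, randomize = FALSE)
  out <- new_partition(res$membership, q_star(W, res$membership),
                       n_iterations = if (inherits(partition, "fconn_partition"))
                         partition$n_iterations else 1L,
                       seed = if (inherits(partition, "fconn_partition"))
                         partition$seed else NA_integer_)
  out
}

#' Positive and negative node strengths
#'
#' @param W Symmetric signed weight matrix (diagonal excluded).
#' @return List with numeric vectors `pos` (\eqn{\sum_j w^+_{ij}}) and `neg`
#'   (\eqn{\sum_j w^-_{ij}}), both non-negative.
#' @export
node_strengths <- function(W) {
  check_symmetric(W)
  diag(W) <- 0
  list(pos = rowSums(pmax(W, 0)), neg = rowSums(-pmin(W, 0)))
}

#' Participation coefficient
#'
#' Diversity of a node's sign-specific connection strength across modules:
#' \eqn{P_i = 1 - \sum_s (\kappa_{is} / k_i)^2} where \eqn{\kappa_{is}} is
#' node \eqn{i}'s summed weight (of the chosen sign) to module \eqn{s} and
#' \eqn{k_i} its total. 0 when all edges stay inside the node's own module;
#' at most \eqn{1 - 1/M}. Nodes with zero strength of the chosen sign get 0.
#'
#' @param W Symmetric signed weight matrix.
#' @param membership Module assignment.
#' @param sign `"positive"` or `"negative"`.
#' @return Per-node participation coefficients in \[0, 1\].
#' @export
participation <- function(W, membership, sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  check_symmetric(W)
  diag(W) <- 0
  Ws <- if (sign == "positive") pmax(W, 0) else -pmin(W, 0)
  memb <- relabel_membership(membership)
  K <- t(rowsum(t(Ws), memb, reorder = TRUE))
  k <- rowSums(Ws)
  P <- 1 - rowSums((K / ifelse(k == 0, 1, k))^2)
  P[k == 0] <- 0
  unname(P)
}

#' Within- and between-module strength z-scores
#'
#' For node \eqn{i}, \eqn{\kappa_i} is its summed sign-specific weight to
#' nodes inside (scope `"within"`) or outside (scope `"between"`) its own
#' module; the z-score standardizes \eqn{\kappa_i} against the mean and
#' sample SD of \eqn{\kappa} over the node's module peers. Modules of size 1
#' or with zero SD yield z = 0 (logged via a message).
#'
#' @param W Symmetric signed weight matrix.
#' @param membership Module assignment.
#' @param sign `"positive"` or `"negative"`.
#' @param scope `"within"` or `"between"`.
#' @return Per-node z-scores (mean approximately 0 within each module).
#' @export
module_strength_zscores <- function(W, membership,
                                    sign = c("positive", "negative"),
                                    scope = c("within", "between")) {
  sign <- match.arg(sign)
  scope <- match.arg(scope)
  check_symmetric(W)
  diag(W) <- 0
  Ws <- if (sign == "positive") pmax(W, 0) else -pmin(W, 0)
  memb <- relabel_membership(membership)
  K <- t(rowsum(t(Ws), memb, reorder = TRUE))
  kwithin <- K[cbind(seq_len(nrow(W)), memb)]
  kappa <- if (scope == "within") kwithin else rowSums(Ws) - kwithin
  z <- numeric(length(kappa))
  for (m in sort(unique(memb))) {
    idx <- which(memb == m)
    if (length(idx) < 2L) {
      message(sprintf("module %d has a single node: z set to 0", m))
      z[idx] <- 0
      next
    }
    s <- stats::sd(kappa[idx])
    if (s == 0) {
      message(sprintf("module %d has zero strength SD: z set to 0", m))
      z[idx] <- 0
    } else {
      z[idx] <- (kappa[idx] - mean(kappa[idx])) / s
    }
  }
  z
}

#' The eight nodal graph measures under a fixed partition
#'
#' @param W Symmetric signed weight matrix (typically Fisher-z connectivity).
#' @param membership Module assignment (vector or `fconn_partition`).
#' @return Data frame with columns `node`, `module`, `pos_strength`,
#'   `neg_strength`, `pos_participation`, `neg_participation`,
#'   `within_pos_z`, `within_neg_z`, `between_pos_z`, `between_neg_z`.
#' @export
nodal_metrics <- function(W, membership) {
  if (inherits(membership, "fconn_partition")) membership <- membership$membership
  memb <- relabel_membership(membership)
  s <- node_strengths(W)
  data.frame(
    node = colnames(W) %||% seq_len(nrow(W)),
    module = memb,
    pos_strength = s$pos,
    neg_strength = s$neg,
    pos_participation = participation(W, memb, "positive"),
    neg_participation = participation(W, memb, "negative"),
    within_pos_z = module_strength_zscores(W, memb, "positive", "within"),
    within_neg_z = module_strength_zscores(W, memb, "negative", "within"),
    between_pos_z = module_strength_zscores(W, memb, "positive", "between"),
    between_neg_z = module_strength_zscores(W, memb, "negative", "between"),
    row.names = NULL
  )
}

# all permutations of 1..k (k small)
perms <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- perms(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Match modules between two partitions
#'
#' Optimal one-to-one module correspondence maximizing the total number of
#' shared nodes (assignment problem on the contingency table; exhaustive for
#' up to 8 modules per side, greedy beyond). Surplus modules on either side
#' are left unmatched (`NA`).
#'
#' @param partition_a,partition_b Memberships (vectors or `fconn_partition`s)
#'   over the same node set.
#' @return Data frame `module_a`, `module_b`, `overlap`; attribute
#'   `unmatched_b` lists surplus modules of `partition_b`.
#' @export
match_modules <- function(partition_a, partition_b) {
  a <- if (inherits(partition_a, "fconn_partition")) partition_a$membership else partition_a
  b <- if (inherits(partition_b, "fconn_partition")) partition_b$membership else partition_b
  if (length(a) != length(b)) stop("partitions must cover the same node set")
  labs_a <- sort(unique(a)); labs_b <- sort(unique(b))
  C <- unclass(table(factor(a, labs_a), factor(b, labs_b)))
  Ma <- nrow(C); Mb <- ncol(C)
  k <- max(Ma, Mb)
  Cs <- matrix(0, k, k)
  Cs[seq_len(Ma), seq_len(Mb)] <- C
  if (k <= 8L) {
    P <- perms(k)
    scores <- apply(P, 1, function(p) sum(Cs[cbind(seq_len(k), p)]))
    assign_b <- P[which.max(scores), ]
  } else {
    assign_b <- integer(k)
    Cw <- Cs
    for (step in seq_len(k)) {
      ij <- arrayInd(which.max(Cw), dim(Cw))
      assign_b[ij[1]] <- ij[2]
      Cw[ij[1], ] <- -1
      Cw[, ij[2]] <- -1
    }
  }
  out <- data.frame(
    module_a = labs_a,
    module_b = ifelse(assign_b[seq_len(Ma)] <= Mb,
                      labs_b[pmin(assign_b[seq_len(Ma)], Mb)], NA),
    overlap = vapply(seq_len(Ma), function(i) {
      j <- assign_b[i]
      if (j <= Mb) C[i, j] else 0L
    }, 0L)
  )
  attr(out, "unmatched_b") <- setdiff(labs_b, out$module_b)
  out
}

#' Mean connection strength between modules
#'
#' Mean of the (signed, typically Fisher-z) weights over all node pairs lying
#' in different modules.
#'
#' @param W Symmetric signed weight matrix.
#' @param membership Module assignment with at least 2 modules.
#' @return Scalar mean intermodular strength.
#' @export
intermodular_mean_strength <- function(W, membership) {
  if (inherits(membership, "fconn_partition")) membership <- membership$membership
  check_symmetric(W)
  if (length(unique(membership)) < 2L) {
    stop("intermodular mean strength requires at least 2 modules")
  }
  diff_mod <- outer(membership, membership, "!=")
  mean(W[diff_mod & upper.tri(W)])
}
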