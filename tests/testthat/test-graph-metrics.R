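test_that("Q* closed forms hold", {
  W <- matrix(0, 6, 6)
  W[1:3, 1:3] <- 1; W[4:6, 4:6] <- 1; diag(W) <- 0
  memb <- rep(1:2, each = 3)
  expect_equal(q_star(W, memb), 0.5)
  expect_equal(q_star(W, rep(1, 6)), 0)
  expect_equal(q_star(W, memb), q_star(W, 3 - memb)) # relabel invariance
  expect_error(q_star(matrix(0, 3, 3), c(1, 1, 2)), "v\\+ = 0")
})

test_that("Q* equals the brute-force double-sum oracle on random graphs", {
  for (i in 1:20) {
    n <- sample(5:12, 1)
    W <- rand_signed_matrix(n, 100 + i)
    m <- sample(1:3, n, replace = TRUE)
    expect_equal(q_star(W, m), oracle_q_star(W, m), tolerance = 1e-12)
  }
})

test_that("positive-only Q* equals standard weighted Newman modularity", {
  for (i in 1:10) {
    n <- sample(6:15, 1)
    W <- abs(rand_signed_matrix(n, 200 + i))
    m <- sample(1:4, n, replace = TRUE)
    expect_equal(q_star(W, m), oracle_newman(W, m), tolerance = 1e-12)
  }
})

test_that("Louvain recovers planted structure and disconnected cliques", {
  W <- matrix(0, 8, 8)
  W[1:4, 1:4] <- 1; W[5:8, 5:8] <- 1; diag(W) <- 0
  p <- louvain_signed(W, seed = 5)
  expect_equal(ari(p$membership, rep(1:2, each = 4)), 1)
  expect_equal(p$q_star, 0.5)
  # planted signed blocks at n = 60
  pb <- planted_block_matrix(60, 4, within = 0.4, between = -0.1, seed = 6)
  part <- fine_tune(pb$W, consensus_partition(pb$W, 10, seed = 7))
  expect_gte(ari(part$membership, pb$membership), 0.9)
})

test_that("Louvain is deterministic given the seed", {
  W <- rand_signed_matrix(30, 55)
  expect_identical(louvain_signed(W, seed = 9), louvain_signed(W, seed = 9))
  p <- consensus_partition(W, 5, seed = 3)
  expect_identical(p, consensus_partition(W, 5, seed = 3))
})

test_that("consensus returns the run partition and honours n_iter", {
  W <- matrix(0, 6, 6); W[1:3, 1:3] <- 1; W[4:6, 4:6] <- 1; diag(W) <- 0
  cp <- consensus_partition(W, 10, seed = 1)
  expect_equal(cp$n_iterations, 10L)
  expect_equal(ari(cp$membership, rep(1:2, each = 3)), 1)
  cp1 <- consensus_partition(W, 1, seed = 4)
  expect_equal(cp1$n_iterations, 1L)
  expect_equal(formals(consensus_partition)$n_iter, 1000)
})

test_that("fine-tuning never lowers Q* and repairs a mislabeled node", {
  pb <- planted_block_matrix(20, 2, within = 0.5, between = -0.1,
                             noise_sd = 0, seed = 8)
  wrong <- pb$membership
  wrong[3] <- 3 - wrong[3]
  tuned <- fine_tune(pb$W, wrong)
  expect_equal(ari(tuned$membership, pb$membership), 1)
  expect_gt(tuned$q_star, q_star(pb$W, wrong))
  # already-optimal partition unchanged
  again <- fine_tune(pb$W, tuned)
  expect_equal(again$membership, tuned$membership)
  # Q* never decreases across random starts
  W <- rand_signed_matrix(15, 77)
  for (i in 1:20) {
    set.seed(i)
    m0 <- sample(1:4, 15, replace = TRUE)
    expect_gte(fine_tune(W, m0)$q_star, q_star(W, m0))
  }
})

test_that("node strengths split signed weight and double-count total", {
  W <- rand_signed_matrix(12, 31)
  s <- node_strengths(W)
  expect_true(all(s$pos >= 0) && all(s$neg >= 0))
  expect_equal(sum(s$pos), sum(pmax(W, 0)))
  expect_equal(sum(s$pos), 2 * sum(pmax(W, 0)[upper.tri(W)]))
  # hand 3-node case
  W3 <- matrix(c(0, 2, -1, 2, 0, 3, -1, 3, 0), 3)
  s3 <- node_strengths(W3)
  expect_equal(s3$pos, c(2, 5, 3))
  expect_equal(s3$neg, c(1, 0, 1))
})

test_that("participation matches the oracle and its closed forms", {
  for (i in 1:15) {
    n <- sample(6:18, 1)
    W <- rand_signed_matrix(n, 300 + i)
    m <- sample(1:4, n, replace = TRUE)
    expect_equal(participation(W, m, "positive"),
                 oracle_participation(W, m, "positive"), tolerance = 1e-12)
    expect_equal(participation(W, m, "negative"),
                 oracle_participation(W, m, "negative"), tolerance = 1e-12)
  }
  # all edges inside own module -> P = 0
  W <- matrix(0, 6, 6); W[1:3, 1:3] <- 1; W[4:6, 4:6] <- 1; diag(W) <- 0
  expect_equal(participation(W, rep(1:2, each = 3), "positive"), rep(0, 6))
  # equal strength to each of M modules -> P = 1 - 1/M
  M <- 4
  W2 <- matrix(1, 8, 8); diag(W2) <- 0
  m2 <- rep(1:M, each = 2)
  expect_equal(participation(W2, m2, "positive")[1], 1 - 1 / M,
               tolerance = 0.05) # own module has one fewer peer
})

test_that("module strength z-scores match the oracle and centre per module", {
  for (i in 1:10) {
    n <- 16
    W <- rand_signed_matrix(n, 400 + i)
    m <- rep(1:4, each = 4)
    for (sgn in c("positive", "negative")) for (sc in c("within", "between")) {
      expect_equal(module_strength_zscores(W, m, sgn, sc),
                   oracle_module_z(W, m, sgn, sc), tolerance = 1e-12)
    }
    z <- module_strength_zscores(W, m, "positive", "within")
    for (mm in 1:4) expect_lt(abs(mean(z[m == mm])), 1e-8)
  }
  # within + between strengths recombine to the total per node
  W <- rand_signed_matrix(12, 41)
  m <- rep(1:3, each = 4)
  Wp <- pmax(W, 0); diag(Wp) <- 0
  K <- t(rowsum(t(Wp), m))
  kw <- K[cbind(1:12, m)]
  expect_equal(kw + (rowSums(Wp) - kw), rowSums(Wp))
  # symmetric module -> z identically 0, singleton module logged
  Ws <- matrix(1, 4, 4); diag(Ws) <- 0
  expect_equal(suppressMessages(
    module_strength_zscores(Ws, c(1, 1, 1, 2), "positive", "within")
  )[4], 0)
})

test_that("module matching recovers relabelings and beats enumeration", {
  a <- rep(1:3, times = c(5, 4, 3))
  mm <- match_modules(a, a)
  expect_equal(mm$module_b, mm$module_a)
  # relabeled partition -> inverse relabeling recovered
  relab <- c(2L, 3L, 1L)[a]
  mm2 <- match_modules(a, relab)
  expect_equal(mm2$module_b, c(2L, 3L, 1L))
  expect_equal(sum(mm2$overlap), length(a))
  # 3x4-module constructed case vs exhaustive assignment search
  set.seed(50)
  pa <- sample(1:3, 40, replace = TRUE)
  pb <- sample(1:4, 40, replace = TRUE)
  mm3 <- match_modules(pa, pb)
  C <- unclass(table(pa, pb))
  best <- 0
  for (p1 in 1:4) for (p2 in setdiff(1:4, p1)) for (p3 in setdiff(1:4, c(p1, p2))) {
    best <- max(best, C[1, p1] + C[2, p2] + C[3, p3])
  }
  expect_equal(sum(mm3$overlap), best)
  expect_error(match_modules(a, a[1:5]), "same node set")
})

test_that("intermodular mean strength reduces to the block value", {
  W <- matrix(-0.2, 8, 8)
  W[1:4, 1:4] <- 0.5; W[5:8, 5:8] <- 0.5; diag(W) <- 0
  m <- rep(1:2, each = 4)
  expect_equal(intermodular_mean_strength(W, m), -0.2)
  # hand 4-node case: two modules of two
  W4 <- matrix(0, 4, 4)
  W4[1, 3] <- 1; W4[1, 4] <- 2; W4[2, 3] <- 3; W4[2, 4] <- 6
  W4 <- W4 + t(W4)
  expect_equal(intermodular_mean_strength(W4, c(1, 1, 2, 2)), 3)
  expect_error(intermodular_mean_strength(W4, rep(1, 4)), "2 modules")
  # complement identity: within and between recombine to the global mean
  W <- rand_signed_matrix(10, 61)
  m <- rep(1:2, each = 5)
  same <- outer(m, m, "==") & upper.tri(W)
  diffm <- outer(m, m, "!=") & upper.tri(W)
  total <- mean(W[upper.tri(W)])
  recomb <- (sum(W[same]) + sum(W[diffm])) / (sum(same) + sum(diffm))
  expect_equal(recomb, total, tolerance = 1e-12)
})

test_that("nodal metrics table carries the eight measures coherently", {
  pb <- planted_block_matrix(24, 3, seed = 70)
  nm <- suppressMessages(nodal_metrics(pb$W, pb$membership))
  expect_equal(nrow(nm), 24L)
  expect_true(all(c("pos_strength", "neg_strength", "pos_participation",
                    "neg_participation", "within_pos_z", "within_neg_z",
                    "between_pos_z", "between_neg_z") %in% names(nm)))
  expect_true(all(nm$pos_participation >= 0 & nm$pos_participation <= 1))
  for (mm in 1:3) {
    expect_lt(abs(mean(nm$within_pos_z[nm$module == mm])), 1e-8)
  }
})
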