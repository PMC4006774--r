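test_that("identical configuration and seed reproduce the cohort bitwise", {
  cfg <- small_cfg(42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(small_cfg(42))
  expect_identical(a, b)
})

test_that("configuration validation names the offending field", {
  expect_error(cohort_config(n_modules = 1), "n_modules")
  expect_error(cohort_config(n_rois = 5, n_modules = 4), "n_rois")
  expect_error(cohort_config(motion_spike_prob = 1.5), "motion_spike_prob")
  expect_error(cohort_config(lambda_within = 0.9), "variance shares")
  expect_error(cohort_config(pcc_node_index = 1000), "pcc_node_index")
})

test_that("pure-noise null configuration yields near-zero correlations", {
  cfg <- cohort_config(
    n_subjects = 4, n_rois = 20, n_modules = 2,
    n_frames_range = c(400L, 400L), lambda_within = 0,
    lambda_between_base = 0, lambda_between_slope_per_week = 0,
    pcc_neg_slope_per_week = 0, longrange_effect = 0,
    nuisance_loading_range = c(0, 0), seed = 9
  )
  coh <- generate_cohort(cfg)
  mean_abs_r <- mean(sapply(coh, function(s) {
    r <- cor(s$roi_timeseries)
    mean(abs(r[upper.tri(r)]))
  }))
  # sampling scale of |r| at T = 400 is ~ sqrt(2/(pi T)) ~ 0.04
  expect_lt(mean_abs_r, 0.1)
})

test_that("within-module correlations exceed between-module in every subject", {
  coh <- default_cohort()
  ok <- vapply(coh, function(s) {
    r <- cor(s$roi_timeseries)
    m <- s$planted_partition
    same <- outer(m, m, "==") & upper.tri(r)
    diffm <- outer(m, m, "!=") & upper.tri(r)
    mean(r[same]) > mean(r[diffm])
  }, TRUE)
  expect_true(all(ok))
})

test_that("subject structure is internally consistent", {
  coh <- generate_cohort(small_cfg(3))
  cfg <- attr(coh, "config")
  for (s in coh) {
    expect_equal(nrow(s$roi_timeseries), nrow(s$motion))
    expect_equal(length(s$planted_partition), cfg$n_rois)
    expect_setequal(unique(s$planted_partition), seq_len(cfg$n_modules))
    expect_true(s$ga_weeks >= cfg$ga_range_weeks[1] &&
                  s$ga_weeks <= cfg$ga_range_weeks[2])
  }
  # hub node is never in the long-range set
  expect_false(cfg$pcc_node_index %in% attr(coh, "longrange_set"))
})

test_that("motion traces censor as designed across spike regimes", {
  tr0 <- generate_motion_trace(200, 0, seed = 2)
  fd0 <- framewise_displacement(tr0)
  expect_true(all(fd0$fd_trans < 1.5))
  tr1 <- generate_motion_trace(100, 1, seed = 2)
  mask1 <- censor_frames(framewise_displacement(tr1)$fd_trans)
  expect_lte(sum(mask1), 1L) # only the conventional first frame survives
  expect_true(exclude_subject(mask1))
  # spike_prob = 0.1 over 300 frames: censored count within the binomial
  # 99% interval around 30 (each repositioning censors exactly one frame)
  tr <- generate_motion_trace(300, 0.1, seed = 7)
  censored <- sum(!censor_frames(framewise_displacement(tr)$fd_trans))
  bounds <- qbinom(c(0.005, 0.995), 300, 0.1)
  expect_gte(censored, bounds[1])
  expect_lte(censored, bounds[2])
  expect_error(generate_motion_trace(1, 0.1), ">= 2")
})

test_that("exclusion rate increases with the spike probability", {
  rate <- vapply(c(0.05, 0.3, 0.6), function(p) {
    excl <- vapply(1:30, function(i) {
      tr <- generate_motion_trace(150, p, seed = 1000 + i)
      exclude_subject(censor_frames(framewise_displacement(tr)$fd_trans))
    }, TRUE)
    mean(excl)
  }, 0)
  expect_true(rate[1] <= rate[2] && rate[2] <= rate[3])
  expect_lt(rate[1], rate[3])
})

test_that("voxel grid fixture plants contiguous parcels sharing a factor", {
  g <- generate_voxel_grid(c(10, 10, 6), 12, n_frames = 100, seed = 3)
  expect_equal(length(g$labels), 600L)
  expect_setequal(unique(g$labels), 1:12)
  # flood-fill audit of planted contiguity
  rs <- build_roi_set(g$labels, g$coords)
  audited <- drop_discontiguous(rs)
  expect_equal(length(audited$roi_ids), 12L)
  # single parcel case
  g1 <- generate_voxel_grid(c(3, 3, 2), 1, n_frames = 10, seed = 1)
  expect_true(all(g1$labels == 1L))
  expect_error(generate_voxel_grid(c(0, 3, 3), 2, 10), "positive extents")
  expect_error(generate_voxel_grid(c(2, 2, 1), 10, 10), "<= the voxel count")
})

test_that("raising the between-module age slope lowers the GA-Q* correlation", {
  cors <- vapply(c(0, 0.004, 0.008), function(slope) {
    cfg <- cohort_config(
      n_subjects = 16, n_rois = 24, n_modules = 3,
      n_frames_range = c(150L, 200L), longrange_set_size = 5,
      lambda_between_slope_per_week = slope,
      pcc_neg_slope_per_week = 0, longrange_effect = 0,
      motion_spike_prob = 0, motion_spike_prob_age_slope = 0, seed = 21
    )
    coh <- generate_cohort(cfg)
    q <- vapply(seq_along(coh), function(i) {
      z <- fisher_z(pairwise_correlation(coh[[i]]$roi_timeseries))
      fine_tune(z, consensus_partition(z, 8, seed = 31 + i))$q_star
    }, 0)
    cor(q, vapply(coh, `[[`, 0, "ga_weeks"))
  }, 0)
  expect_true(cors[1] > cors[2] && cors[2] > cors[3])
})

test_that("cohort files round-trip through the plain-text writers", {
  coh <- generate_cohort(cohort_config(
    n_subjects = 5, n_rois = 12, n_modules = 2,
    n_frames_range = c(100L, 120L), longrange_set_size = 4, seed = 8
  ))
  dir <- tempfile("cohort_")
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(length(back), 5L)
  expect_equal(vapply(back, `[[`, 0, "ga_weeks"),
               vapply(coh, `[[`, 0, "ga_weeks"), tolerance = 1e-6)
  expect_equal(unclass(back[[2]]$motion), unclass(coh[[2]]$motion),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(dim(back[[1]]$roi_timeseries), dim(coh[[1]]$roi_timeseries))
})
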