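#' Configuration for the synthetic fetal cohort generator
#'
#' Defaults emulate the study conditions the pipeline was designed for: a
#' cohort of fetuses spanning gestational ages (GA) 19--39 weeks scanned at
#' TR = 2 s for 180--463 frames, with low-frequency (< 0.1 Hz) modular BOLD
#' structure, shared nuisance (white-matter/CSF-like) components, substantial
#' motion that decreases with GA, and three planted developmental effects:
#' (1) between-module coupling rises with GA (so signed modularity Q* falls),
#' (2) one designated hub node's loading on every other module's factor grows
#' more negative with GA, and (3) a mutually distant ROI subset gains extra
#' shared signal with GA (long-range strengthening).
#'
#' Per node \eqn{i} in module \eqn{m(i)} the generated signal is
#' \deqn{x_i(t) = \sqrt{\lambda_w} f_{m(i)}(t) + \sqrt{\lambda_b(GA)} g(t) +
#'   \textrm{(hub/long-range/nuisance loadings)} + \sigma_i \epsilon_i(t)}
#' with all shared factors low-pass filtered below 0.1 Hz and \eqn{\sigma_i}
#' chosen so each node has unit variance.
#'
#' @param n_subjects Number of subjects.
#' @param n_rois Number of ROIs (network nodes).
#' @param n_modules Number of planted modules (>= 2, `n_rois >= 2 * n_modules`).
#' @param n_frames_range Integer pair: per-subject frame count is drawn
#'   uniformly from this range.
#' @param tr_seconds Repetition time in seconds.
#' @param ga_range_weeks Gestational-age range (weeks) spanned by the cohort.
#' @param lambda_within Variance share of the module factor per node.
#' @param lambda_between_base Between-module (global factor) variance share at
#'   the youngest GA.
#' @param lambda_between_slope_per_week Increase in the between-module share
#'   per GA week; drives the modularity decline.
#' @param pcc_node_index Index of the planted anticorrelating hub node.
#' @param pcc_neg_slope_per_week Growth per GA week of the hub's negative
#'   loading amplitude on each other module's factor.
#' @param longrange_effect Variance share, at the oldest GA, of the extra
#'   factor shared by the designated mutually distant ROI subset.
#' @param longrange_set_size Number of ROIs in the distant subset.
#' @param motion_spike_prob Per-frame probability of a motion spike at the
#'   midpoint GA.
#' @param motion_spike_prob_age_slope Change in spike probability per GA week
#'   (negative: younger fetuses move more).
#' @param nuisance_k Number of shared confound (noise-tissue) factors.
#' @param nuisance_loading_range Amplitude range for per-node confound
#'   loadings (random sign).
#' @param seed Master seed; the cohort is bitwise reproducible given the
#'   configuration.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 30,
                          n_rois = 60,
                          n_modules = 4,
                          n_frames_range = c(180L, 463L),
                          tr_seconds = 2,
                          ga_range_weeks = c(19, 39),
                          lambda_within = 0.25,
                          lambda_between_base = 0.02,
                          lambda_between_slope_per_week = 0.005,
                          pcc_node_index = 1,
                          pcc_neg_slope_per_week = 0.02,
                          longrange_effect = 0.08,
                          longrange_set_size = 8,
                          motion_spike_prob = 0.4,
                          motion_spike_prob_age_slope = -0.01,
                          nuisance_k = 3,
                          nuisance_loading_range = c(0.05, 0.2),
                          seed = 1) {
  cfg <- list(
    n_subjects = n_subjects, n_rois = n_rois, n_modules = n_modules,
    n_frames_range = n_frames_range, tr_seconds = tr_seconds,
    ga_range_weeks = ga_range_weeks, lambda_within = lambda_within,
    lambda_between_base = lambda_between_base,
    lambda_between_slope_per_week = lambda_between_slope_per_week,
    pcc_node_index = pcc_node_index,
    pcc_neg_slope_per_week = pcc_neg_slope_per_week,
    longrange_effect = longrange_effect,
    longrange_set_size = longrange_set_size,
    motion_spike_prob = motion_spike_prob,
    motion_spike_prob_age_slope = motion_spike_prob_age_slope,
    nuisance_k = nuisance_k,
    nuisance_loading_range = nuisance_loading_range,
    seed = seed
  )
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  fail <- function(field, msg) {
    stop(sprintf("invalid cohort configuration: `%s` %s", field, msg), call. = FALSE)
  }
  if (!is_count(cfg$n_subjects)) fail("n_subjects", "must be a positive integer")
  if (!is_count(cfg$n_rois)) fail("n_rois", "must be a positive integer")
  if (!is_count(cfg$n_modules) || cfg$n_modules < 2) {
    fail("n_modules", "must be an integer >= 2")
  }
  if (cfg$n_rois < 2 * cfg$n_modules) {
    fail("n_rois", "must be at least 2 * n_modules")
  }
  if (length(cfg$n_frames_range) != 2L || any(cfg$n_frames_range < 2) ||
      cfg$n_frames_range[1] > cfg$n_frames_range[2]) {
    fail("n_frames_range", "must be an increasing pair of counts >= 2")
  }
  if (!is.numeric(cfg$tr_seconds) || cfg$tr_seconds <= 0) {
    fail("tr_seconds", "must be positive")
  }
  if (length(cfg$ga_range_weeks) != 2L ||
      cfg$ga_range_weeks[1] >= cfg$ga_range_weeks[2]) {
    fail("ga_range_weeks", "must be an increasing pair")
  }
  if (!is_prob(cfg$lambda_within)) fail("lambda_within", "must be in [0, 1]")
  if (!is_prob(cfg$lambda_between_base)) {
    fail("lambda_between_base", "must be in [0, 1]")
  }
  if (!is.numeric(cfg$lambda_between_slope_per_week)) {
    fail("lambda_between_slope_per_week", "must be numeric")
  }
  if (!is_count(cfg$pcc_node_index) || cfg$pcc_node_index > cfg$n_rois) {
    fail("pcc_node_index", "must be a node index within 1..n_rois")
  }
  if (!is.numeric(cfg$pcc_neg_slope_per_week) || cfg$pcc_neg_slope_per_week < 0) {
    fail("pcc_neg_slope_per_week", "must be a non-negative number")
  }
  if (!is.numeric(cfg$longrange_effect) || cfg$longrange_effect < 0 ||
      cfg$longrange_effect > 1) {
    fail("longrange_effect", "must be in [0, 1]")
  }
  if (!is_count(cfg$longrange_set_size) || cfg$longrange_set_size > cfg$n_rois) {
    fail("longrange_set_size", "must be a count <= n_rois")
  }
  ga_span <- diff(cfg$ga_range_weeks)
  p_lo <- cfg$motion_spike_prob + cfg$motion_spike_prob_age_slope * (-ga_span / 2)
  p_hi <- cfg$motion_spike_prob + cfg$motion_spike_prob_age_slope * (ga_span / 2)
  if (!is_prob(cfg$motion_spike_prob) || min(p_lo, p_hi) < 0 || max(p_lo, p_hi) > 1) {
    fail("motion_spike_prob", "must stay in [0, 1] across the GA range")
  }
  if (!is_count(cfg$nuisance_k)) fail("nuisance_k", "must be a positive integer")
  if (length(cfg$nuisance_loading_range) != 2L ||
      any(cfg$nuisance_loading_range < 0) ||
      cfg$nuisance_loading_range[1] > cfg$nuisance_loading_range[2]) {
    fail("nuisance_loading_range", "must be an increasing non-negative pair")
  }
  # Worst-case (oldest GA) variance share must leave room for node-unique
  # noise. The hub node never belongs to the distant long-range set, so the
  # worst case carries the larger of the two planted loadings, not both.
  lb_max <- cfg$lambda_between_base +
    max(0, cfg$lambda_between_slope_per_week) * ga_span
  eta_max <- cfg$pcc_neg_slope_per_week * ga_span
  worst <- cfg$lambda_within + lb_max +
    max((cfg$n_modules - 1) * eta_max^2, cfg$longrange_effect) +
    cfg$nuisance_k * max(cfg$nuisance_loading_range)^2
  if (worst >= 1) {
    fail("lambda_within", sprintf(
      "variance shares sum to %.3f >= 1 for the worst-case node; reduce effect sizes",
      worst
    ))
  }
  invisible(cfg)
}

# Low-pass filtered unit-variance Gaussian series. A centred moving-average
# (boxcar) kernel of length L = round(1 / (2 * TR * f_c)) has its first
# spectral null at f_c; with TR = 2 s and f_c = 0.1 Hz this is a 5-frame
# boxcar, confining shared signal below ~0.1 Hz.
lowpass_series <- function(n, tr_seconds = 2, cutoff_hz = 0.1) {
  len <- max(2L, round(1 / (2 * tr_seconds * cutoff_hz)))
  x <- stats::rnorm(n + len - 1L)
  sm <- as.numeric(stats::filter(x, rep(1 / len, len), sides = 1))
  sm <- sm[len:(n + len - 1L)]
  (sm - mean(sm)) / stats::sd(sm)
}

#' Generate a synthetic rigid-body motion trace
#'
#' A smooth random-walk baseline (well below the 1.5 mm censoring threshold)
#' plus Bernoulli repositioning steps: at a spike frame the fetus jumps to a
#' new position (per-axis translational step of 2--6 mm, random sign) and
#' stays there, so exactly that frame's framewise displacement exceeds the
#' threshold and frame censoring is exercised.
#'
#' @param n_frames Number of frames (>= 2).
#' @param spike_prob Per-frame spike probability in \[0, 1\].
#' @param seed RNG seed.
#' @return A [motion_trace()].
#' @export
generate_motion_trace <- function(n_frames, spike_prob, seed = 1) {
  if (!is_count(n_frames) || n_frames < 2) {
    stop("`n_frames` must be an integer >= 2 (derivatives undefined otherwise)")
  }
  if (!is_prob(spike_prob)) stop("`spike_prob` must be in [0, 1]")
  with_seed(seed, {
    trans <- apply(matrix(stats::rnorm(n_frames * 3, sd = 0.03), ncol = 3), 2, cumsum)
    rot <- apply(matrix(stats::rnorm(n_frames * 3, sd = 0.002), ncol = 3), 2, cumsum)
    spikes <- stats::runif(n_frames) < spike_prob
    spikes[1L] <- FALSE # first frame has FD 0 by convention
    if (any(spikes)) {
      idx <- which(spikes)
      step_t <- matrix(0, n_frames, 3)
      step_r <- matrix(0, n_frames, 3)
      sgn <- matrix(sample(c(-1, 1), length(idx) * 3, replace = TRUE), ncol = 3)
      step_t[idx, ] <- matrix(stats::runif(length(idx) * 3, 2, 6), ncol = 3) * sgn
      step_r[idx, ] <- matrix(stats::runif(length(idx) * 3, 0.05, 0.2), ncol = 3) * sgn
      trans <- trans + apply(step_t, 2, cumsum)
      rot <- rot + apply(step_r, 2, cumsum)
    }
    motion_trace(cbind(trans, rot))
  })
}

#' Generate a voxel grid with planted contiguous parcels
#'
#' Builds ground truth for the parcellation module: `n_parcels` spatially
#' contiguous parcels grown from seeded multi-source breadth-first search on
#' the 6-connected grid, each sharing a low-frequency factor.
#'
#' @param shape Integer triple of grid extents.
#' @param n_parcels Number of parcels (<= voxel count).
#' @param n_frames Frames per voxel timeseries.
#' @param seed RNG seed.
#' @return List with `timeseries` (frames x V), `labels` (length V, 1-based
#'   parcel ids), `coords` (V x 3, 1-based grid coordinates), `shape`.
#' @export
generate_voxel_grid <- function(shape, n_parcels, n_frames, seed = 1) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) {
    stop("`shape` must be three positive extents")
  }
  nv <- prod(shape)
  if (!is_count(n_parcels) || n_parcels > nv) {
    stop("`n_parcels` must be a count <= the voxel count")
  }
  coords <- as.matrix(expand.grid(
    x = seq_len(shape[1]), y = seq_len(shape[2]), z = seq_len(shape[3])
  ))
  with_seed(seed, {
    seeds <- sample.int(nv, n_parcels)
    labels <- integer(nv)
    labels[seeds] <- seq_len(n_parcels)
    adj <- grid_neighbors(shape)
    frontier <- seeds
    while (length(frontier) > 0L) {
      nxt <- integer(0)
      for (v in sample(frontier)) { # randomized order -> irregular boundaries
        for (u in adj[[v]]) {
          if (labels[u] == 0L) {
            labels[u] <- labels[v]
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
    }
    factors <- sapply(seq_len(n_parcels), function(i) lowpass_series(n_frames))
    ts <- sqrt(0.6) * factors[, labels, drop = FALSE] +
      sqrt(0.4) * matrix(stats::rnorm(n_frames * nv), nrow = n_frames)
    list(timeseries = ts, labels = labels, coords = coords, shape = shape)
  })
}

# 6-connectivity neighbor lists for a 3D grid.
grid_neighbors <- function(shape) {
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  idx <- function(x, y, z) x + (y - 1L) * nx + (z - 1L) * nx * ny
  nv <- nx * ny * nz
  out <- vector("list", nv)
  for (z in seq_len(nz)) for (y in seq_len(ny)) for (x in seq_len(nx)) {
    v <- idx(x, y, z)
    nb <- integer(0)
    if (x > 1L) nb <- c(nb, idx(x - 1L, y, z))
    if (x < nx) nb <- c(nb, idx(x + 1L, y, z))
    if (y > 1L) nb <- c(nb, idx(x, y - 1L, z))
    if (y < ny) nb <- c(nb, idx(x, y + 1L, z))
    if (z > 1L) nb <- c(nb, idx(x, y, z - 1L))
    if (z < nz) nb <- c(nb, idx(x, y, z + 1L))
    out[[v]] <- nb
  }
  out
}

# Sample ROI centroids uniformly inside a 120 x 90 x 80 mm ellipsoid
# (half-axes 60/45/40), roughly a late-gestation cranial volume.
sample_centroids <- function(n) {
  out <- matrix(NA_real_, 0, 3)
  half <- c(60, 45, 40)
  while (nrow(out) < n) {
    cand <- cbind(
      stats::runif(2 * n, -half[1], half[1]),
      stats::runif(2 * n, -half[2], half[2]),
      stats::runif(2 * n, -half[3], half[3])
    )
    keep <- rowSums(sweep(cand, 2, half, "/")^2) <= 1
    out <- rbind(out, cand[keep, , drop = FALSE])
  }
  out <- out[seq_len(n), , drop = FALSE]
  colnames(out) <- c("x_mm", "y_mm", "z_mm")
  out
}

# Greedy max-min selection of a mutually distant subset of centroids,
# excluding `exclude` indices.
pick_distant_set <- function(centroids, size, exclude = integer(0)) {
  d <- as.matrix(stats::dist(centroids))
  avail <- setdiff(seq_len(nrow(centroids)), exclude)
  first <- avail[which.max(apply(d[avail, avail, drop = FALSE], 1, max))]
  set <- first
  while (length(set) < size) {
    rest <- setdiff(avail, set)
    mind <- apply(d[rest, set, drop = FALSE], 1, min)
    set <- c(set, rest[which.max(mind)])
  }
  sort(set)
}

#' Generate a synthetic fetal cohort
#'
#' Draws per-subject gestational ages, frame counts, motion traces,
#' noise-tissue surrogates, and modular low-frequency ROI timeseries with the
#' planted developmental effects described in [cohort_config()]. Identical
#' configuration (including seed) reproduces the cohort bitwise.
#'
#' @param config A [cohort_config()].
#' @return List of class `synthetic_cohort`: one `synthetic_subject` per
#'   subject (fields `subject_id`, `ga_weeks`, `roi_timeseries`, `motion`,
#'   `noise_tissue_timeseries`, `planted_partition`, `roi_centroids`), with
#'   attributes `config`, `roi_centroids`, `planted_partition`,
#'   `longrange_set`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  validate_cohort_config(config)
  cfg <- config
  n <- cfg$n_rois
  M <- cfg$n_modules
  ga_min <- cfg$ga_range_weeks[1]
  ga_mid <- mean(cfg$ga_range_weeks)
  ga_span <- diff(cfg$ga_range_weeks)

  with_seed(cfg$seed, {
    # cohort-level structure shared by all subjects
    centroids <- sample_centroids(n)
    membership <- rep(seq_len(M), length.out = n)
    membership <- sort(membership) # contiguous index blocks per module
    hub <- cfg$pcc_node_index
    lr_set <- pick_distant_set(centroids, cfg$longrange_set_size, exclude = hub)
    nuis_load <- matrix(
      stats::runif(n * cfg$nuisance_k, cfg$nuisance_loading_range[1],
                   cfg$nuisance_loading_range[2]) *
        sample(c(-1, 1), n * cfg$nuisance_k, replace = TRUE),
      nrow = n
    )
    ga <- sort(stats::runif(cfg$n_subjects, cfg$ga_range_weeks[1],
                            cfg$ga_range_weeks[2]))
    n_frames <- cfg$n_frames_range[1] - 1L +
      sample.int(diff(cfg$n_frames_range) + 1L, cfg$n_subjects, replace = TRUE)
    subj_seeds <- derive_seeds(sample.int(.Machine$integer.max - 1L, 1L),
                               cfg$n_subjects)

    subjects <- vector("list", cfg$n_subjects)
    for (s in seq_len(cfg$n_subjects)) {
      subjects[[s]] <- with_seed(subj_seeds[s], {
        Tn <- n_frames[s]
        lam_b <- cfg$lambda_between_base +
          cfg$lambda_between_slope_per_week * (ga[s] - ga_min)
        eta <- cfg$pcc_neg_slope_per_week * (ga[s] - ga_min)
        lam_lr <- cfg$longrange_effect * (ga[s] - ga_min) / ga_span
        spike_p <- min(1, max(0, cfg$motion_spike_prob +
          cfg$motion_spike_prob_age_slope * (ga[s] - ga_mid)))

        # shared low-frequency factors
        f_mod <- sapply(seq_len(M), function(i)
          lowpass_series(Tn, cfg$tr_seconds))
        g <- lowpass_series(Tn, cfg$tr_seconds)
        h <- lowpass_series(Tn, cfg$tr_seconds)
        u <- sapply(seq_len(cfg$nuisance_k), function(i)
          lowpass_series(Tn, cfg$tr_seconds))
        u <- matrix(u, nrow = Tn)

        # node loading matrix onto (M module factors, g, h, k nuisance)
        L <- matrix(0, n, M + 2 + cfg$nuisance_k)
        L[cbind(seq_len(n), membership)] <- sqrt(cfg$lambda_within)
        L[, M + 1] <- sqrt(lam_b)
        L[lr_set, M + 2] <- sqrt(lam_lr)
        L[, (M + 3):(M + 2 + cfg$nuisance_k)] <- nuis_load
        # planted hub: negative loading on every other module's factor
        other <- setdiff(seq_len(M), membership[hub])
        L[hub, other] <- -eta

        shares <- rowSums(L^2)
        sigma <- sqrt(pmax(0, 1 - shares))
        F_all <- cbind(f_mod, g, h, u)
        X <- F_all %*% t(L) +
          matrix(stats::rnorm(Tn * n), nrow = Tn) %*% diag(sigma)
        colnames(X) <- sprintf("roi_%03d", seq_len(n))

        # noise-tissue surrogates: each confound factor observed through a
        # few noisy "voxel average" channels per tissue class
        noise_ts <- do.call(cbind, lapply(seq_len(cfg$nuisance_k), function(i) {
          sapply(1:2, function(j) u[, i] + 0.3 * stats::rnorm(Tn))
        }))
        colnames(noise_ts) <- sprintf("tissue_%02d", seq_len(ncol(noise_ts)))

        motion <- generate_motion_trace(Tn, spike_p,
                                        seed = subj_seeds[s] %% 100000L + 1L)

        structure(list(
          subject_id = sprintf("sub-%02d", s),
          ga_weeks = ga[s],
          roi_timeseries = X,
          motion = motion,
          noise_tissue_timeseries = noise_ts,
          planted_partition = membership,
          roi_centroids = centroids
        ), class = "synthetic_subject")
      })
    }
    structure(subjects,
      class = "synthetic_cohort",
      config = cfg,
      roi_centroids = centroids,
      planted_partition = membership,
      longrange_set = lr_set
    )
  })
}

#' Write a synthetic cohort to plain-text files
#'
#' Writes, per subject, the ROI timeseries and noise-tissue TSVs, a 6-column
#' whitespace motion parameter file (`rp_<id>.txt`, translations in mm then
#' rotations in radians), plus cohort-level centroid TSV, metadata CSV
#' (`subject_id`, `ga_weeks`) and planted-truth JSON.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wr <- function(x, path, ...) {
    utils::write.table(x, path, ...)
    files <<- c(files, path)
  }
  for (s in cohort) {
    id <- s$subject_id
    wr(s$roi_timeseries, file.path(dir, paste0(id, "_timeseries.tsv")),
       sep = "\t", quote = FALSE, row.names = FALSE)
    wr(s$noise_tissue_timeseries, file.path(dir, paste0(id, "_noise.tsv")),
       sep = "\t", quote = FALSE, row.names = FALSE)
    wr(format(unclass(s$motion), digits = 10),
       file.path(dir, paste0("rp_", id, ".txt")),
       sep = " ", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  cen <- attr(cohort, "roi_centroids")
  wr(data.frame(roi_id = sprintf("roi_%03d", seq_len(nrow(cen))), cen),
     file.path(dir, "roi_centroids.tsv"),
     sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(
    subject_id = vapply(cohort, `[[`, "", "subject_id"),
    ga_weeks = vapply(cohort, `[[`, 0, "ga_weeks")
  )
  p <- file.path(dir, "metadata.csv")
  utils::write.csv(meta, p, row.names = FALSE)
  files <- c(files, p)
  truth <- list(
    planted_partition = attr(cohort, "planted_partition"),
    longrange_set = attr(cohort, "longrange_set"),
    hub_node = attr(cohort, "config")$pcc_node_index,
    config = unclass(attr(cohort, "config"))
  )
  p <- file.path(dir, "planted_truth.json")
  jsonlite::write_json(truth, p, auto_unbox = TRUE, digits = NA)
  files <- c(files, p)
  invisible(files)
}
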