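#' Analyze a cohort end to end
#'
#' In-memory driver for the full analysis: motion QC and frame censoring,
#' subject exclusion, aCompCor-style nuisance regression, Fisher-z
#' connectivity, consensus signed-modularity partitioning with fine-tuning,
#' nodal metrics with robust age regression and BH-FDR, distance-strength
#' profiles, and the global GA correlations (partial on any flagged movement
#' covariate).
#'
#' @param cohort A `synthetic_cohort` (or any list of subjects with the same
#'   fields).
#' @param fd_threshold_mm Censoring threshold on translational FD (mm).
#' @param min_frames Minimum retained frames to keep a subject.
#' @param k_components Number of noise-tissue principal components.
#' @param n_consensus Louvain restarts per subject for the consensus
#'   partition (default 1000).
#' @param extreme_pct Distance-tail percentage for the length analysis.
#' @param cut_weeks Median-age split point (weeks).
#' @param fdr_q FDR level for the nodal family corrections.
#' @param alpha_length Alpha for the extreme-connection group tests.
#' @param seed Master seed for all stochastic stages.
#' @return List of class `fconn_analysis`; see Details in the vignette.
#' @export
analyze_cohort <- function(cohort,
                           fd_threshold_mm = 1.5,
                           min_frames = 90,
                           k_components = 3,
                           n_consensus = 1000,
                           extreme_pct = 5,
                           cut_weeks = 31,
                           fdr_q = 0.05,
                           alpha_length = 0.025,
                           seed = 1) {
  n_sub <- length(cohort)
  qc <- vector("list", n_sub)
  masks <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    sub <- cohort[[s]]
    fd <- framewise_displacement(sub$motion)
    mask <- censor_frames(fd$fd_trans, fd_threshold_mm)
    sm <- motion_summary(sub$motion, mask)
    sm$subject_id <- sub$subject_id
    sm$ga_weeks <- sub$ga_weeks
    sm$excluded <- exclude_subject(mask, min_frames)
    qc[[s]] <- sm
    masks[[s]] <- mask
  }
  qc <- do.call(rbind, qc)
  keep <- which(!qc$excluded)
  if (length(keep) < 5L) stop("fewer than 5 subjects retained after exclusion")
  ga <- qc$ga_weeks[keep]
  groups <- split_median_age(ga, cut_weeks)

  move_tests <- movement_group_test(qc[keep, ], groups)
  flagged <- move_tests$parameter[move_tests$flagged]
  covariates <- if (length(flagged) > 0L) {
    as.matrix(qc[keep, flagged, drop = FALSE])
  } else {
    NULL
  }

  sub_seeds <- derive_seeds(seed, length(keep))
  conns <- vector("list", length(keep))
  parts <- vector("list", length(keep))
  q_vals <- numeric(length(keep))
  intermod <- numeric(length(keep))
  metrics <- vector("list", length(keep))
  for (ii in seq_along(keep)) {
    s <- keep[ii]
    sub <- cohort[[s]]
    mask <- masks[[s]]
    comps <- extract_noise_components(
      sub$noise_tissue_timeseries[mask, , drop = FALSE], k_components
    )
    X <- build_regressors(sub$motion, comps, mask)
    resid <- regress_out(sub$roi_timeseries[mask, , drop = FALSE], X)
    conn <- build_connectivity(resid, subject_id = sub$subject_id)
    part <- fine_tune(conn$z, consensus_partition(conn$z, n_consensus,
                                                  seed = sub_seeds[ii]))
    conns[[ii]] <- conn
    parts[[ii]] <- part
    q_vals[ii] <- part$q_star
    intermod[ii] <- intermodular_mean_strength(conn$z, part)
    m <- nodal_metrics(conn$z, part)
    m$subject_id <- sub$subject_id
    metrics[[ii]] <- m
  }

  global <- rbind(
    ga_correlation(q_vals, ga, covariates, effect = "q_star_vs_ga"),
    ga_correlation(intermod, ga, covariates,
                   effect = "intermodular_strength_vs_ga")
  )

  measure_cols <- c("pos_strength", "neg_strength", "pos_participation",
                    "neg_participation", "within_pos_z", "within_neg_z",
                    "between_pos_z", "between_neg_z")
  n_nodes <- nrow(metrics[[1L]])
  nodal <- list()
  for (mc in measure_cols) {
    vals <- sapply(metrics, function(m) m[[mc]]) # nodes x subjects
    rows <- lapply(seq_len(n_nodes), function(j) {
      r <- robust_age_regression(vals[j, ], ga, effect = mc)
      r$node <- j
      r
    })
    fam <- do.call(rbind, rows)
    fc <- fdr_correct(fam$p, fdr_q)
    fam$q <- fc$q_values
    fam$reject <- fc$reject
    nodal[[mc]] <- fam
  }
  nodal <- do.call(rbind, nodal)
  rownames(nodal) <- NULL

  hub_rows <- nodal[nodal$effect == "between_neg_z" & nodal$reject &
                      nodal$t > 0, , drop = FALSE]
  followup <- NULL
  hub_node <- NA_integer_
  if (nrow(hub_rows) > 0L) {
    hub_node <- hub_rows$node[which.max(hub_rows$t)]
    followup <- pcc_followup(lapply(conns, `[[`, "z"), parts, hub_node, ga)
  }

  centroids <- cohort[[keep[1L]]]$roi_centroids
  dist_tbl <- NULL
  extremes <- NULL
  range_row <- NULL
  if (!is.null(centroids)) {
    D <- roi_distances(centroids)
    bins <- lapply(conns, function(cn) strength_length_bins(cn$r, D))
    ext <- lapply(conns, function(cn) extreme_connection_strength(cn$r, D,
                                                                  extreme_pct))
    rng <- vapply(conns, function(cn) correlation_range_summary(cn$r)$range, 0)
    long_r <- vapply(ext, `[[`, 0, "mean_r_longest")
    short_r <- vapply(ext, `[[`, 0, "mean_r_shortest")
    yo <- groups == "younger"
    extremes <- list(
      per_subject = data.frame(
        subject_id = qc$subject_id[keep],
        ga_weeks = ga,
        group = groups,
        mean_r_longest = long_r,
        mean_r_shortest = short_r,
        long_cutoff_mm = vapply(ext, `[[`, 0, "long_cutoff_mm"),
        short_cutoff_mm = vapply(ext, `[[`, 0, "short_cutoff_mm")
      ),
      longest_test = group_ttest(long_r[!yo], long_r[yo], alpha_length,
                                 effect = "older_vs_younger_longest"),
      shortest_test = group_ttest(short_r[!yo], short_r[yo], alpha_length,
                                  effect = "older_vs_younger_shortest")
    )
    dist_tbl <- bins
    range_row <- ga_correlation(rng, ga, covariates,
                                effect = "correlation_range_vs_ga")
  }

  structure(list(
    qc = qc,
    retained = keep,
    ga_weeks = ga,
    groups = groups,
    movement_tests = move_tests,
    movement_covariates = flagged,
    connectivity = conns,
    partitions = parts,
    q_star = q_vals,
    intermodular_strength = intermod,
    global = global,
    nodal_metrics = metrics,
    nodal_inference = nodal,
    hub_node = hub_node,
    hub_followup = followup,
    distance_bins = dist_tbl,
    extreme_connections = extremes,
    range_vs_ga = range_row,
    params = list(
      fd_threshold_mm = fd_threshold_mm, min_frames = min_frames,
      k_components = k_components, n_consensus = n_consensus,
      extreme_pct = extreme_pct, cut_weeks = cut_weeks, fdr_q = fdr_q,
      alpha_length = alpha_length, seed = seed
    )
  ), class = "fconn_analysis")
}

#' Write a labelled square matrix as TSV
#'
#' @param M Square matrix with (or without) dimnames.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_matrix <- function(M, path) {
  if (is.null(rownames(M))) {
    rownames(M) <- colnames(M) %||% sprintf("roi_%03d", seq_len(nrow(M)))
  }
  if (is.null(colnames(M))) colnames(M) <- rownames(M)
  df <- data.frame(roi_id = rownames(M),
                   format(M, digits = 15, trim = TRUE, scientific = TRUE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labelled square matrix from TSV
#'
#' Validates that row and column labels match and that the matrix is
#' symmetric; the roundtrip with [write_matrix()] is lossless to 15
#' significant digits.
#'
#' @param path Path written by [write_matrix()].
#' @return The labelled symmetric matrix.
#' @export
read_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  labs <- as.character(df[[1L]])
  M <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(M) <- "double"
  if (!identical(labs, colnames(M))) {
    bad <- which(labs != colnames(M))[1L]
    stop(sprintf("row/column label mismatch at position %d: '%s' vs '%s'",
                 bad, labs[bad], colnames(M)[bad]))
  }
  rownames(M) <- labs
  asym <- abs(M - t(M))
  if (max(asym) > 1e-8) {
    ij <- arrayInd(which.max(asym), dim(M))
    stop(sprintf("matrix not symmetric: first offending entry [%d, %d]",
                 ij[1], ij[2]))
  }
  M
}

#' Run the full pipeline with file outputs
#'
#' Orchestrates simulate (optional) -> qc -> regress -> connect -> graph ->
#' distance -> stats, writing every artifact plus a manifest (inputs,
#' parameters, seed, content hashes) under `out_dir`. In synthetic mode the
#' cohort is generated from `config$cohort`; otherwise subject files are read
#' from `config$data_dir` (layout as written by [write_cohort()]).
#'
#' @param config List: either `cohort` (a [cohort_config()] or argument list)
#'   for synthetic mode, or `data_dir` with cohort files; optional stage
#'   parameters as in [analyze_cohort()]; `seed`.
#' @param out_dir Output directory.
#' @return The `fconn_analysis`, invisibly; files and `manifest.json` are
#'   written under `out_dir`.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("fconn_run_")) {
  seed <- config$seed %||% 1
  if (!is.null(config$cohort)) {
    cohort <- if (inherits(config$cohort, "synthetic_cohort")) {
      config$cohort
    } else if (inherits(config$cohort, "cohort_config")) {
      generate_cohort(config$cohort)
    } else {
      generate_cohort(do.call(cohort_config, config$cohort))
    }
  } else if (!is.null(config$data_dir)) {
    cohort <- read_cohort(config$data_dir)
  } else {
    stop("config must provide either `cohort` (synthetic mode) or `data_dir`")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- analyze_cohort(
    cohort,
    fd_threshold_mm = config$fd_threshold_mm %||% 1.5,
    min_frames = config$min_frames %||% 90,
    k_components = config$k_components %||% 3,
    n_consensus = config$n_consensus %||% 1000,
    extreme_pct = config$extreme_pct %||% 5,
    cut_weeks = config$cut_weeks %||% 31,
    fdr_q = config$fdr_q %||% 0.05,
    alpha_length = config$alpha_length %||% 0.025,
    seed = seed
  )
  files <- character(0)
  wcsv <- function(x, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(x, p, row.names = FALSE)
    files <<- c(files, p)
  }
  wcsv(res$qc, "qc_summary.csv")
  wcsv(res$movement_tests, "movement_group_tests.csv")
  wcsv(res$global, "global_effects.csv")
  wcsv(res$nodal_inference, "nodal_effects.csv")
  if (!is.null(res$hub_followup)) wcsv(res$hub_followup, "hub_followup.csv")
  if (!is.null(res$extreme_connections)) {
    wcsv(res$extreme_connections$per_subject, "extreme_connections.csv")
    wcsv(rbind(res$extreme_connections$longest_test,
               res$extreme_connections$shortest_test),
         "extreme_connection_tests.csv")
  }
  excluded <- res$qc$subject_id[res$qc$excluded]
  p <- file.path(out_dir, "exclusion_log.txt")
  writeLines(c(sprintf("excluded %d subject(s) (< %d retained frames)",
                       length(excluded), res$params$min_frames), excluded), p)
  files <- c(files, p)
  for (ii in seq_along(res$connectivity)) {
    cn <- res$connectivity[[ii]]
    p <- file.path(out_dir, paste0(cn$subject_id, "_fisherz.tsv"))
    write_matrix(cn$z, p)
    files <- c(files, p)
    pt <- res$partitions[[ii]]
    p <- file.path(out_dir, paste0(cn$subject_id, "_partition.tsv"))
    utils::write.table(
      data.frame(roi_id = cn$roi_ids, module = pt$membership),
      p, sep = "\t", quote = FALSE, row.names = FALSE
    )
    files <- c(files, p)
  }
  manifest <- list(
    created = format(Sys.time(), tz = "UTC"),
    seed = seed,
    parameters = res$params,
    n_subjects = length(cohort),
    n_retained = length(res$retained),
    files = lapply(files, function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}

#' Read a cohort from files written by [write_cohort()]
#'
#' @param dir Directory holding `metadata.csv`, per-subject timeseries/noise
#'   TSVs and `rp_*.txt` motion files, and `roi_centroids.tsv`.
#' @return A list of subjects usable by [analyze_cohort()].
#' @export
read_cohort <- function(dir) {
  meta_path <- file.path(dir, "metadata.csv")
  if (!file.exists(meta_path)) stop(sprintf("missing metadata file: %s", meta_path))
  meta <- utils::read.csv(meta_path)
  cen_path <- file.path(dir, "roi_centroids.tsv")
  centroids <- NULL
  if (file.exists(cen_path)) {
    cen <- utils::read.table(cen_path, header = TRUE, sep = "\t")
    centroids <- as.matrix(cen[, -1L])
    rownames(centroids) <- cen[[1L]]
  }
  subjects <- lapply(seq_len(nrow(meta)), function(i) {
    id <- meta$subject_id[i]
    ts_path <- file.path(dir, paste0(id, "_timeseries.tsv"))
    noise_path <- file.path(dir, paste0(id, "_noise.tsv"))
    rp_path <- file.path(dir, paste0("rp_", id, ".txt"))
    for (p in c(ts_path, noise_path, rp_path)) {
      if (!file.exists(p)) stop(sprintf("missing input file: %s", p))
    }
    structure(list(
      subject_id = id,
      ga_weeks = meta$ga_weeks[i],
      roi_timeseries = as.matrix(utils::read.table(ts_path, header = TRUE,
                                                   sep = "\t")),
      motion = read_motion_file(rp_path),
      noise_tissue_timeseries = as.matrix(utils::read.table(noise_path,
                                                            header = TRUE,
                                                            sep = "\t")),
      roi_centroids = centroids
    ), class = "synthetic_subject")
  })
  structure(subjects, class = "synthetic_cohort", roi_centroids = centroids)
}
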