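# End-to-end pipeline: simulate -> agreement -> taste -> motion energy ->
# appeal-level GLM -> trial-wise FC -> MTD -> report. Every stage writes
# plain TSV artifacts; reruns with the same seed are byte-identical.

#' Default pipeline configuration
#'
#' A flat list of every design parameter and analysis flag. Defaults
#' reproduce the reference study layout: 24 participants, 31 movies of
#' which 7 repeated, 4 runs x 8 trials of 10 s fixation + 30 s movie +
#' 4 s response at TR = 2 s, 19 ROIs.
#'
#' @param ... overrides by name; unknown keys are rejected.
#' @return named list of configuration values.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_participants = 24L, n_movies = 31L, n_repeats = 7L,
    shared_sd = 0.4, individual_sd = 1, error_sd = 0.3,
    runs = 4L, trials_per_run = 8L, tr_s = 2,
    trial_fix_s = 10, trial_movie_s = 30, trial_response_s = 4,
    baseline_beta = 1, appeal_slope = 0, noise_sd = 1,
    ar1_phi = 0.3, drift_amp = 0.5,
    edge_roi_i = "", edge_roi_j = "", edge_base_r = 0, edge_appeal_slope = 0,
    rating_rate_hz = 10, rating_smoothness_s = 2,
    me_frames = 24L, me_frame_px = 64L, me_rate_hz = 12,
    # analysis flags (design choices left open by convention)
    mm1c_average_space = "z", center_participants = TRUE,
    ci_method = "t", baseline_agg = "mean",
    select_method = "top-k", fc_appeal_values = "ratings",
    highpass_hz = 0.01, band_low_hz = 0.008, band_high_hz = 0.2,
    fd_threshold = 0.5, dvars_threshold = 3,
    mtd_window = 3L, mtd_rois = "PPA,aMPFC,PCC",
    alpha = 0.05, q_level = 0.05)
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown)) {
      stop_param("unknown config key(s): ", paste(unknown, collapse = ", "))
    }
    cfg[names(over)] <- over
  }
  cfg
}

#' Load a pipeline configuration from a flat JSON file
#'
#' @param path JSON file with a flat object of config keys.
#' @return validated config list (unknown keys rejected).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_param("config not found: ", path)
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, vals)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Chains every stage on a simulated dataset with the configured ground
#' truth, writing all TSV artifacts plus a provenance log (seed, package
#' version, every flag) into `out_dir`.
#'
#' Stages: `simulate` (ratings, continuous traces, ROI BOLD, confounds,
#' events), `agreement` (MM1, MM1c), `taste` (variance decomposition),
#' `motion_energy` (Gabor-jet ME of a synthetic stack + rating
#' correlations), `glm` (appeal-level contrasts with Bonferroni),
#' `fc` (trial-wise edges, appeal regression, FDR), `mtd` (3-node dynamic
#' connectivity vs rating change), `report` (one summary table).
#'
#' @param config list from [pipeline_config()] or a path to a JSON config.
#' @param out_dir output directory (created if needed).
#' @param stages character vector of stages to run (default all, in order).
#' @return invisibly, a named list with each stage's in-memory results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         stages = c("simulate", "agreement", "taste",
                                    "motion_energy", "glm", "fc", "mtd",
                                    "report")) {
  cfg <- if (is.character(config)) read_config(config) else
    do.call(pipeline_config, config[])
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = cfg)
  log_lines <- c(sprintf("aestheticfmri %s",
                         as.character(utils::packageVersion("aestheticfmri"))),
                 sprintf("%s = %s", names(cfg),
                         vapply(cfg, function(v) paste(format(v), collapse = ","),
                                character(1))))
  writeLines(log_lines, file.path(out_dir, "pipeline_log.txt"))

  rspec <- rating_sim_spec(cfg$n_participants, cfg$n_movies, cfg$n_repeats,
                           cfg$shared_sd, cfg$individual_sd, cfg$error_sd,
                           squash = FALSE, seed = derive_seed(cfg$seed, 101L))
  edges <- if (nzchar(cfg$edge_roi_i)) {
    data.frame(roi_i = cfg$edge_roi_i, roi_j = cfg$edge_roi_j,
               base_r = cfg$edge_base_r, appeal_slope = cfg$edge_appeal_slope)
  } else NULL
  # one movie per trial; a short final run absorbs any shortfall (the
  # reference design analyses 31 of 4 x 8 presented trials)
  n_trials <- cfg$n_movies

  if ("simulate" %in% stages) {
    ratings <- gen_ratings(rspec)
    traces <- gen_continuous(rspec, duration_s = cfg$trial_movie_s,
                             rate_hz = cfg$rating_rate_hz,
                             smoothness_s = cfg$rating_smoothness_s)
    write_ratings(ratings$table, file.path(out_dir, "ratings.csv"))
    write_continuous(traces, file.path(out_dir, "continuous_ratings.tsv"))
    jsonlite::write_json(
      list(shared_fraction = ratings$truth$shared_fraction,
           shared_sd = cfg$shared_sd, individual_sd = cfg$individual_sd,
           error_sd = cfg$error_sd),
      file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
    res$ratings <- ratings
    res$traces <- traces
  }

  if ("agreement" %in% stages) {
    if (is.null(res$ratings)) stop_param("agreement stage requires the simulate stage artifacts (ratings)")
    mm1 <- mm1_overall(res$ratings$table, ci_method = cfg$ci_method)
    mm1c <- mm1_continuous(res$traces, average_space = cfg$mm1c_average_space,
                           ci_method = cfg$ci_method)
    agree <- rbind(
      data.frame(participant_id = names(mm1$per_participant_r),
                 statistic = "MM1", r = unname(mm1$per_participant_r)),
      data.frame(participant_id = names(mm1c$per_participant_r),
                 statistic = "MM1c", r = unname(mm1c$per_participant_r)))
    agree$z <- atanh(clip_r(agree$r)$r)
    write_tsv(agree, file.path(out_dir, "agreement.tsv"))
    res$mm1 <- mm1; res$mm1c <- mm1c
  }

  if ("taste" %in% stages) {
    if (is.null(res$ratings)) stop_param("taste stage requires the simulate stage artifacts (ratings)")
    dec <- decompose_taste(res$ratings$table,
                           center_participants = cfg$center_participants)
    write_tsv(data.frame(
      var_total = dec$var_total, var_error = dec$var_error,
      var_repeatable = dec$var_repeatable,
      shared_fraction = dec$shared_fraction,
      individual_fraction = dec$individual_fraction,
      unrepeatable = dec$unrepeatable),
      file.path(out_dir, "decomposition.tsv"))
    res$decomposition <- dec
  }

  if ("motion_energy" %in% stages) {
    if (is.null(res$ratings)) stop_param("motion_energy stage requires the simulate stage artifacts (ratings)")
    bank <- build_gabor_bank(wavelengths = c(4, 8, 16), orientations = 6,
                             grid = c(6, 6))
    me_means <- numeric(cfg$n_movies)
    me_rows <- list()
    for (m in seq_len(cfg$n_movies)) {
      fspec <- frame_sim_spec(cfg$me_frames, cfg$me_frame_px, cfg$me_frame_px,
                              speed_px_per_frame = 0.5 + (m %% 5) * 0.4,
                              texture_seed = derive_seed(cfg$seed, 200L + m))
      tr_me <- motion_energy_trace(gen_frames(fspec), bank,
                                   native_rate = cfg$me_rate_hz)
      me_means[m] <- mean(tr_me$values)
      me_rows[[m]] <- data.frame(movie_id = sprintf("mov-%02d", m),
                                 time_s = seq_along(tr_me$values) / cfg$me_rate_hz,
                                 me = tr_me$values)
    }
    names(me_means) <- sprintf("mov-%02d", seq_len(cfg$n_movies))
    write_tsv(do.call(rbind, me_rows), file.path(out_dir, "motion_energy.tsv"))
    write_tsv(data.frame(movie_id = names(me_means), me_mean = me_means),
              file.path(out_dir, "movie_me_mean.tsv"))
    me_overall <- correlate_with_covariate(res$ratings$table, me_means,
                                           ci_method = cfg$ci_method)
    res$me_means <- me_means
    res$me_overall_r <- me_overall
  }

  needs_bold <- any(c("glm", "fc", "mtd") %in% stages)
  if (needs_bold) {
    if (is.null(res$ratings)) stop_param("glm/fc/mtd stages require the simulate stage artifacts (ratings)")
    bspec <- bold_sim_spec(
      n_participants = cfg$n_participants,
      runs = cfg$runs, trials_per_run = cfg$trials_per_run,
      n_trials = n_trials,
      trial_structure = c(cfg$trial_fix_s, cfg$trial_movie_s,
                          cfg$trial_response_s),
      tr_s = cfg$tr_s, baseline_beta = cfg$baseline_beta,
      appeal_slope = cfg$appeal_slope, edges = edges,
      ar1_phi = cfg$ar1_phi, drift_amp = cfg$drift_amp,
      noise_sd = cfg$noise_sd, seed = derive_seed(cfg$seed, 301L))
    appeal_map <- bin_quartiles(res$ratings$table)
    appeal_mat <- t(vapply(split(appeal_map, appeal_map$participant_id),
                           function(d) d$level[order(d$movie_id)][seq_len(n_trials)],
                           integer(n_trials)))
    sim <- gen_bold(bspec, appeal = appeal_mat)
    for (p in names(sim$bundles)) {
      b <- sim$bundles[[p]]
      write_roi_timeseries(b$ts, b$run,
                           file.path(out_dir, paste0(p, "_roi_timeseries.tsv")))
      write_confounds(b$confounds,
                      file.path(out_dir, paste0(p, "_confounds.tsv")))
      write_events(b$events, file.path(out_dir, paste0(p, "_events.tsv")))
    }
    res$bold <- sim
    res$appeal_map <- appeal_map
  }

  if ("glm" %in% stages) {
    fits <- lapply(res$bold$bundles, function(b) {
      pp <- preprocess_roi(b, highpass_hz = cfg$highpass_hz)
      X <- build_design(b$events, b$tr_s, b$run, confounds = b$confounds,
                        highpass_hz = cfg$highpass_hz)
      fit_glm(pp$ts, X)
    })
    contrasts <- do.call(rbind, lapply(
      c("movies_vs_baseline", "4v1", "4v321"), function(cn) {
        contrast_test(fits, cn, alpha = cfg$alpha,
                      baseline_agg = cfg$baseline_agg)
      }))
    write_tsv(contrasts, file.path(out_dir, "glm_contrasts.tsv"))
    beta_rows <- do.call(rbind, lapply(names(fits), function(p) {
      b <- fits[[p]]$betas[paste0("level_", 1:4), , drop = FALSE]
      data.frame(participant_id = p, regressor = rownames(b), b,
                 check.names = FALSE, row.names = NULL)
    }))
    write_tsv(beta_rows, file.path(out_dir, "betas.tsv"))
    res$glm_fits <- fits
    res$contrasts <- contrasts
  }

  if ("fc" %in% stages) {
    dn_spec <- denoise_spec(band = c(cfg$band_low_hz, cfg$band_high_hz),
                            fd_threshold = cfg$fd_threshold,
                            dvars_threshold = cfg$dvars_threshold)
    t1 <- res$ratings$table[res$ratings$table$presentation == 1L, ]
    stats_list <- list(); fc_rows <- list()
    for (p in names(res$bold$bundles)) {
      b <- suppressWarnings(denoise(res$bold$bundles[[p]], dn_spec))
      idx <- select_trial_timepoints(b$events, b$tr_s, b$run,
                                     method = cfg$select_method)
      stack <- suppressWarnings(trial_fc(b, idx))
      mv <- b$events[b$events$trial_type == "movie", ]
      vals <- if (cfg$fc_appeal_values == "bins") {
        am <- res$appeal_map[res$appeal_map$participant_id == p, ]
        am$level[match(mv$movie_id, am$movie_id)]
      } else {
        t1$rating[t1$participant_id == p][match(mv$movie_id,
          t1$movie_id[t1$participant_id == p])]
      }
      vals <- vals[match(rownames(stack$z), as.character(mv$trial_id))]
      stats_list[[p]] <- fc_appeal_regression(stack, vals)
      fc_rows[[p]] <- data.frame(participant_id = p,
                                 trial = rep(rownames(stack$z),
                                             ncol(stack$z)),
                                 edge = rep(colnames(stack$z),
                                            each = nrow(stack$z)),
                                 z = as.vector(stack$z))
    }
    write_tsv(do.call(rbind, fc_rows), file.path(out_dir, "fc_trialwise.tsv"))
    edge_stats <- group_edge_test(stats_list, q_level = cfg$q_level)
    write_tsv(edge_stats, file.path(out_dir, "fc_edges.tsv"))
    res$fc_stats <- stats_list
    res$edge_stats <- edge_stats
  }

  if ("mtd" %in% stages) {
    rois <- strsplit(cfg$mtd_rois, ",", fixed = TRUE)[[1]]
    movie_ids <- sprintf("mov-%02d", seq_len(n_trials))
    fits <- list()
    for (p in names(res$bold$bundles)) {
      b <- suppressWarnings(denoise(res$bold$bundles[[p]],
        denoise_spec(band = c(cfg$band_low_hz, cfg$band_high_hz),
                     fd_threshold = cfg$fd_threshold,
                     dvars_threshold = cfg$dvars_threshold)))
      tr_p <- Filter(function(t) t$participant_id == p &&
                       t$movie_id %in% movie_ids, res$traces)
      tr_p <- tr_p[order(vapply(tr_p, `[[`, character(1), "movie_id"))]
      regs <- change_regressors(tr_p, b$events, b$tr_s, b$run)
      m <- suppressWarnings(mtd(b$ts[, rois, drop = FALSE],
                                window_halfwidth = cfg$mtd_window))
      fits[[p]] <- mtd_glm(m, regs, roi_subset = rois)
    }
    mtd_res <- mtd_paired_test(fits)
    write_tsv(mtd_res, file.path(out_dir, "mtd_results.tsv"))
    res$mtd_fits <- fits
    res$mtd_results <- mtd_res
  }

  if ("report" %in% stages) {
    rows <- list()
    add <- function(stat, value) {
      rows[[length(rows) + 1L]] <<- data.frame(statistic = stat, value = value)
    }
    if (!is.null(res$mm1)) {
      add("mm1_mean_r", res$mm1$summary$mean_r)
      add("mm1c_mean_r", res$mm1c$summary$mean_r)
    }
    if (!is.null(res$decomposition)) {
      add("shared_fraction", res$decomposition$shared_fraction)
      add("individual_fraction", res$decomposition$individual_fraction)
    }
    if (!is.null(res$me_overall_r)) {
      add("me_overall_r", res$me_overall_r$summary$mean_r)
    }
    if (!is.null(res$contrasts)) {
      add("glm_sig_movies_vs_baseline",
          sum(res$contrasts$bonferroni_sig[
            res$contrasts$contrast == "movies_vs_baseline"]))
      add("glm_sig_4v1",
          sum(res$contrasts$bonferroni_sig[res$contrasts$contrast == "4v1"]))
    }
    if (!is.null(res$edge_stats)) {
      add("fc_sig_edges_linear",
          sum(res$edge_stats$significant[res$edge_stats$regressor == "linear"]))
      add("fc_sig_edges_quadratic",
          sum(res$edge_stats$significant[
            res$edge_stats$regressor == "quadratic"]))
    }
    if (!is.null(res$mtd_results)) {
      add("mtd_min_p", min(res$mtd_results$p))
    }
    write_tsv(do.call(rbind, rows), file.path(out_dir, "summary.tsv"))
  }
  invisible(res)
}
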