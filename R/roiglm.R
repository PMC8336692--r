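# Appeal-level GLM on ROI-averaged BOLD timeseries: preprocessing, design
# construction, OLS fitting, contrasts and group tests.

#' Bundle ROI timeseries with run structure, events and confounds
#'
#' @param ts numeric matrix, scans x ROIs (runs concatenated).
#' @param run integer vector, run id per scan.
#' @param tr_s repetition time in seconds.
#' @param events data.frame with `onset` (seconds, relative to run start),
#'   `duration`, `trial_type` (`"movie"` or `"response"`), `trial_id`,
#'   `appeal_level` (1-4 for movie events, NA otherwise), `run_id`.
#' @param confounds optional data.frame aligned to scans (fMRIPrep-style
#'   columns: `trans_x` ... `rot_z`, `framewise_displacement`, `std_dvars`,
#'   `a_comp_cor_00` ... `a_comp_cor_05`).
#' @return object of class `"roi_bundle"`.
#' @export
roi_bundle <- function(ts, run, tr_s, events = NULL, confounds = NULL) {
  ts <- as.matrix(ts)
  if (length(run) != nrow(ts)) stop_param("`run` must have one entry per scan")
  if (!is.null(confounds) && nrow(confounds) != nrow(ts)) {
    stop_param("confounds not aligned to scans")
  }
  if (!is.null(events)) validate_events(events, tr_s, run)
  structure(list(ts = ts, run = as.integer(run), tr_s = tr_s,
                 roi_names = colnames(ts), events = events,
                 confounds = confounds),
            class = "roi_bundle")
}

validate_events <- function(events, tr_s, run) {
  need <- c("onset", "duration", "trial_type", "run_id")
  miss <- setdiff(need, names(events))
  if (length(miss)) stop_param("events missing column(s): ",
                               paste(miss, collapse = ", "))
  if (any(events$onset < 0)) stop_param("event onsets must be nonnegative")
  if (any(events$duration <= 0)) stop_param("event durations must be positive")
  for (r in unique(events$run_id)) {
    e <- events[events$run_id == r, ]
    if (is.unsorted(e$onset)) stop_param("onsets must be nondecreasing within run ", r)
    mv <- e[e$trial_type == "movie", ]
    if (nrow(mv) > 1L &&
        any(mv$onset[-1] < (mv$onset + mv$duration)[-nrow(mv)])) {
      stop_param("overlapping movie trials in run ", r)
    }
    n_r <- sum(run == r)
    if (any(e$onset + e$duration > n_r * tr_s + 1e-9)) {
      stop_param("event exceeds scan duration in run ", r)
    }
  }
  invisible(events)
}

#' Per-run high-pass filter, detrend and z-scoring of ROI timeseries
#'
#' Within each run: regress out a discrete-cosine high-pass basis
#' (frequencies below `highpass_hz`) together with an intercept and linear
#' trend, then z-score each ROI. Runs shorter than two filter periods skip
#' the high-pass with a warning.
#'
#' @param bundle a [roi_bundle()].
#' @param highpass_hz cutoff frequency, default 0.01 Hz.
#' @param detrend,zscore toggles for the linear detrend and z-scoring.
#' @return the bundle with filtered `ts`.
#' @export
preprocess_roi <- function(bundle, highpass_hz = 0.01, detrend = TRUE,
                           zscore = TRUE) {
  stopifnot(inherits(bundle, "roi_bundle"))
  out <- bundle$ts
  for (r in unique(bundle$run)) {
    idx <- which(bundle$run == r)
    n <- length(idx)
    X <- cbind(intercept = rep(1, n))
    if (detrend) X <- cbind(X, trend = seq_len(n))
    if (n * bundle$tr_s < 2 / highpass_hz) {
      warning("run ", r, " shorter than two filter periods; high-pass skipped")
    } else {
      X <- cbind(X, dct_basis(n, bundle$tr_s, highpass_hz))
    }
    res <- stats::lm.fit(X, out[idx, , drop = FALSE])$residuals
    if (zscore) res <- scale(res)
    out[idx, ] <- res
  }
  bundle$ts <- out
  bundle
}

# Expand 6 motion parameters into the 24-parameter block: the parameters,
# their within-run temporal derivatives (first scan = 0), and quadratics of
# both.
motion24 <- function(confounds, run) {
  cols <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  miss <- setdiff(cols, names(confounds))
  if (length(miss)) stop_param("confounds missing motion column(s): ",
                               paste(miss, collapse = ", "))
  m <- as.matrix(confounds[cols])
  d <- m * 0
  for (r in unique(run)) {
    idx <- which(run == r)
    d[idx[-1], ] <- diff(m[idx, , drop = FALSE])
  }
  out <- cbind(m, d, m^2, d^2)
  colnames(out) <- c(cols, paste0(cols, "_derivative1"),
                     paste0(cols, "_power2"),
                     paste0(cols, "_derivative1_power2"))
  out
}

#' Build the appeal-level design matrix
#'
#' Four HRF-convolved boxcar regressors for the movie-on periods (one per
#' appeal level), one for the response periods, 24 motion-derived nuisance
#' columns when confounds are supplied, and one intercept per run.
#' Convolution is done per run at 10x oversampled resolution.
#'
#' @param events event table (see [roi_bundle()]); movie rows must carry
#'   `appeal_level` in 1-4 (attach one with [bin_quartiles()] output via
#'   `appeal` if the table lacks it).
#' @param tr TR in seconds.
#' @param run integer run id per scan (defines scan counts per run).
#' @param confounds optional confound table aligned to scans.
#' @param appeal optional data.frame (`movie_id` or `trial_id`, `level`)
#'   used to fill `appeal_level` when absent from `events`.
#' @param highpass_hz when non-NULL, per-run discrete-cosine drift columns
#'   below this frequency are appended, so that high-pass filtering of the
#'   data does not attenuate the task betas (the drift basis matches the
#'   one used by [preprocess_roi()]).
#' @return object of class `"design_matrix"`: list with `X` (scans x
#'   regressors), `task_cols`, `nuisance_cols`, `tr`, `run`.
#' @export
build_design <- function(events, tr, run, confounds = NULL, appeal = NULL,
                         highpass_hz = NULL) {
  events <- merge_appeal(events, appeal)
  validate_events(events, tr, run)
  mv <- events[events$trial_type == "movie", ]
  if (anyNA(mv$appeal_level)) stop_param("appeal level missing for trial(s) ",
    paste(mv$trial_id[is.na(mv$appeal_level)], collapse = ", "))
  runs <- unique(run)
  X_task <- NULL
  for (lev in 1:4) {
    e <- mv[mv$appeal_level == lev, ]
    if (nrow(e) == 0L) stop_param("no trials at appeal level ", lev)
    col <- unlist(lapply(runs, function(r) {
      er <- e[e$run_id == r, ]
      n_r <- sum(run == r)
      if (nrow(er) == 0L) return(numeric(n_r))
      convolve_events(er$onset, er$duration, n_r, tr)
    }))
    X_task <- cbind(X_task, col)
  }
  resp <- events[events$trial_type == "response", ]
  resp_col <- unlist(lapply(runs, function(r) {
    er <- resp[resp$run_id == r, ]
    n_r <- sum(run == r)
    if (nrow(er) == 0L) return(numeric(n_r))
    convolve_events(er$onset, er$duration, n_r, tr)
  }))
  X_task <- cbind(X_task, resp_col)
  colnames(X_task) <- c(paste0("level_", 1:4), "response")
  nuis <- if (!is.null(confounds)) motion24(confounds, run) else NULL
  drift <- drift_block(run, tr, highpass_hz)
  run_ints <- sapply(runs, function(r) as.numeric(run == r))
  colnames(run_ints) <- paste0("run_", runs)
  X <- cbind(X_task, nuis, drift, run_ints)
  structure(list(X = X, task_cols = colnames(X_task),
                 nuisance_cols = colnames(nuis), tr = tr, run = run),
            class = "design_matrix")
}

# Per-run DCT drift columns below the cutoff (NULL cutoff -> none).
drift_block <- function(run, tr, highpass_hz) {
  if (is.null(highpass_hz)) return(NULL)
  runs <- unique(run)
  n <- length(run)
  cols <- NULL
  for (r in runs) {
    idx <- which(run == r)
    B <- dct_basis(length(idx), tr, highpass_hz)
    if (ncol(B) == 0L) next
    full <- matrix(0, n, ncol(B))
    full[idx, ] <- B
    colnames(full) <- sprintf("drift_run%s_%d", r, seq_len(ncol(B)))
    cols <- cbind(cols, full)
  }
  cols
}

merge_appeal <- function(events, appeal) {
  if (is.null(appeal)) return(events)
  key <- if ("movie_id" %in% names(appeal) && "movie_id" %in% names(events)) {
    "movie_id"
  } else "trial_id"
  events$appeal_level <- NULL
  lev <- appeal$level[match(events[[key]], appeal[[key]])]
  events$appeal_level <- ifelse(events$trial_type == "movie", lev, NA)
  events
}

#' Fit the ROI GLM by ordinary least squares
#'
#' @param Y scans x ROIs matrix (typically [preprocess_roi()] output).
#' @param design a `"design_matrix"` (or bare matrix).
#' @return object of class `"glm_fit"`: `betas` (regressors x ROIs),
#'   `sigma2`, `dof`, `regressors`.
#' @export
fit_glm <- function(Y, design) {
  X <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  Y <- as.matrix(Y)
  if (nrow(Y) != nrow(X)) stop_param("Y and design have different row counts")
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop_param("design is rank deficient; collinear column(s): ",
               paste(bad, collapse = ", "))
  }
  betas <- qr.coef(qrx, Y)
  resid <- Y - X %*% betas
  dof <- nrow(X) - ncol(X)
  structure(list(betas = betas, sigma2 = colSums(resid^2) / dof,
                 dof = dof, regressors = colnames(X)),
            class = "glm_fit")
}

# Canonical contrast weight vectors over the appeal-level regressors.
contrast_weights <- function(name, baseline_agg = c("mean", "sum")) {
  baseline_agg <- match.arg(baseline_agg)
  switch(name,
    movies_vs_baseline = {
      w <- if (baseline_agg == "mean") rep(1 / 4, 4) else rep(1, 4)
      stats::setNames(w, paste0("level_", 1:4))
    },
    "4v1" = c(level_1 = -1, level_4 = 1),
    "4v321" = c(level_1 = -1 / 3, level_2 = -1 / 3, level_3 = -1 / 3, level_4 = 1),
    stop_param("unknown contrast: ", name))
}

#' Group-level contrast test across participants
#'
#' Per participant, the contrast effect c'beta is computed per ROI; the
#' effects are compared to zero across participants with one-sample
#' t-tests, Bonferroni-corrected at `alpha / n_ROIs`. This two-stage
#' procedure is the balanced-design equivalent of a random-intercept mixed
#' model on the per-level betas.
#'
#' @param fits list of `"glm_fit"` objects, one per participant, with a
#'   common regressor layout.
#' @param contrast `"movies_vs_baseline"`, `"4v1"`, `"4v321"`, or a named
#'   numeric weight vector over regressors.
#' @param alpha family-wise error level for Bonferroni, default 0.05.
#' @param baseline_agg `"mean"` (default) or `"sum"` of the level betas for
#'   the movies-vs-baseline contrast.
#' @return data.frame (class `"contrast_result"`): roi, contrast, mean
#'   effect, group_t, p, dof, bonferroni_sig, degenerate flag.
#' @export
contrast_test <- function(fits, contrast = "movies_vs_baseline", alpha = 0.05,
                          baseline_agg = "mean") {
  if (length(fits) < 3L) stop_param("need at least 3 participants")
  w <- if (is.character(contrast)) {
    contrast_weights(contrast, baseline_agg)
  } else contrast
  cname <- if (is.character(contrast)) contrast else "custom"
  layout <- fits[[1]]$regressors
  if (!all(names(w) %in% layout)) stop_param("contrast names regressors absent from the design")
  eff <- vapply(fits, function(f) {
    if (!identical(f$regressors, layout)) {
      stop_param("regressor layout differs across participants")
    }
    drop(crossprod(w, f$betas[names(w), , drop = FALSE]))
  }, numeric(ncol(fits[[1]]$betas)))
  if (is.null(dim(eff))) eff <- rbind(eff)   # single-ROI case
  effects <- t(eff)                          # participants x ROIs
  rois <- colnames(fits[[1]]$betas)
  tests <- lapply(seq_along(rois), function(j) one_sample_t(effects[, j]))
  p <- vapply(tests, `[[`, numeric(1), "p")
  data.frame(roi = rois, contrast = cname,
             effect = colMeans(effects),
             group_t = vapply(tests, `[[`, numeric(1), "t"),
             p = p,
             dof = vapply(tests, `[[`, numeric(1), "dof"),
             bonferroni_sig = bonferroni(p, alpha),
             degenerate = vapply(tests, `[[`, logical(1), "degenerate"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Trial-wise beta series (least-squares-all)
#'
#' One HRF-convolved regressor per movie trial, the response regressor,
#' motion nuisance and run intercepts; the per-trial betas are the unit of
#' trial-wise analyses and average (per appeal level, on a balanced
#' noiseless design) to the level-GLM betas.
#'
#' @param Y scans x ROIs matrix.
#' @param events event table (movie rows need `trial_id`).
#' @param tr TR (s).
#' @param run run id per scan.
#' @param confounds optional confound table.
#' @param highpass_hz optional drift-column cutoff as in [build_design()].
#' @return list with `betas` (trials x ROIs), `trial_id`, `appeal_level`.
#' @export
beta_series <- function(Y, events, tr, run, confounds = NULL,
                        highpass_hz = NULL) {
  validate_events(events, tr, run)
  mv <- events[events$trial_type == "movie", ]
  runs <- unique(run)
  Xt <- sapply(seq_len(nrow(mv)), function(i) {
    unlist(lapply(runs, function(r) {
      n_r <- sum(run == r)
      if (mv$run_id[i] != r) return(numeric(n_r))
      convolve_events(mv$onset[i], mv$duration[i], n_r, tr)
    }))
  })
  colnames(Xt) <- paste0("trial_", mv$trial_id)
  resp <- events[events$trial_type == "response", ]
  resp_col <- unlist(lapply(runs, function(r) {
    er <- resp[resp$run_id == r, ]
    n_r <- sum(run == r)
    if (nrow(er) == 0L) return(numeric(n_r))
    convolve_events(er$onset, er$duration, n_r, tr)
  }))
  nuis <- if (!is.null(confounds)) motion24(confounds, run) else NULL
  run_ints <- sapply(runs, function(r) as.numeric(run == r))
  X <- cbind(Xt, response = resp_col, nuis,
             drift_block(run, tr, highpass_hz), run_ints)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop_param("collinear trial regressors: ", paste(bad, collapse = ", "))
  }
  betas <- qr.coef(qrx, as.matrix(Y))[seq_len(ncol(Xt)), , drop = FALSE]
  rownames(betas) <- colnames(Xt)
  list(betas = betas, trial_id = mv$trial_id,
       appeal_level = mv$appeal_level)
}
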