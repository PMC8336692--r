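# Synthetic-data generators with known ground truth: overall ratings,
# continuous rating traces, ROI BOLD bundles with appeal-modulated
# amplitude and edge connectivity, and translating frame stacks.
# All generators are deterministic under a fixed seed; per-participant
# streams are derived from the root seed by fixed offsets.

#' Specification for the overall-rating generator
#'
#' Latent additive model for overall aesthetic ratings:
#' rating(p, m, k) = shared_sd * mu_m + individual_sd * tau_pm +
#' error_sd * eps_pmk with mu, tau, eps iid standard normal, so the
#' ground-truth shared fraction of repeatable variance is
#' shared_sd^2 / (shared_sd^2 + individual_sd^2). Defaults give a mostly
#' individual taste profile (shared fraction ~0.14) with leave-one-out
#' agreement in the middle of the range typical for naturalistic video
#' ratings.
#'
#' @param n_participants,n_movies,n_repeats design counts; the first
#'   `n_repeats` movies receive a second presentation.
#' @param shared_sd,individual_sd,error_sd component standard deviations.
#' @param squash map ratings into \[-1, 1\] via tanh(x / 2.5)? Default
#'   FALSE (squashing distorts variance fractions).
#' @param seed integer root seed.
#' @return object of class `"rating_sim_spec"`.
#' @export
rating_sim_spec <- function(n_participants = 24, n_movies = 31, n_repeats = 7,
                            shared_sd = 0.4, individual_sd = 1, error_sd = 0.3,
                            squash = FALSE, seed = 1) {
  spec <- list(
    n_participants = check_count(n_participants, "n_participants", 2L),
    n_movies = check_count(n_movies, "n_movies", 2L),
    n_repeats = check_count(n_repeats, "n_repeats", 0L),
    shared_sd = check_number(shared_sd, "shared_sd", 0),
    individual_sd = check_number(individual_sd, "individual_sd", 0),
    error_sd = check_number(error_sd, "error_sd", 0),
    squash = check_flag(squash, "squash"),
    seed = check_count(seed, "seed", 0L))
  if (spec$n_repeats > spec$n_movies) stop_param("n_repeats must not exceed n_movies")
  structure(spec, class = "rating_sim_spec")
}

#' Generate overall ratings with known shared/individual/error structure
#'
#' @param spec a [rating_sim_spec()].
#' @return list with `table` (a [rating_table()]) and `truth` (component
#'   sds, latent movie and taste effects, and the ground-truth
#'   `shared_fraction`).
#' @export
gen_ratings <- function(spec) {
  stopifnot(inherits(spec, "rating_sim_spec"))
  P <- spec$n_participants; M <- spec$n_movies
  with_seed(spec$seed, {
    mu <- stats::rnorm(M)
    tau <- matrix(stats::rnorm(P * M), P, M)
    base <- spec$shared_sd * matrix(mu, P, M, byrow = TRUE) +
      spec$individual_sd * tau
    k1 <- base + spec$error_sd * matrix(stats::rnorm(P * M), P, M)
    k2 <- base[, seq_len(spec$n_repeats), drop = FALSE] +
      spec$error_sd * matrix(stats::rnorm(P * spec$n_repeats), P, spec$n_repeats)
    sq <- function(x) if (spec$squash) tanh(x / 2.5) else x
    tab <- rbind(
      data.frame(participant_id = rep(sprintf("sub-%02d", seq_len(P)), M),
                 movie_id = rep(sprintf("mov-%02d", seq_len(M)), each = P),
                 presentation = 1L, rating = as.vector(sq(k1))),
      if (spec$n_repeats > 0)
        data.frame(participant_id = rep(sprintf("sub-%02d", seq_len(P)),
                                        spec$n_repeats),
                   movie_id = rep(sprintf("mov-%02d", seq_len(spec$n_repeats)),
                                  each = P),
                   presentation = 2L, rating = as.vector(sq(k2))))
    denom <- spec$shared_sd^2 + spec$individual_sd^2
    list(table = rating_table(tab),
         truth = list(shared_fraction = if (denom > 0) spec$shared_sd^2 / denom
                      else NA_real_,
                      mu = mu, tau = tau,
                      shared_sd = spec$shared_sd,
                      individual_sd = spec$individual_sd,
                      error_sd = spec$error_sd))
  })
}

# Low-pass filter white noise by zeroing FFT bins above the cutoff, then
# scale to unit max absolute value.
smooth_noise <- function(n, rate_hz, smoothness_s) {
  x <- stats::rnorm(n)
  f <- c(0, seq_len(n - 1)) / n * rate_hz
  f <- pmin(f, rate_hz - f)          # two-sided frequency axis
  keep <- f <= 1 / smoothness_s
  y <- Re(stats::fft(stats::fft(x) * keep, inverse = TRUE)) / n
  m <- max(abs(y))
  if (m == 0) y else y / m
}

#' Generate continuous rating traces
#'
#' Each trace mixes a per-movie shared smooth signal, a per-trace private
#' smooth signal and smooth noise, all produced by low-pass filtering white
#' noise at cutoff 1/`smoothness_s` and rescaling to unit amplitude;
#' mixing weights follow the component sds in `spec` and the mixture is normalized into
#' \[-1, 1\].
#'
#' @param spec a [rating_sim_spec()] (sds and counts reused).
#' @param duration_s trace duration (default 30 s).
#' @param rate_hz sampling rate (default 10 Hz).
#' @param smoothness_s smoothness timescale (default 2 s); must be > 0.
#' @return list of [rating_trace()] objects (participant x movie).
#' @export
gen_continuous <- function(spec, duration_s = 30, rate_hz = 10,
                           smoothness_s = 2) {
  stopifnot(inherits(spec, "rating_sim_spec"))
  smoothness_s <- check_number(smoothness_s, "smoothness_s", 0, strict = TRUE)
  n <- round(duration_s * rate_hz)
  if (n < 2) stop_param("duration_s * rate_hz must be at least 2")
  P <- spec$n_participants; M <- spec$n_movies
  wsum <- spec$shared_sd + spec$individual_sd + spec$error_sd
  if (wsum == 0) stop_param("at least one component sd must be positive")
  with_seed(spec$seed, {
    shared <- replicate(M, smooth_noise(n, rate_hz, smoothness_s))
    traces <- vector("list", P * M)
    k <- 0L
    for (p in seq_len(P)) for (m in seq_len(M)) {
      v <- (spec$shared_sd * shared[, m] +
            spec$individual_sd * smooth_noise(n, rate_hz, smoothness_s) +
            spec$error_sd * smooth_noise(n, rate_hz, smoothness_s)) / wsum
      k <- k + 1L
      traces[[k]] <- rating_trace(sprintf("sub-%02d", p),
                                  sprintf("mov-%02d", m), rate_hz, v)
    }
    traces
  })
}

#' Specification for the ROI BOLD generator
#'
#' Emulates the study design: per run, a short initial blank, a sequence of
#' trials (fixation + movie + response), and a final blank. Movie events
#' add an HRF-convolved boxcar with amplitude
#' `baseline_beta + appeal_slope * level` per ROI. Parametrized ROI pairs
#' receive noise whose correlation during each trial's retained window is
#' `base_r + appeal_slope_edge * level`; elsewhere noise is independent.
#' AR(1) temporal autocorrelation and a slow cosine drift are added, and an
#' fMRIPrep-style confound table is emitted.
#'
#' @param n_participants participants to simulate.
#' @param roi_names ROI labels; default the 19 visual/DMN/reward regions of
#'   the reference design.
#' @param runs,trials_per_run run layout (default 4 x 8).
#' @param n_trials total trials simulated; defaults to
#'   `runs * trials_per_run` but may be smaller (short final run), as when
#'   one trial of the reference design is dropped, leaving 31.
#' @param trial_structure c(fixation, movie, response) durations in s.
#' @param tr_s TR (default 2 s).
#' @param baseline_beta,appeal_slope scalar or per-ROI amplitude parameters.
#' @param response_beta amplitude of the response-period events.
#' @param edges optional data.frame (`roi_i`, `roi_j`, `base_r`,
#'   `appeal_slope`) of parametrized connectivity edges; must satisfy
#'   |base_r + 4 * appeal_slope| < 1.
#' @param ar1_phi AR(1) noise autocorrelation in \[0, 1).
#' @param drift_amp low-frequency drift amplitude (signal units).
#' @param noise_sd noise standard deviation (0 = noiseless).
#' @param initial_blank_s,final_blank_s run padding (defaults 2 and 10 s).
#' @param seed integer root seed.
#' @return object of class `"bold_sim_spec"`.
#' @export
bold_sim_spec <- function(n_participants = 24,
                          roi_names = default_roi_names(),
                          runs = 4, trials_per_run = 8, n_trials = NULL,
                          trial_structure = c(10, 30, 4), tr_s = 2,
                          baseline_beta = 1, appeal_slope = 0,
                          response_beta = 0.5, edges = NULL,
                          ar1_phi = 0.3, drift_amp = 0.5, noise_sd = 1,
                          initial_blank_s = 2, final_blank_s = 10,
                          seed = 1) {
  R <- length(roi_names)
  spec <- list(
    n_participants = check_count(n_participants, "n_participants"),
    roi_names = as.character(roi_names),
    runs = check_count(runs, "runs"),
    trials_per_run = check_count(trials_per_run, "trials_per_run"),
    n_trials = if (is.null(n_trials)) {
      check_count(runs, "runs") * check_count(trials_per_run, "trials_per_run")
    } else check_count(n_trials, "n_trials"),
    trial_structure = trial_structure,
    tr_s = check_number(tr_s, "tr_s", 0, strict = TRUE),
    baseline_beta = rep_len(baseline_beta, R),
    appeal_slope = rep_len(appeal_slope, R),
    response_beta = check_number(response_beta, "response_beta"),
    edges = edges,
    ar1_phi = check_number(ar1_phi, "ar1_phi", 0),
    drift_amp = check_number(drift_amp, "drift_amp", 0),
    noise_sd = check_number(noise_sd, "noise_sd", 0),
    initial_blank_s = initial_blank_s, final_blank_s = final_blank_s,
    seed = check_count(seed, "seed", 0L))
  if (spec$ar1_phi >= 1) stop_param("ar1_phi must be in [0, 1)")
  if (spec$n_trials > spec$runs * spec$trials_per_run) {
    stop_param("n_trials exceeds runs * trials_per_run")
  }
  if (length(trial_structure) != 3L || any(trial_structure <= 0)) {
    stop_param("trial_structure must be c(fixation, movie, response) > 0")
  }
  if (!is.null(edges)) {
    need <- c("roi_i", "roi_j", "base_r", "appeal_slope")
    if (!all(need %in% names(edges))) {
      stop_param("edges needs columns ", paste(need, collapse = ", "))
    }
    if (!all(edges$roi_i %in% roi_names) || !all(edges$roi_j %in% roi_names)) {
      stop_param("edge ROI names not in roi_names")
    }
    extreme <- pmax(abs(edges$base_r + 4 * edges$appeal_slope),
                    abs(edges$base_r + edges$appeal_slope))
    if (any(extreme >= 1)) {
      stop_param("infeasible edge correlation: |base_r + level*slope| must stay < 1")
    }
  }
  structure(spec, class = "bold_sim_spec")
}

#' Default ROI labels of the reference design
#'
#' Seven visual regions, five default-mode nodes and seven reward regions.
#' @return character vector of length 19.
#' @export
default_roi_names <- function() {
  c("pericalcarine", "FFA", "LO", "hMT", "OPA", "PPA", "RSC",
    "aMPFC", "dMPFC", "vMPFC", "PCC", "IPL",
    "NAc", "caudate", "putamen", "pallidum", "lOFC", "mOFC", "maOFC")
}

# Event table for one participant's session (run-relative onsets).
session_events <- function(spec, appeal_levels) {
  fix <- spec$trial_structure[1]; mov <- spec$trial_structure[2]
  resp <- spec$trial_structure[3]
  trial_len <- fix + mov + resp
  ev <- list()
  t_id <- 0L
  for (r in seq_len(spec$runs)) {
    for (k in seq_len(spec$trials_per_run)) {
      if (t_id >= spec$n_trials) break
      t_id <- t_id + 1L
      on <- spec$initial_blank_s + (k - 1) * trial_len + fix
      ev[[length(ev) + 1L]] <- data.frame(
        onset = c(on, on + mov), duration = c(mov, resp),
        trial_type = c("movie", "response"),
        trial_id = t_id, movie_id = sprintf("mov-%02d", t_id),
        appeal_level = c(appeal_levels[t_id], NA), run_id = r)
    }
  }
  do.call(rbind, ev)
}

#' Generate ROI BOLD bundles with known ground truth
#'
#' @param spec a [bold_sim_spec()].
#' @param appeal matrix (participants x trials) of appeal levels 1-4; by
#'   default a balanced random assignment per participant.
#' @return list with `bundles` (one [roi_bundle()] per participant) and
#'   `truth` (injected betas, edges, appeal matrix).
#' @export
gen_bold <- function(spec, appeal = NULL) {
  stopifnot(inherits(spec, "bold_sim_spec"))
  n_trials <- spec$n_trials
  if (is.null(appeal)) {
    appeal <- with_seed(derive_seed(spec$seed, 0L),
      t(replicate(spec$n_participants,
                  sample(rep_len(1:4, n_trials)))))
  }
  appeal <- matrix(as.integer(appeal), spec$n_participants, n_trials)
  if (!all(appeal %in% 1:4)) stop_param("appeal levels must be in 1..4")
  bundles <- lapply(seq_len(spec$n_participants), function(p) {
    gen_bold_one(spec, appeal[p, ], derive_seed(spec$seed, p))
  })
  names(bundles) <- sprintf("sub-%02d", seq_len(spec$n_participants))
  list(bundles = bundles,
       truth = list(baseline_beta = stats::setNames(spec$baseline_beta,
                                                    spec$roi_names),
                    appeal_slope = stats::setNames(spec$appeal_slope,
                                                   spec$roi_names),
                    response_beta = spec$response_beta,
                    edges = spec$edges, appeal = appeal))
}

gen_bold_one <- function(spec, levels, seed) {
  R <- length(spec$roi_names)
  trial_len <- sum(spec$trial_structure)
  run_dur <- spec$initial_blank_s + spec$trials_per_run * trial_len +
    spec$final_blank_s
  n_run <- as.integer(round(run_dur / spec$tr_s))
  n_tot <- n_run * spec$runs
  run <- rep(seq_len(spec$runs), each = n_run)
  events <- session_events(spec, levels)
  mv <- events[events$trial_type == "movie", ]
  resp <- events[events$trial_type == "response", ]

  # deterministic task signal via the same convolution path as the designs
  sig <- matrix(0, n_tot, R)
  base_reg <- numeric(n_tot)   # unit-amplitude movie regressor per trial sum
  lev_reg <- matrix(0, n_tot, 4L)
  for (r in seq_len(spec$runs)) {
    idx <- which(run == r)
    er <- mv[mv$run_id == r, ]
    for (lev in 1:4) {
      e <- er[er$appeal_level == lev, ]
      if (nrow(e)) {
        lev_reg[idx, lev] <- lev_reg[idx, lev] +
          convolve_events(e$onset, e$duration, n_run, spec$tr_s)
      }
    }
    rr <- resp[resp$run_id == r, ]
    base_reg[idx] <- convolve_events(rr$onset, rr$duration, n_run, spec$tr_s)
  }
  for (j in seq_len(R)) {
    amp <- spec$baseline_beta[j] + spec$appeal_slope[j] * (1:4)
    sig[, j] <- lev_reg %*% amp + spec$response_beta * base_reg
  }

  with_seed(seed, {
    noise <- matrix(stats::rnorm(n_tot * R), n_tot, R)
    if (!is.null(spec$edges) && nrow(spec$edges)) {
      wins <- select_trial_timepoints(events, spec$tr_s, run)
      for (k in seq_len(nrow(spec$edges))) {
        i <- match(spec$edges$roi_i[k], spec$roi_names)
        j <- match(spec$edges$roi_j[k], spec$roi_names)
        for (t in seq_along(wins)) {
          rho <- spec$edges$base_r[k] +
            spec$edges$appeal_slope[k] * levels[t]
          w <- wins[[t]]
          noise[w, j] <- rho * noise[w, i] +
            sqrt(1 - rho^2) * stats::rnorm(length(w))
        }
      }
    }
    if (spec$ar1_phi > 0) {
      for (r in seq_len(spec$runs)) {
        idx <- which(run == r)
        noise[idx, ] <- apply(noise[idx, , drop = FALSE], 2, function(e) {
          as.numeric(stats::filter(e * sqrt(1 - spec$ar1_phi^2),
                                   spec$ar1_phi, method = "recursive"))
        })
      }
    }
    drift <- matrix(0, n_tot, R)
    if (spec$drift_amp > 0) {
      tt <- (seq_len(n_run) - 1) * spec$tr_s
      for (r in seq_len(spec$runs)) {
        ph <- stats::runif(R, 0, 2 * pi)
        per <- stats::runif(R, 200, 400)
        drift[run == r, ] <- sapply(seq_len(R), function(j) {
          spec$drift_amp * cos(2 * pi * tt / per[j] + ph[j])
        })
      }
    }
    Y <- sig + spec$noise_sd * noise + drift
    colnames(Y) <- spec$roi_names
    conf <- sim_confounds(n_tot, run)
    roi_bundle(Y, run, spec$tr_s, events = events, confounds = conf)
  })
}

# fMRIPrep-style confound table: slow random-walk motion parameters with
# occasional spikes, FD derived from them, standardized DVARS, and six
# aCompCor components.
sim_confounds <- function(n, run) {
  motion <- sapply(1:6, function(j) cumsum(stats::rnorm(n, 0, 0.02)))
  spikes <- which(stats::runif(n) < 0.01)
  if (length(spikes)) motion[spikes, ] <- motion[spikes, ] +
    matrix(stats::rnorm(length(spikes) * 6, 0, 0.4), length(spikes), 6)
  colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                        "rot_x", "rot_y", "rot_z")
  fd <- numeric(n)
  for (r in unique(run)) {
    idx <- which(run == r)
    fd[idx[-1]] <- rowSums(abs(diff(motion[idx, , drop = FALSE])))
  }
  dvars <- stats::rnorm(n)
  acc <- sapply(1:6, function(j) stats::rnorm(n))
  colnames(acc) <- sprintf("a_comp_cor_%02d", 0:5)
  data.frame(motion, framewise_displacement = fd, std_dvars = dvars, acc)
}

#' Specification for the translating-texture frame generator
#'
#' @param n_frames number of frames (>= 1).
#' @param height,width frame size in pixels.
#' @param speed_px_per_frame scalar or length `n_frames - 1` vector of
#'   nonnegative per-frame horizontal translation magnitudes (subpixel
#'   allowed, toroidal wrap).
#' @param band radial spatial-frequency pass band in cycles/pixel used to
#'   band-pass the noise texture.
#' @param texture_seed integer seed.
#' @return object of class `"frame_sim_spec"`.
#' @export
frame_sim_spec <- function(n_frames, height, width, speed_px_per_frame = 0,
                           band = c(0.02, 0.15), texture_seed = 1) {
  n_frames <- check_count(n_frames, "n_frames")
  height <- check_count(height, "height")
  width <- check_count(width, "width")
  sp <- rep_len(speed_px_per_frame, max(1L, n_frames - 1L))
  if (any(sp < 0)) stop_param("speeds must be nonnegative")
  structure(list(n_frames = n_frames, height = height, width = width,
                 speed = sp, band = band,
                 texture_seed = check_count(texture_seed, "texture_seed", 0L)),
            class = "frame_sim_spec")
}

# Toroidal subpixel horizontal shift via an FFT phase ramp.
shift_image <- function(img, dx) {
  n <- ncol(img)
  fx <- c(0, seq_len(n - 1)) / n
  fx[fx > 0.5] <- fx[fx > 0.5] - 1
  ramp <- exp(-2i * pi * dx * fx)
  out <- t(apply(img, 1, function(row) {
    Re(stats::fft(stats::fft(row) * ramp, inverse = TRUE)) / n
  }))
  out
}

#' Generate a translating band-pass noise frame stack
#'
#' A band-pass filtered noise texture is translated horizontally
#' frame-to-frame by the stated per-frame speed (toroidal wrap, subpixel
#' shifts through Fourier interpolation). Frames are grayscale in \[0, 1\].
#'
#' @param spec a [frame_sim_spec()].
#' @return numeric array height x width x n_frames.
#' @export
gen_frames <- function(spec) {
  stopifnot(inherits(spec, "frame_sim_spec"))
  with_seed(spec$texture_seed, {
    tex <- matrix(stats::rnorm(spec$height * spec$width),
                  spec$height, spec$width)
    fy <- c(0, seq_len(spec$height - 1)) / spec$height
    fy <- pmin(fy, 1 - fy)
    fx <- c(0, seq_len(spec$width - 1)) / spec$width
    fx <- pmin(fx, 1 - fx)
    rad <- sqrt(outer(fy^2, fx^2, `+`))
    keep <- rad >= spec$band[1] & rad <= spec$band[2]
    tex <- Re(stats::fft(stats::fft(tex) * keep, inverse = TRUE)) /
      length(tex)
    rng <- range(tex)
    tex <- (tex - rng[1]) / (rng[2] - rng[1])
    out <- array(0, c(spec$height, spec$width, spec$n_frames))
    out[, , 1] <- tex
    shift <- 0
    if (spec$n_frames > 1) for (k in 2:spec$n_frames) {
      shift <- shift + spec$speed[k - 1]
      out[, , k] <- pmin(1, pmax(0, shift_image(tex, shift)))
    }
    out
  })
}
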