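# Canonical double-gamma HRF and event-regressor convolution, shared by the
# activation GLM, the trial-window selection, the connectivity denoiser and
# the BOLD simulator (so noiseless simulations are exactly identifiable).

#' Canonical double-gamma hemodynamic response function
#'
#' SPM-style canonical HRF: a gamma density peaking near 5-6 s minus a
#' scaled gamma undershoot peaking near 15-16 s, peak-normalized to 1
#' (the peak is located on a dense internal grid so normalization does not
#' depend on the sampling grid).
#'
#' @param t_grid nonnegative, regularly spaced time points (seconds).
#' @param peak_delay,under_delay delays of response and undershoot (s);
#'   defaults 6 and 16.
#' @param peak_disp,under_disp dispersions (s); defaults 1 and 1.
#' @param ratio undershoot ratio, default 1/6.
#' @return numeric vector, h evaluated on `t_grid` with max(h) = 1.
#' @export
canonical_hrf <- function(t_grid, peak_delay = 6, under_delay = 16,
                          peak_disp = 1, under_disp = 1, ratio = 1 / 6) {
  if (any(t_grid < 0)) stop_param("`t_grid` must be nonnegative")
  if (peak_disp <= 0 || under_disp <= 0) stop_param("dispersions must be positive")
  raw <- function(t) {
    stats::dgamma(t, shape = peak_delay / peak_disp, scale = peak_disp) -
      ratio * stats::dgamma(t, shape = under_delay / under_disp, scale = under_disp)
  }
  key <- paste("pk", peak_delay, under_delay, peak_disp, under_disp, ratio)
  peak <- .hrf_cache[[key]]
  if (is.null(peak)) {
    peak <- max(raw(seq(0, peak_delay + under_delay, by = 0.01)))
    .hrf_cache[[key]] <- peak
  }
  raw(t_grid) / peak
}

# memoised HRF samples for convolution, rescaled to unit integral so that a
# sustained boxcar of amplitude a plateaus at a (betas keep amplitude units
# regardless of block length or grid resolution)
.hrf_cache <- new.env(parent = emptyenv())

hrf_samples <- function(dt, hrf_params = list()) {
  key <- paste("h", dt, paste(unlist(hrf_params), collapse = ","))
  h <- .hrf_cache[[key]]
  if (is.null(h)) {
    h <- do.call(canonical_hrf,
                 c(list(t_grid = seq(0, 32, by = dt)), hrf_params))
    h <- h / (sum(h) * dt)
    .hrf_cache[[key]] <- h
  }
  h
}

# Convolve boxcar events with the canonical HRF at TR resolution, using a
# x10 oversampled grid then decimating to scan times (scan i at t=(i-1)*TR).
# onsets/durations in seconds relative to the run start; amplitudes scale
# each event's boxcar. Returns a length-n_scans regressor.
convolve_events <- function(onsets, durations, n_scans, tr,
                            amplitudes = NULL, oversample = 10L,
                            hrf_params = list()) {
  if (is.null(amplitudes)) amplitudes <- rep(1, length(onsets))
  dt <- tr / oversample
  n_hi <- n_scans * oversample
  box <- numeric(n_hi)
  for (k in seq_along(onsets)) {
    i0 <- floor(onsets[k] / dt) + 1L
    i1 <- min(n_hi, ceiling((onsets[k] + durations[k]) / dt))
    if (i0 > n_hi) stop_param("event onset beyond scan duration")
    box[i0:i1] <- box[i0:i1] + amplitudes[k]
  }
  h <- hrf_samples(dt, hrf_params)
  conv <- stats::convolve(box, rev(h), type = "open")[seq_len(n_hi)] * dt
  conv[seq(1L, n_hi, by = oversample)]
}

# Discrete-cosine high-pass basis: DCT regressors with frequency below
# `cutoff_hz` for a run of n scans at the given TR (excluding the constant).
dct_basis <- function(n, tr, cutoff_hz) {
  dur <- n * tr
  k_max <- floor(2 * dur * cutoff_hz)
  if (k_max < 1L) return(matrix(numeric(0), n, 0))
  t <- seq_len(n) - 0.5
  sapply(seq_len(k_max), function(k) cos(pi * k * t / n))
}
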