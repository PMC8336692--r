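# Gabor-jet motion energy: a simple-cell jet model (quadrature Gabor
# magnitudes on a spatial grid) applied per frame, with framewise jet
# differences as the motion-energy trace.

#' Build a Gabor-jet filter bank
#'
#' Complex (quadrature-pair) Gabor kernels at every scale x orientation,
#' evaluated on a regular spatial grid. Kernels are made exactly zero-mean
#' by subtracting a scaled Gaussian envelope, so a constant frame yields a
#' zero jet. Defaults follow the simple-cell jet literature: 5 scales with
#' wavelengths log-spaced 4-32 px, 8 orientations, a 12 x 12 grid, and an
#' envelope of about half a wavelength.
#'
#' @param scales number of scales (ignored when `wavelengths` given).
#' @param orientations number of orientations (evenly spaced over pi).
#' @param grid c(rows, cols) of evaluation points.
#' @param wavelengths wavelengths in pixels per scale.
#' @param bandwidth envelope width as a fraction of wavelength
#'   (sigma = bandwidth * lambda), default 0.56 (~1 octave).
#' @return object of class `"gabor_bank"`: list of complex kernel matrices
#'   plus layout metadata. Jet dimension = scales * orientations *
#'   grid rows * grid cols.
#' @export
build_gabor_bank <- function(scales = 5, orientations = 8, grid = c(12, 12),
                             wavelengths = NULL, bandwidth = 0.56) {
  orientations <- check_count(orientations, "orientations")
  if (is.null(wavelengths)) {
    scales <- check_count(scales, "scales")
    wavelengths <- exp(seq(log(4), log(32), length.out = scales))
  }
  scales <- length(wavelengths)
  if (any(wavelengths <= 0)) stop_param("wavelengths must be positive")
  thetas <- (seq_len(orientations) - 1) * pi / orientations
  kernels <- list()
  for (s in seq_len(scales)) {
    lambda <- wavelengths[s]
    sigma <- bandwidth * lambda
    half <- ceiling(2.5 * sigma)
    ax <- -half:half
    gx <- outer(rep(1, length(ax)), ax)
    gy <- outer(ax, rep(1, length(ax)))
    env <- exp(-(gx^2 + gy^2) / (2 * sigma^2))
    for (o in seq_len(orientations)) {
      th <- thetas[o]
      carrier <- exp(2i * pi * (gx * cos(th) + gy * sin(th)) / lambda)
      k <- env * carrier
      k <- k - env * (sum(k) / sum(env))    # exact zero DC
      kernels[[length(kernels) + 1L]] <- k
    }
  }
  structure(list(kernels = kernels, wavelengths = wavelengths,
                 orientations = orientations, thetas = thetas,
                 grid = as.integer(grid), bandwidth = bandwidth),
            class = "gabor_bank")
}

#' @export
print.gabor_bank <- function(x, ...) {
  cat(sprintf("Gabor-jet bank: %d scales x %d orientations, %d x %d grid (jet dim %d)\n",
              length(x$wavelengths), x$orientations, x$grid[1], x$grid[2],
              jet_dim(x)))
  cat("  wavelengths (px):", paste(round(x$wavelengths, 2), collapse = ", "), "\n")
  invisible(x)
}

jet_dim <- function(bank) {
  length(bank$kernels) * prod(bank$grid)
}

grid_points <- function(bank, h, w) {
  gi <- round(seq(1, h, length.out = bank$grid[1] + 2))[-c(1, bank$grid[1] + 2)]
  gj <- round(seq(1, w, length.out = bank$grid[2] + 2))[-c(1, bank$grid[2] + 2)]
  list(i = gi, j = gj)
}

#' Compute the Gabor jet of one frame
#'
#' Filters the frame with every kernel of the bank (circular convolution
#' via FFT) and returns the complex-modulus responses at the grid points:
#' the "jet" vector. Magnitude responses make the jet invariant to global
#' luminance offsets and insensitive to phase shifts.
#'
#' @param frame grayscale matrix (any real range).
#' @param bank a [build_gabor_bank()].
#' @return numeric jet vector of length scales * orientations * grid points.
#' @export
frame_jet <- function(frame, bank) {
  frame <- as.matrix(frame)
  if (any(!is.finite(frame))) stop_param("frame contains non-finite pixels")
  h <- nrow(frame); w <- ncol(frame)
  ksize <- vapply(bank$kernels, nrow, integer(1))
  if (max(ksize) > min(h, w)) {
    stop_param("frame smaller than the largest kernel (",
               max(ksize), " px); reduce the longest wavelength")
  }
  gp <- grid_points(bank, h, w)
  ff <- stats::fft(frame)
  out <- numeric(0)
  for (k in bank$kernels) {
    half <- (nrow(k) - 1L) %/% 2L
    pad <- matrix(0 + 0i, h, w)
    ri <- ((-half:half) %% h) + 1L
    ci <- ((-half:half) %% w) + 1L
    pad[ri, ci] <- k
    resp <- stats::fft(ff * Conj(stats::fft(pad)), inverse = TRUE) / (h * w)
    out <- c(out, as.vector(Mod(resp[gp$i, gp$j])))
  }
  out
}

#' Motion-energy trace of a frame stack
#'
#' ME(t) = norm of the jet difference between consecutive frames, one
#' value per frame transition.
#'
#' @param frames array h x w x n (a 4-D array is channel-averaged to
#'   grayscale first) or list of matrices.
#' @param bank a [build_gabor_bank()].
#' @param native_rate frames per second (for later resampling).
#' @param norm `"L2"` (default) or `"L1"` jet difference.
#' @return object of class `"motion_energy_trace"`: `values`
#'   (length n - 1, nonnegative), `native_rate`.
#' @export
motion_energy_trace <- function(frames, bank, native_rate = 30,
                                norm = c("L2", "L1")) {
  norm <- match.arg(norm)
  if (is.list(frames)) frames <- simplify2array(frames)
  if (length(dim(frames)) == 4L) {
    frames <- apply(frames, c(1, 2, 4), mean)    # channel mean -> grayscale
  }
  n <- dim(frames)[3]
  if (is.na(n) || n < 2L) stop_param("need at least 2 frames")
  jets <- vapply(seq_len(n), function(k) frame_jet(frames[, , k], bank),
                 numeric(jet_dim(bank)))
  d <- diff(t(jets))
  values <- if (norm == "L2") sqrt(rowSums(d^2)) else rowSums(abs(d))
  structure(list(values = values, native_rate = native_rate),
            class = "motion_energy_trace")
}

#' Resample a motion-energy trace by block means
#'
#' Non-overlapping block means down to `target_hz` (native rate must be an
#' integer multiple), as for the rating traces; the movie-level mean is
#' also returned for correlation with overall ratings.
#'
#' @param trace a `"motion_energy_trace"`.
#' @param target_hz target rate, default 10.
#' @return the trace resampled, with an added `movie_mean` field.
#' @export
resample_me <- function(trace, target_hz = 10) {
  stopifnot(inherits(trace, "motion_energy_trace"))
  if (trace$native_rate < target_hz) stop_param("native rate below target")
  v <- downsample_trace(trace$values, target_hz, rate_hz = trace$native_rate)
  structure(list(values = v, native_rate = target_hz,
                 movie_mean = mean(v)),
            class = "motion_energy_trace")
}
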