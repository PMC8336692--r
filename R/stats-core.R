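#' Fisher-z mean and confidence interval for a sample of correlations
#'
#' Transforms correlation coefficients to Fisher z (`atanh`), computes the
#' mean and a 95% confidence interval in z space, and transforms back to r.
#' This is the standard way to summarise per-participant agreement scores at
#' the group level. Two CI constructions are offered: `"t"` (default)
#' treats the participants as the sample and uses a t-based CI on the z
#' values; `"se"` uses the large-sample per-correlation standard error
#' 1/sqrt(n_obs - 3) and requires `n_obs`.
#'
#' @param r numeric vector of correlation coefficients (NAs dropped).
#' @param conf confidence level, default 0.95.
#' @param method `"t"` or `"se"`.
#' @param n_obs number of observations behind each r; needed for
#'   `method = "se"`.
#' @return an object of class `"fisher_summary"`: list with `mean_r`,
#'   `ci_low`, `ci_high`, `mean_z`, `n`, `r` (clipped input), and
#'   `clipped` flag.
#' @export
fisher_mean_ci <- function(r, conf = 0.95, method = c("t", "se"), n_obs = NULL) {
  method <- match.arg(method)
  r <- r[!is.na(r)]
  if (length(r) < 2L) stop_param("need at least 2 correlation values")
  if (any(abs(r) > 1)) stop_param("correlations must lie in [-1, 1]")
  cl <- clip_r(r)
  z <- atanh(cl$r)
  n <- length(z)
  mz <- mean(z)
  if (method == "t") {
    sez <- stats::sd(z) / sqrt(n)
    half <- stats::qt(1 - (1 - conf) / 2, df = n - 1) * sez
  } else {
    if (is.null(n_obs)) stop_param("`n_obs` required for method = \"se\"")
    if (n_obs <= 3) stop_param("`n_obs` must exceed 3 for the SE-based CI")
    sez <- 1 / sqrt(n_obs - 3) / sqrt(n)
    half <- stats::qnorm(1 - (1 - conf) / 2) * sez
  }
  structure(list(mean_r = tanh(mz), ci_low = tanh(mz - half),
                 ci_high = tanh(mz + half), mean_z = mz, n = n,
                 r = cl$r, clipped = cl$clipped),
            class = "fisher_summary")
}

#' @export
print.fisher_summary <- function(x, ...) {
  cat(sprintf("Fisher-z group summary (n = %d)\n", x$n))
  cat(sprintf("  mean r = %.3f, 95%% CI [%.3f, %.3f]\n",
              x$mean_r, x$ci_low, x$ci_high))
  if (x$clipped) cat("  note: some |r| clipped to 1 - 1e-7\n")
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up BH procedure: q-values are p * m / rank with a reverse cumulative
#' minimum to enforce monotonicity; the rejection set at level `q_level`
#' contains all tests up to the largest rank k with p_(k) <= k/m * q_level.
#'
#' @param p vector of p-values in \[0, 1\].
#' @param q_level FDR level, default 0.05.
#' @return list with `q` (same order as input) and `reject` (logical).
#' @export
bh_fdr <- function(p, q_level = 0.05) {
  if (any(!is.finite(p))) stop_param("p-values must be finite")
  if (any(p < 0 | p > 1)) stop_param("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  q_sorted <- rev(cummin(rev(ranked * m / seq_len(m))))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  # step-up rejection: largest k with p_(k) <= k/m * alpha
  ok <- ranked <= seq_len(m) / m * q_level
  k <- if (any(ok)) max(which(ok)) else 0L
  reject <- logical(m)
  if (k > 0L) reject[o[seq_len(k)]] <- TRUE
  list(q = q, reject = reject)
}

#' Bonferroni correction
#'
#' @param p vector of p-values.
#' @param alpha family-wise error level, default 0.05.
#' @return logical rejection vector (p < alpha / m).
#' @export
bonferroni <- function(p, alpha = 0.05) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop_param("p-values must be finite and in [0, 1]")
  }
  p < alpha / length(p)
}

#' One-sample and paired t tests with a zero-variance guard
#'
#' Thin wrappers around [stats::t.test()] that flag the degenerate
#' zero-variance case (all values identical) instead of erroring: the
#' statistic is reported as +/-Inf (or 0 when the mean equals `mu`) with
#' `degenerate = TRUE`.
#'
#' @param x numeric values.
#' @param mu null mean, default 0.
#' @return list with `t`, `p`, `dof`, `mean`, `degenerate`.
#' @export
one_sample_t <- function(x, mu = 0) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2L) stop_param("need at least 2 values")
  if (stats::sd(x) <= 1e-10 * max(abs(x), 1)) {   # numerically constant
    d <- mean(x) - mu
    return(list(t = if (d == 0) 0 else sign(d) * Inf,
                p = if (d == 0) 1 else 0,
                dof = n - 1L, mean = mean(x), degenerate = TRUE))
  }
  tt <- stats::t.test(x, mu = mu)
  list(t = unname(tt$statistic), p = tt$p.value,
       dof = unname(tt$parameter), mean = mean(x), degenerate = FALSE)
}

#' @rdname one_sample_t
#' @param a,b paired samples of equal length.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stop_param("paired samples must have equal length")
  keep <- !is.na(a) & !is.na(b)
  one_sample_t(a[keep] - b[keep], mu = 0)
}
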