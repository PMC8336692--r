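# Internal helpers shared across modules.

# Derive a reproducible child seed from a root seed and a stream index.
# Keeps results parallel-safe across participants without sharing one RNG
# stream; stays below .Machine$integer.max.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(stream)) %% 2147483647L)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

stop_param <- function(...) stop(..., call. = FALSE)

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_param(sprintf("`%s` must be TRUE or FALSE", name))
  }
  x
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    stop_param(sprintf("`%s` must be an integer >= %d", name, min))
  }
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      (strict && x <= min) || (!strict && x < min)) {
    stop_param(sprintf("`%s` must be a finite number %s %s", name,
                       if (strict) ">" else ">=", format(min)))
  }
  as.numeric(x)
}

# Clip correlations away from +/-1 before the Fisher transform; returns the
# clipped values and whether any clipping happened (degeneracy flag).
clip_r <- function(r, eps = 1e-7) {
  clipped <- abs(r) > 1 - eps & !is.na(r)
  r[clipped] <- sign(r[clipped]) * (1 - eps)
  list(r = r, clipped = any(clipped))
}

# Column-wise Pearson correlation of one vector against each column of m,
# returning NA for zero-variance columns instead of erroring.
safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}
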