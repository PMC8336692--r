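# Independent oracle implementations used to cross-check the package:
# deliberately literal, loop-based, and sharing no code with R/.

# Leave-one-out agreement by explicit loops over a movies x participants
# matrix of ratings.
oracle_mm1 <- function(mat) {
  out <- numeric(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    others <- mat[, -j, drop = FALSE]
    avg <- apply(others, 1, mean)
    out[j] <- stats::cor(mat[, j], avg)
  }
  out
}

# BH step-up by literal sorting.
oracle_bh <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  thresh <- (seq_len(m) / m) * alpha
  below <- which(sorted <= thresh)
  reject <- rep(FALSE, m)
  if (length(below)) reject[o[seq_len(max(below))]] <- TRUE
  q <- rep(NA_real_, m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, sorted[i] * m / i)
    q[o[i]] <- min(1, running)
  }
  list(q = q, reject = reject)
}

# Naive MTD: explicit loops over time, ROI pairs and the smoothing window.
oracle_mtd <- function(ts, w) {
  dt <- apply(ts, 2, diff)
  sig <- sqrt(colMeans(dt^2))
  R <- ncol(ts); n <- nrow(dt)
  pairs <- utils::combn(R, 2)
  raw <- matrix(NA_real_, n, ncol(pairs))
  for (e in seq_len(ncol(pairs))) {
    i <- pairs[1, e]; j <- pairs[2, e]
    for (t in seq_len(n)) {
      raw[t, e] <- dt[t, i] * dt[t, j] / (sig[i] * sig[j])
    }
  }
  sm <- raw
  for (e in seq_len(ncol(pairs))) {
    for (t in seq_len(n)) {
      lo <- max(1, t - w); hi <- min(n, t + w)
      sm[t, e] <- mean(raw[lo:hi, e])
    }
  }
  list(raw = raw, mtd = sm)
}

# Direct per-trial correlation loop for the trial-FC stack.
oracle_trial_fc <- function(ts, trial_idx) {
  R <- ncol(ts)
  pairs <- utils::combn(R, 2)
  z <- matrix(NA_real_, length(trial_idx), ncol(pairs))
  for (t in seq_along(trial_idx)) {
    seg <- ts[trial_idx[[t]], ]
    for (e in seq_len(ncol(pairs))) {
      r <- stats::cor(seg[, pairs[1, e]], seg[, pairs[2, e]])
      r <- max(min(r, 1 - 1e-7), -(1 - 1e-7))
      z[t, e] <- atanh(r)
    }
  }
  z
}

# Small complete rating table without repeats.
make_rating_table <- function(mat) {
  movies <- sprintf("m%02d", seq_len(nrow(mat)))
  parts <- sprintf("p%02d", seq_len(ncol(mat)))
  rating_table(data.frame(
    participant_id = rep(parts, each = nrow(mat)),
    movie_id = rep(movies, ncol(mat)),
    presentation = 1L,
    rating = as.vector(mat)))
}

# Minimal single-run event table.
make_events <- function(onsets, duration = 30, response = TRUE, run_id = 1L,
                        levels = NULL) {
  ev <- data.frame(onset = onsets, duration = duration, trial_type = "movie",
                   trial_id = seq_along(onsets),
                   appeal_level = levels %||% rep_len(1:4, length(onsets)),
                   run_id = run_id)
  if (response) {
    resp <- data.frame(onset = onsets + duration, duration = 4,
                       trial_type = "response", trial_id = seq_along(onsets),
                       appeal_level = NA, run_id = run_id)
    ev <- rbind(ev, resp)
    ev <- ev[order(ev$onset), ]
  }
  ev
}

`%||%` <- function(a, b) if (is.null(a)) b else a
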