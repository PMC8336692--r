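# Canonical HRF, preprocessing, design construction, GLM fitting and
# group contrasts.

test_that("canonical HRF has the double-gamma shape", {
  expect_equal(canonical_hrf(0), 0)
  dense <- seq(0, 40, by = 0.1)
  h <- canonical_hrf(dense)
  expect_equal(max(h), 1, tolerance = 1e-6)          # peak-normalized
  expect_lt(abs(dense[which.max(h)] - 5), 0.11)      # mode of gamma(6,1)
  expect_lt(max(abs(h[dense > 30])), 0.01)           # late tail < 1% of peak
  # integral: densities integrate to 1 and 1/6, normalized by the raw peak
  raw_peak <- max(dgamma(dense, 6, 1) - dgamma(dense, 16, 1) / 6)
  expect_equal(sum(h) * 0.1, (1 - 1 / 6) / raw_peak, tolerance = 1e-2)
  expect_error(canonical_hrf(0:10, peak_disp = 0), "dispersions")
  expect_error(canonical_hrf(-1:5), "nonnegative")
})

test_that("event convolution matches a direct-sum oracle and has HRF lag", {
  n <- 40; tr <- 2
  reg <- aestheticfmri:::convolve_events(10, 30, n, tr)
  # oracle: direct Riemann sum of h over the boxcar at fine resolution
  dt <- 0.01
  tt <- (seq_len(n) - 1) * tr
  u <- seq(0, 32, by = dt)
  h_unit <- canonical_hrf(u) / (sum(canonical_hrf(u)) * dt)  # unit integral
  orc <- sapply(tt, function(t) {
    sum(h_unit * (t - u >= 10 & t - u < 40)) * dt
  })
  expect_gt(cor(reg, orc), 0.999)
  expect_equal(reg, orc, tolerance = 0.02)
  expect_true(all(abs(reg[tt < 10]) < 1e-10))  # support starts at onset
  expect_gt(sum(reg > 0.1), 15)              # positive for > 15 TRs
})

test_that("preprocess_roi filters, detrends and z-scores per run", {
  tr <- 2; n <- 200
  tt <- (seq_len(n) - 1) * tr
  slow <- sin(2 * pi * 0.003 * tt)            # below the 0.01 Hz cutoff
  fast <- rnorm(n)
  b <- roi_bundle(cbind(slow = slow + fast * 0.01, fast = fast),
                  rep(1L, n), tr)
  out <- preprocess_roi(b, zscore = FALSE)
  expect_lt(var(out$ts[, "slow"]), 0.01 * var(slow))
  outz <- preprocess_roi(b)
  expect_equal(colMeans(outz$ts), c(slow = 0, fast = 0), tolerance = 1e-10)
  expect_equal(apply(outz$ts, 2, sd), c(slow = 1, fast = 1), tolerance = 1e-10)
  short <- roi_bundle(matrix(rnorm(20), 10), rep(1L, 10), 2)
  expect_warning(preprocess_roi(short), "high-pass skipped")
})

test_that("build_design has the documented column layout and errors", {
  ev <- make_events(c(10, 54, 98, 142), levels = c(1, 2, 3, 4))
  n <- 100
  d <- build_design(ev, 2, rep(1L, n))
  expect_equal(colnames(d$X), c(paste0("level_", 1:4), "response", "run_1"))
  ev2 <- ev; ev2$appeal_level[ev2$trial_type == "movie"][2] <- NA
  expect_error(build_design(ev2, 2, rep(1L, n)), "appeal level missing")
  ev3 <- make_events(c(10, 54, 98, 142), levels = c(1, 1, 3, 4))
  expect_error(build_design(ev3, 2, rep(1L, n)), "level 2")
  ev4 <- make_events(1000)
  expect_error(build_design(ev4, 2, rep(1L, n)), "exceeds scan duration")
})

test_that("fit_glm is exact on noiseless data and linear", {
  set.seed(10)
  X <- cbind(1, rnorm(50), rnorm(50))
  colnames(X) <- c("a", "b", "c")
  b0 <- matrix(c(1, -2, 0.5, 3, 0, 1), 3, 2)
  Y <- X %*% b0
  fit <- fit_glm(Y, X)
  expect_equal(unname(fit$betas), unname(b0), tolerance = 1e-10)
  fit2 <- fit_glm(2 * Y, X)
  expect_equal(unname(fit2$betas), unname(2 * b0), tolerance = 1e-10)
  # noise orthogonal to the design has zero betas
  e <- residuals(lm(rnorm(50) ~ X - 1))
  fit3 <- fit_glm(cbind(e), X)
  expect_lt(max(abs(fit3$betas)), 1e-10)
  Xbad <- cbind(X, d = X[, "b"])
  expect_error(fit_glm(Y, Xbad), "collinear")
})

test_that("contrast weights have the canonical structure", {
  w41 <- aestheticfmri:::contrast_weights("4v1")
  expect_equal(sum(w41), 0)
  w4321 <- aestheticfmri:::contrast_weights("4v321")
  expect_equal(sum(w4321), 0)
  expect_equal(w4321[["level_4"]], 1)
  wmv <- aestheticfmri:::contrast_weights("movies_vs_baseline")
  expect_equal(sum(wmv), 1)
  expect_equal(sum(aestheticfmri:::contrast_weights("movies_vs_baseline",
                                                    "sum")), 4)
})

test_that("contrast_test aggregates per-participant effects with Bonferroni", {
  # build fits directly: 2 ROIs, one with a real 4v1 effect
  set.seed(20)
  fits <- lapply(1:12, function(p) {
    betas <- matrix(rnorm(10, 0, 0.05), 5, 2,
                    dimnames = list(c(paste0("level_", 1:4), "response"),
                                    c("roiA", "roiB")))
    betas["level_4", "roiA"] <- betas["level_1", "roiA"] + 1
    structure(list(betas = betas, sigma2 = c(1, 1), dof = 100,
                   regressors = rownames(betas)), class = "glm_fit")
  })
  res <- contrast_test(fits, "4v1")
  expect_true(res$bonferroni_sig[res$roi == "roiA"])
  expect_false(res$bonferroni_sig[res$roi == "roiB"])
  expect_error(contrast_test(fits[1:2], "4v1"), "3 participants")

  # identical nonzero effects across participants: degenerate flag, finite p
  fits_const <- lapply(1:5, function(p) {
    betas <- matrix(0, 5, 1, dimnames = list(c(paste0("level_", 1:4),
                                               "response"), "roi"))
    betas["level_4", 1] <- 1
    structure(list(betas = betas, sigma2 = 1, dof = 100,
                   regressors = rownames(betas)), class = "glm_fit")
  })
  res2 <- contrast_test(fits_const, "4v1")
  expect_true(res2$degenerate)
  expect_equal(res2$group_t, Inf)
})

test_that("beta series equals trial amplitudes and level means on noiseless data", {
  bs <- bold_sim_spec(n_participants = 1, roi_names = c("A", "B"), runs = 2,
                      trials_per_run = 4, baseline_beta = c(1, 2),
                      appeal_slope = c(0.5, -0.25), ar1_phi = 0,
                      drift_amp = 0, noise_sd = 0, seed = 30)
  lev <- c(2, 4, 1, 3, 3, 1, 4, 2)
  sim <- gen_bold(bs, matrix(lev, 1))
  b <- sim$bundles[[1]]
  bser <- beta_series(b$ts, b$events, b$tr_s, b$run)
  for (i in seq_along(lev)) {
    expect_equal(unname(bser$betas[i, ]),
                 unname(sim$truth$baseline_beta +
                          sim$truth$appeal_slope * lev[i]),
                 tolerance = 1e-8)
  }
  # level means of trial betas equal the level-GLM betas
  fit <- fit_glm(b$ts, build_design(b$events, b$tr_s, b$run))
  for (l in 1:4) {
    expect_equal(colMeans(bser$betas[bser$appeal_level == l, , drop = FALSE]),
                 fit$betas[paste0("level_", l), ], tolerance = 1e-6)
  }
  # permuting trial labels permutes rows identically
  ev_perm <- b$events
  mv_rows <- which(ev_perm$trial_type == "movie")
  bser2 <- beta_series(b$ts, b$events, b$tr_s, b$run)
  expect_identical(bser$betas, bser2$betas)
})

test_that("noiseless end-to-end recovery preserves appeal-slope ordering", {
  bs <- bold_sim_spec(n_participants = 1, roi_names = c("up", "flat", "down"),
                      runs = 2, trials_per_run = 5, baseline_beta = 1,
                      appeal_slope = c(0.4, 0, -0.4), ar1_phi = 0,
                      drift_amp = 0, noise_sd = 0, seed = 44)
  sim <- gen_bold(bs, matrix(rep_len(1:4, 10), 1))
  b <- sim$bundles[[1]]
  pp <- preprocess_roi(b)
  fit <- fit_glm(pp$ts, build_design(b$events, b$tr_s, b$run))
  eff <- fit$betas["level_4", ] - fit$betas["level_1", ]
  expect_true(eff["up"] > eff["flat"] && eff["flat"] > eff["down"])
})
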