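# Denoising, trial-window selection, trial-wise FC, appeal regression,
# group edge tests and MTD.

make_noise_bundle <- function(n = 364, R = 3, tr = 2, seed = 1,
                              events = NULL) {
  set.seed(seed)
  ts <- matrix(rnorm(n * R), n, R,
               dimnames = list(NULL, paste0("roi", seq_len(R))))
  run <- rep(1:2, each = n / 2)
  conf <- data.frame(
    trans_x = rnorm(n, 0, 0.01), trans_y = rnorm(n, 0, 0.01),
    trans_z = rnorm(n, 0, 0.01), rot_x = rnorm(n, 0, 0.01),
    rot_y = rnorm(n, 0, 0.01), rot_z = rnorm(n, 0, 0.01),
    framewise_displacement = abs(rnorm(n, 0.1, 0.05)),
    std_dvars = rnorm(n),
    a_comp_cor_00 = rnorm(n), a_comp_cor_01 = rnorm(n),
    a_comp_cor_02 = rnorm(n), a_comp_cor_03 = rnorm(n),
    a_comp_cor_04 = rnorm(n), a_comp_cor_05 = rnorm(n))
  roi_bundle(ts, run, tr, events = events, confounds = conf)
}

test_that("denoise removes injected confounds and censors high-motion frames", {
  b <- make_noise_bundle(seed = 3)
  b$ts[, 1] <- b$ts[, 1] + 5 * b$confounds$a_comp_cor_02
  b$confounds$framewise_displacement[c(40, 41)] <- 1.2
  # regression stage alone leaves residuals exactly orthogonal to the
  # injected confound; the spike regressor zeroes the censored frame
  reg_only <- denoise(b, denoise_spec(band = NULL, regress_task = FALSE))
  expect_lt(abs(cor(reg_only$ts[, 1], b$confounds$a_comp_cor_02)), 1e-6)
  expect_true(all(reg_only$censor[c(40, 41)]))
  expect_lt(max(abs(reg_only$ts[40, ])), 1e-10)
  # the zero-phase band-pass afterwards mixes timepoints, so only a small
  # sampling-level correlation can reappear
  out <- denoise(b, denoise_spec(regress_task = FALSE))
  expect_lt(abs(cor(out$ts[, 1], b$confounds$a_comp_cor_02)), 0.1)
})

test_that("band-pass response passes 0.1 Hz and attenuates out-of-band sinusoids", {
  tr <- 0.5; n <- 4000     # fine sampling so 0.4 Hz sits below Nyquist
  tt <- (seq_len(n) - 1) * tr
  mk <- function(f) sin(2 * pi * f * tt)
  b <- make_noise_bundle(n = n, R = 3, seed = 4)
  b$ts <- cbind(pass = mk(0.1), low = mk(0.004), high = mk(0.4))
  b$run <- rep(1L, n)
  b$tr_s <- tr
  b$confounds <- b$confounds[1:n, ]
  b$confounds$framewise_displacement[] <- 0.1   # no censoring
  out <- denoise(b, denoise_spec(regress_task = FALSE))
  mid <- seq(n %/% 4, 3 * (n %/% 4))            # avoid edge transients
  amp <- apply(out$ts, 2, function(v) sqrt(mean(v[mid]^2)) * sqrt(2))
  expect_gt(amp["pass"], 0.9)
  expect_lt(amp["low"], 0.1)
  expect_lt(amp["high"], 0.1)
})

test_that("denoise excludes runs with excessive censoring", {
  b <- make_noise_bundle(seed = 5)
  b$confounds$framewise_displacement[b$run == 2] <- 1
  expect_warning(out <- denoise(b, denoise_spec(regress_task = FALSE)),
                 "excluded")
  expect_equal(out$excluded_runs, 2L)
})

test_that("trial windows have exactly duration/TR indices with HRF lag", {
  ev <- do.call(rbind, lapply(0:1, function(r) {
    make_events(2 + (0:7) * 44 + 10, run_id = r + 1L)
  }))
  run <- rep(1:2, each = 182)
  idx <- select_trial_timepoints(ev, 2, run)
  expect_length(idx, 16)
  expect_true(all(lengths(idx) == 15))          # 30 s at TR 2 s
  for (i in seq_along(idx)) {
    expect_true(all(diff(idx[[i]]) == 1))       # contiguous
  }
  # shifted later than onset by the hemodynamic lag: first index at least
  # onset/TR + 2
  on1 <- ev$onset[ev$trial_type == "movie" & ev$run_id == 1][1]
  expect_gte(idx[[1]][1], on1 / 2 + 2)
  # no overlap between consecutive trials
  expect_false(anyDuplicated(unlist(idx)) > 0)

  ev10 <- make_events(c(20, 60), duration = 10, response = FALSE)
  idx10 <- select_trial_timepoints(ev10, 2, rep(1L, 50))
  expect_true(all(lengths(idx10) == 5))         # 10 s trial, TR 2 -> 5
})

test_that("positive-threshold selection retains more than top-k", {
  ev <- make_events(c(12, 100), duration = 30, response = FALSE)
  run <- rep(1L, 100)
  topk <- select_trial_timepoints(ev, 2, run)
  pos <- select_trial_timepoints(ev, 2, run, method = "positive-threshold")
  expect_true(all(lengths(pos) > lengths(topk)))
})

test_that("trial_fc matches the literal per-trial correlation loop", {
  set.seed(6)
  n <- 200; R <- 5
  ts <- matrix(rnorm(n * R), n, R, dimnames = list(NULL, paste0("r", 1:R)))
  idx <- split(1:150, rep(1:10, each = 15))
  names(idx) <- as.character(1:10)
  b <- roi_bundle(ts, rep(1L, n), 2)
  got <- trial_fc(b, idx)
  expect_equal(unname(got$z), oracle_trial_fc(ts, idx), tolerance = 1e-12)
  expect_equal(dim(got$z), c(10, choose(R, 2)))
})

test_that("trial_fc clips perfect correlations and drops starved trials", {
  n <- 60
  x <- rnorm(n)
  ts <- cbind(a = x, b = x, c = rnorm(n))
  b <- roi_bundle(ts, rep(1L, n), 2)
  idx <- list(`1` = 1:15, `2` = 16:30)
  got <- trial_fc(b, idx)
  expect_true(got$clipped)
  expect_equal(unname(got$z[, "a:b"]), rep(atanh(1 - 1e-7), 2))
  # censoring starves a trial below the minimum
  b$censor <- c(rep(TRUE, 10), rep(FALSE, n - 10))
  expect_warning(got2 <- trial_fc(b, idx), "dropped")
  expect_equal(got2$dropped_trials, "1")
})

test_that("19 ROIs give exactly 171 edges", {
  expect_length(aestheticfmri:::edge_names(default_roi_names()), 171)
  expect_length(default_roi_names(), 19)
})

test_that("fc_appeal_regression handles trivial and exact-fit cases", {
  set.seed(8)
  z <- matrix(0.4, 31, 2, dimnames = list(1:31, c("e1", "e2")))
  stack <- structure(list(z = z, edges = c("e1", "e2"),
                          n_retained = rep(15, 31), dropped_trials = character(0),
                          clipped = FALSE), class = "trial_fc_stack")
  ratings <- rnorm(31)
  got <- fc_appeal_regression(stack, ratings)
  expect_equal(unname(got$t_linear), c(0, 0))
  expect_equal(unname(got$t_quadratic), c(0, 0))

  lin <- as.numeric(scale(ratings))
  stack$z[, 1] <- 0.1 + 0.2 * lin            # exact linear fit
  got2 <- fc_appeal_regression(stack, ratings)
  expect_true(got2$degenerate[["e1"]])
  expect_equal(got2$t_linear[["e1"]], Inf)
  expect_equal(got2$t_quadratic[["e1"]], 0)
  expect_error(fc_appeal_regression(stack, rep(1, 31)), "constant")
})

test_that("fc_appeal_regression t-values match lm on noisy edges", {
  set.seed(9)
  ratings <- rnorm(31)
  lin <- as.numeric(scale(ratings))
  q_res <- lm.fit(cbind(1, lin), lin^2)$residuals
  quad <- as.numeric(scale(q_res))
  z <- matrix(rnorm(31 * 3, sd = 0.3), 31, 3,
              dimnames = list(1:31, c("a", "b", "c")))
  z[, 2] <- z[, 2] + 0.15 * lin
  stack <- structure(list(z = z, edges = c("a", "b", "c"),
                          n_retained = rep(15, 31),
                          dropped_trials = character(0), clipped = FALSE),
                     class = "trial_fc_stack")
  got <- fc_appeal_regression(stack, ratings)
  for (j in 1:3) {
    fit <- summary(lm(z[, j] ~ lin + quad))
    expect_equal(got$t_linear[[j]], fit$coefficients["lin", "t value"],
                 tolerance = 1e-10)
    expect_equal(got$t_quadratic[[j]], fit$coefficients["quad", "t value"],
                 tolerance = 1e-10)
  }
})

test_that("group_edge_test applies BH within regressor families", {
  set.seed(10)
  mk_stat <- function(shift1) {
    tl <- c(e1 = rnorm(1, shift1), e2 = rnorm(1), e3 = rnorm(1))
    list(t_linear = tl, t_quadratic = tl * 0 + rnorm(3),
         degenerate = tl * 0 > 1, dof = 28)
  }
  stats <- lapply(rep(4, 12), mk_stat)
  res <- group_edge_test(stats)
  expect_equal(nrow(res), 6)
  lin <- res[res$regressor == "linear", ]
  expect_true(lin$significant[lin$edge == "e1"])
  expect_equal(lin$q, bh_fdr(lin$p)$q, tolerance = 1e-12)
  expect_error(group_edge_test(stats[1:2]), "3 participants")
})

test_that("mtd matches the naive loop oracle exactly", {
  set.seed(11)
  ts <- matrix(rnorm(500), 100, 5, dimnames = list(NULL, paste0("r", 1:5)))
  got <- mtd(ts, 3)
  orc <- oracle_mtd(ts, 3)
  expect_equal(unname(got$raw), orc$raw, tolerance = 1e-12)
  expect_equal(unname(got$mtd), orc$mtd, tolerance = 1e-12)
  expect_equal(dim(got$mtd), c(99, 10))
})

test_that("identical series have raw MTD with time-mean exactly 1", {
  x <- cumsum(rnorm(80))
  got <- mtd(cbind(a = x, b = x, c = rnorm(80)), 3)
  expect_equal(mean(got$raw[, "a:b"]), 1, tolerance = 1e-12)
})

test_that("mtd time-mean approximates the derivative correlation and nulls out", {
  set.seed(12)
  means <- replicate(40, {
    ts <- matrix(rnorm(400), 200, 2)
    mean(mtd(ts, 3)$raw[, 1])
  })
  expect_lt(abs(mean(means)), 3 * sd(means) / sqrt(40))
  # long stationary series: time-mean tracks cor(diff(x), diff(y))
  n <- 5000
  x <- rnorm(n); y <- 0.6 * x + sqrt(1 - 0.36) * rnorm(n)
  ts <- apply(cbind(x, y), 2, cumsum)
  m <- mean(mtd(ts, 3)$raw[, 1])
  expect_lt(abs(m - cor(diff(ts[, 1]), diff(ts[, 2]))), 0.02)
  expect_warning(mtd(cbind(a = rep(1, 20), b = rnorm(20))), "undefined")
  expect_error(mtd(matrix(rnorm(6), 3, 2), 3), "timepoints")
})

test_that("change_regressors threshold the smoothed rating derivative", {
  ev <- make_events(c(12, 56), duration = 30, response = FALSE)
  run <- rep(1L, 60)
  up <- rating_trace("p", "m1", 10, seq(-1, 1, length.out = 300))
  up2 <- rating_trace("p", "m2", 10, seq(-1, 1, length.out = 300))
  regs <- change_regressors(list(up, up2), ev, 2, run)
  expect_equal(unname(regs[, "negative"]), rep(0, 60))
  expect_gt(max(regs[, "positive"]), 0)

  # symmetric ramp up then down: equal pre-convolution mass means similar
  # total area in both regressors
  tri <- c(seq(-1, 1, length.out = 150), seq(1, -1, length.out = 150))
  t1 <- rating_trace("p", "m1", 10, tri)
  t2 <- rating_trace("p", "m2", 10, tri)
  regs2 <- change_regressors(list(t1, t2), ev, 2, run)
  expect_equal(sum(regs2[, "positive"]), sum(regs2[, "negative"]),
               tolerance = 0.1)
  expect_error(change_regressors(list(up), ev, 2, run), "one trace per")
  short <- rating_trace("p", "m1", 10, rep(0, 100))
  expect_error(change_regressors(list(short, up2), ev, 2, run), "aligned")
})

test_that("mtd_glm tests the 3-node subset and the paired test is antisymmetric", {
  set.seed(13)
  ev <- make_events(c(12, 56), duration = 30, response = FALSE)
  run <- rep(1L, 60)
  tr1 <- rating_trace("p", "m1", 10, cumsum(rnorm(300, 0, 0.05)))
  tr2 <- rating_trace("p", "m2", 10, cumsum(rnorm(300, 0.01, 0.05)))
  regs <- change_regressors(list(tr1, tr2), ev, 2, run)
  ts <- matrix(rnorm(60 * 4), 60, 4,
               dimnames = list(NULL, c("PPA", "aMPFC", "PCC", "other")))
  m <- mtd(ts, 3)
  fit <- mtd_glm(m, regs, roi_subset = c("PPA", "aMPFC", "PCC"))
  expect_equal(nrow(fit$t), 3)      # 3 nodes -> 3 edges
  swapped <- regs[, c("negative", "positive")]
  colnames(swapped) <- c("positive", "negative")
  fit2 <- mtd_glm(m, swapped, roi_subset = c("PPA", "aMPFC", "PCC"))
  res <- mtd_paired_test(list(fit, fit))
  res2 <- mtd_paired_test(list(fit2, fit2))
  expect_equal(res$paired_t, -res2$paired_t, tolerance = 1e-10)
  expect_error(mtd_glm(m, cbind(positive = regs[, 1], negative = regs[, 1])),
               "collinear")
})
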