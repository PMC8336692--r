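# Rating scaling, binning, agreement and the taste decomposition.

test_that("scale_ratings maps the device range affinely onto [-1, 1]", {
  raw <- data.frame(rating = c(0, 50, 100, 75))
  got <- scale_ratings(raw, 0, 100)$rating
  expect_equal(got, c(-1, 0, 1, 0.5))
  tab <- data.frame(rating = c(-1, -0.2, 0.8, 1))
  expect_equal(scale_ratings(tab, -1, 1)$rating, tab$rating)   # idempotent
  expect_error(scale_ratings(data.frame(rating = 101), 0, 100), "device range")
  expect_error(scale_ratings(raw, 100, 0), "exceed")
})

test_that("downsample_trace computes non-overlapping block means", {
  tr <- rating_trace("p1", "m1", 60, rep(0.25, 1800))
  got <- downsample_trace(tr, 10)
  expect_equal(length(got$values), 300)   # 30 s at 60 -> 10 Hz
  expect_equal(got$rate_hz, 10)
  expect_true(all(got$values == 0.25))
  alt <- rating_trace("p1", "m1", 60, rep(c(1, -1), 900))
  expect_equal(downsample_trace(alt, 10)$values, rep(0, 300))
  expect_error(downsample_trace(tr, 7), "integer multiple")
})

test_that("bin_quartiles follows the rank rule with balanced blocks", {
  tab <- make_rating_table(matrix(1:8, 8, 1))
  lv <- bin_quartiles(tab)
  expect_equal(lv$level[order(tab$rating)], c(1, 1, 2, 2, 3, 3, 4, 4))

  set.seed(2)
  tab31 <- make_rating_table(matrix(sample(seq(0.01, 0.99, length.out = 31)), 31, 1))
  lv31 <- bin_quartiles(tab31)
  sizes <- as.integer(table(lv31$level))
  expect_equal(sizes, c(8, 8, 7, 8))     # short block at level 3
  # levels respect rating order
  expect_true(all(diff(lv31$level[order(tab31$rating)]) >= 0))
})

test_that("bin_quartiles is per-participant and rejects degenerate input", {
  m <- cbind(c(3, 1, 4, 2, 5, 7, 6, 8), c(3, 1, 4, 2, 5, 7, 6, 8) / 10)
  lv <- bin_quartiles(make_rating_table(m))
  a <- lv[lv$participant_id == "p01", "level"]
  b <- lv[lv$participant_id == "p02", "level"]
  expect_equal(a, b)   # identical multisets -> identical assignment
  expect_error(bin_quartiles(make_rating_table(matrix(1, 8, 1))),
               "degenerate")
})

test_that("mm1_overall equals the literal leave-one-out loop", {
  set.seed(5)
  mat <- matrix(rnorm(8 * 12), 12, 8)
  got <- mm1_overall(make_rating_table(mat))
  expect_equal(unname(got$per_participant_r), oracle_mm1(mat),
               tolerance = 1e-12)
})

test_that("mm1_overall trivial structures give r = 1 / r = -1", {
  shared <- matrix(rep(c(0.1, 0.5, -0.3, 0.8), 4), 4, 4)
  got <- mm1_overall(make_rating_table(shared))
  expect_equal(unname(got$per_participant_r), rep(1, 4), tolerance = 1e-12)
  anti <- mm1_overall(make_rating_table(cbind(c(1, 2, 3), c(3, 2, 1))))
  expect_equal(unname(anti$per_participant_r), c(-1, -1), tolerance = 1e-12)
})

test_that("a rater's agreement is invariant to their own positive affine transform", {
  # Pearson r is affine-invariant in each argument, so rescaling one
  # participant's ratings cannot change that participant's own MM1 score
  # (it does change the others' mean seen by other raters, which is why
  # the check is per rater).
  set.seed(9)
  mat <- matrix(rnorm(10 * 6), 10, 6)
  base <- mm1_overall(make_rating_table(mat))
  for (j in c(1, 4)) {
    tilted <- mat
    tilted[, j] <- 2.7 * mat[, j] - 0.4
    got <- mm1_overall(make_rating_table(tilted))
    expect_equal(got$per_participant_r[[j]], base$per_participant_r[[j]],
                 tolerance = 1e-10)
  }
})

test_that("mm1_continuous scores identical traces at 1 and excludes flat ones", {
  v <- sin(seq(0, 4 * pi, length.out = 100))
  traces <- lapply(1:5, function(p) rating_trace(paste0("p", p), "m1", 10, v))
  got <- mm1_continuous(traces)
  # |r| is clipped at 1 - 1e-7 before the Fisher transform
  expect_equal(unname(got$per_participant_r), rep(1, 5), tolerance = 1e-6)
  expect_equal(got$per_cell$r, rep(1, 5), tolerance = 1e-12)

  traces[[3]] <- rating_trace("p3", "m1", 10, rep(0, 100))
  expect_warning(got2 <- mm1_continuous(traces), "flat")
  expect_equal(sum(!is.na(got2$per_cell$r)), 4)
  expect_equal(got2$summary$n, 4)
})

test_that("mm1_continuous matches a per-movie leave-one-out loop oracle", {
  set.seed(31)
  n_p <- 5; n_m <- 3; len <- 60
  traces <- list()
  arr <- array(rnorm(len * n_p * n_m), c(len, n_p, n_m))
  for (m in seq_len(n_m)) for (p in seq_len(n_p)) {
    traces[[length(traces) + 1]] <-
      rating_trace(sprintf("p%d", p), sprintf("m%d", m), 10, arr[, p, m])
  }
  got <- mm1_continuous(traces, average_space = "z")
  manual <- sapply(seq_len(n_p), function(p) {
    rs <- sapply(seq_len(n_m), function(m) {
      cor(arr[, p, m], rowMeans(arr[, -p, m]))
    })
    tanh(mean(atanh(rs)))
  })
  expect_equal(unname(got$per_participant_r[sprintf("p%d", 1:n_p)]),
               manual, tolerance = 1e-12)
})

test_that("decompose_taste trivial structures are exact", {
  # all participants share one profile, perfect repeats -> all shared
  prof <- c(0.9, -0.5, 0.2, 0.7, -0.1)
  tab <- do.call(rbind, lapply(1:6, function(p) {
    do.call(rbind, lapply(1:2, function(k) {
      data.frame(participant_id = paste0("p", p),
                 movie_id = paste0("m", 1:5), presentation = k,
                 rating = prof)
    }))
  }))
  dec <- decompose_taste(rating_table(tab))
  expect_equal(dec$var_error, 0)
  expect_equal(dec$shared_fraction, 1, tolerance = 1e-12)

  # participant-specific uncorrelated profiles, perfect repeats
  set.seed(13)
  P <- 60
  tab2 <- do.call(rbind, lapply(seq_len(P), function(p) {
    prof <- rnorm(8)
    do.call(rbind, lapply(1:2, function(k) {
      data.frame(participant_id = sprintf("p%03d", p),
                 movie_id = paste0("m", 1:8), presentation = k,
                 rating = prof)
    }))
  }))
  dec2 <- decompose_taste(rating_table(tab2))
  expect_equal(dec2$var_error, 0)
  expect_lt(abs(dec2$shared_fraction), 0.1)
  expect_equal(dec2$shared_fraction + dec2$individual_fraction, 1)
})

test_that("decompose_taste recovers generator ground truth on repeated movies", {
  # quick bias check at modest replicate count (the full sweep lives in the
  # acceptance suite)
  est <- sapply(1:40, function(i) {
    g <- gen_ratings(rating_sim_spec(n_participants = 24, n_movies = 31,
                                     n_repeats = 31, shared_sd = 1,
                                     individual_sd = 1, error_sd = 0.2,
                                     seed = 1000 + i))
    decompose_taste(g$table)$shared_fraction
  })
  expect_lt(abs(mean(est) - 0.5), 0.05)
})

test_that("decompose_taste flags unrepeatable data", {
  set.seed(3)
  # pure noise between presentations: repeatable variance can go negative
  tab <- do.call(rbind, lapply(1:4, function(p) {
    do.call(rbind, lapply(1:2, function(k) {
      data.frame(participant_id = paste0("p", p),
                 movie_id = paste0("m", 1:3), presentation = k,
                 rating = rnorm(3, sd = 2))
    }))
  }))
  dec <- decompose_taste(rating_table(tab))
  if (dec$unrepeatable) {
    expect_true(is.na(dec$shared_fraction))
  } else {
    expect_equal(dec$shared_fraction + dec$individual_fraction, 1)
  }
})

test_that("correlate_with_covariate recovers trivial relations", {
  set.seed(21)
  mat <- matrix(rnorm(12 * 4), 12, 4)
  tab <- make_rating_table(mat)
  own <- correlate_with_covariate(tab, setNames(mat[, 1],
                                                sprintf("m%02d", 1:12)))
  expect_equal(unname(own$per_participant_r["p01"]), 1, tolerance = 1e-12)
  neg <- correlate_with_covariate(tab, setNames(-mat[, 2],
                                                sprintf("m%02d", 1:12)))
  expect_equal(unname(neg$per_participant_r["p02"]), -1, tolerance = 1e-12)
  expect_error(correlate_with_covariate(tab, setNames(rep(1, 12),
                                                      sprintf("m%02d", 1:12))),
               "constant")
})
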