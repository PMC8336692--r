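# Behavioral ratings: scaling, quartile binning, inter-rater agreement
# (MM1 / MM1c), shared-vs-individual taste decomposition, and covariate
# correlations.

#' Validate an overall-rating table
#'
#' The canonical behavioral table: one row per (participant, movie,
#' presentation) with a rating in \[-1, 1\]. Presentation 2 rows are the
#' repeated showings used by [decompose_taste()].
#'
#' @param df data.frame with columns `participant_id`, `movie_id`,
#'   `presentation` (1 or 2) and `rating`.
#' @return the validated data.frame (invisibly classed `"rating_table"`).
#' @export
rating_table <- function(df) {
  need <- c("participant_id", "movie_id", "presentation", "rating")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_param("missing column(s): ", paste(miss, collapse = ", "))
  if (!all(df$presentation %in% c(1L, 2L))) {
    stop_param("`presentation` must be 1 or 2")
  }
  if (anyNA(df$rating)) stop_param("ratings must not be NA")
  key <- paste(df$participant_id, df$movie_id, df$presentation)
  if (anyDuplicated(key)) {
    stop_param("duplicate (participant, movie, presentation) cells")
  }
  class(df) <- unique(c("rating_table", class(df)))
  df
}

#' Rescale raw device ratings to \[-1, 1\]
#'
#' Affine map from the response device range to \[-1, 1\] (device minimum
#' maps to -1, maximum to +1, midpoint to 0).
#'
#' @param raw data.frame with a `rating` column (plus id columns, kept).
#' @param device_min,device_max raw device range, `device_max > device_min`.
#' @return the table with `rating` rescaled.
#' @export
scale_ratings <- function(raw, device_min, device_max) {
  if (!is.numeric(device_min) || !is.numeric(device_max) ||
      device_max <= device_min) {
    stop_param("`device_max` must exceed `device_min`")
  }
  if (!"rating" %in% names(raw)) stop_param("`raw` needs a `rating` column")
  r <- raw$rating
  if (any(r < device_min - 1e-12 | r > device_max + 1e-12)) {
    stop_param("raw rating outside the device range")
  }
  raw$rating <- 2 * (r - device_min) / (device_max - device_min) - 1
  raw
}

#' A continuous rating trace
#'
#' One enjoyment timecourse for one (participant, movie), sampled at a
#' constant rate.
#'
#' @param participant_id,movie_id identifiers.
#' @param rate_hz sampling rate in Hz.
#' @param values numeric vector of ratings.
#' @return object of class `"rating_trace"`.
#' @export
rating_trace <- function(participant_id, movie_id, rate_hz, values) {
  rate_hz <- check_number(rate_hz, "rate_hz", 0, strict = TRUE)
  if (!is.numeric(values) || anyNA(values)) {
    stop_param("`values` must be numeric without NA")
  }
  structure(list(participant_id = participant_id, movie_id = movie_id,
                 rate_hz = rate_hz, values = as.numeric(values)),
            class = "rating_trace")
}

#' Downsample a continuous trace by non-overlapping block means
#'
#' The native rate must be an integer multiple of the target (e.g., the
#' 60 Hz dial traces downsampled to 10 Hz: blocks of 6 samples averaged).
#' No interpolation is performed.
#'
#' @param trace a [rating_trace()] (or bare numeric vector).
#' @param target_hz target sampling rate.
#' @param rate_hz native rate, required when `trace` is a bare vector.
#' @return downsampled trace of the same type as the input.
#' @export
downsample_trace <- function(trace, target_hz, rate_hz = NULL) {
  is_obj <- inherits(trace, "rating_trace")
  values <- if (is_obj) trace$values else as.numeric(trace)
  rate <- if (is_obj) trace$rate_hz else rate_hz
  if (is.null(rate)) stop_param("`rate_hz` required for a bare vector")
  k <- rate / target_hz
  if (abs(k - round(k)) > 1e-9 || k < 1) {
    stop_param("native rate must be an integer multiple of `target_hz`")
  }
  k <- as.integer(round(k))
  n_blocks <- length(values) %/% k
  if (n_blocks < 1L) stop_param("trace shorter than one block")
  v <- values[seq_len(n_blocks * k)]
  out <- colMeans(matrix(v, nrow = k))
  if (is_obj) {
    rating_trace(trace$participant_id, trace$movie_id, target_hz, out)
  } else out
}

# Rank-based quartile split: block sizes ceil/floor(n/4), the larger blocks
# assigned extremes-first (levels 1, 4, 2, 3), ties broken by original order.
quartile_sizes <- function(n) {
  q <- n %/% 4L
  r <- n %% 4L
  sizes <- rep(q, 4L)
  extra_order <- c(1L, 4L, 2L, 3L)
  if (r > 0L) sizes[extra_order[seq_len(r)]] <- q + 1L
  sizes
}

#' Bin each participant's overall ratings into four appeal levels
#'
#' Per-participant quartile binning: the participant's presentation-1
#' ratings are ranked (ties broken by original trial order) and split into
#' four contiguous rank blocks, level 1 = least appealing quartile up to
#' level 4 = most appealing. Block sizes are as balanced as n allows
#' (n = 31 gives sizes 8, 8, 8, 7 with the short block at level 3).
#'
#' @param table a [rating_table()].
#' @return data.frame `participant_id`, `movie_id`, `level` (integer 1-4).
#' @export
bin_quartiles <- function(table) {
  table <- rating_table(as.data.frame(table))
  t1 <- table[table$presentation == 1L, ]
  out <- lapply(split(t1, t1$participant_id), function(d) {
    n <- nrow(d)
    if (n < 4L) stop_param("participant ", d$participant_id[1],
                           ": need at least 4 movies to bin")
    if (length(unique(d$rating)) == 1L) {
      stop_param("participant ", d$participant_id[1],
                 ": all ratings identical, quartile binning is degenerate")
    }
    sizes <- quartile_sizes(n)
    lev <- rep.int(1:4, sizes)
    ord <- order(d$rating)          # stable: ties keep original trial order
    level <- integer(n)
    level[ord] <- lev
    data.frame(participant_id = d$participant_id, movie_id = d$movie_id,
               level = level, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Build a movies x participants matrix of presentation-1 ratings.
rating_matrix <- function(table) {
  t1 <- table[table$presentation == 1L, ]
  movies <- sort(unique(t1$movie_id))
  parts <- sort(unique(t1$participant_id))
  m <- matrix(NA_real_, length(movies), length(parts),
              dimnames = list(as.character(movies), as.character(parts)))
  m[cbind(match(t1$movie_id, movies), match(t1$participant_id, parts))] <- t1$rating
  if (anyNA(m)) stop_param("incomplete design: every participant must rate every movie")
  m
}

#' Mean-minus-one agreement for overall ratings
#'
#' For each participant, the Pearson correlation between their
#' presentation-1 ratings and the average ratings of all other
#' participants (leave-one-out). The group summary is computed in Fisher-z
#' space via [fisher_mean_ci()]. Participants whose rating vector (or whose
#' others' mean) has zero variance get a missing r and are excluded from
#' the group summary with a warning.
#'
#' @param table a [rating_table()].
#' @param ci_method passed to [fisher_mean_ci()].
#' @return object of class `"agreement_result"`: `per_participant_r` (named),
#'   `summary` (a `fisher_summary`), `statistic = "MM1"`.
#' @export
mm1_overall <- function(table, ci_method = "t") {
  m <- rating_matrix(rating_table(as.data.frame(table)))
  if (ncol(m) < 2L) stop_param("need at least 2 participants")
  if (nrow(m) < 2L) stop_param("need at least 2 movies")
  r <- vapply(seq_len(ncol(m)), function(j) {
    others <- rowMeans(m[, -j, drop = FALSE])
    safe_cor(m[, j], others)
  }, numeric(1))
  names(r) <- colnames(m)
  if (anyNA(r)) warning("zero-variance participant(s) excluded from MM1 summary")
  agreement_result(r, "MM1", ci_method)
}

agreement_result <- function(r, statistic, ci_method = "t") {
  structure(list(per_participant_r = r,
                 summary = fisher_mean_ci(r[!is.na(r)], method = ci_method),
                 statistic = statistic),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("%s agreement across %d participants\n", x$statistic,
              length(x$per_participant_r)))
  print(x$summary)
  invisible(x)
}

#' Mean-minus-one agreement for continuous rating traces (MM1c)
#'
#' Per (participant, movie), the Pearson correlation between that
#' participant's trace and the time-point-wise mean trace of all other
#' participants; the per-participant score averages those correlations
#' across movies (in Fisher-z space by default), and the group summary is
#' again a Fisher-z mean with 95% CI. Flat (zero-variance) traces yield
#' missing cells that are excluded with a warning.
#'
#' @param traces list of [rating_trace()] objects, time-aligned and of
#'   equal length within each movie.
#' @param average_space `"z"` (default: average per-participant across
#'   movies in Fisher-z space, then back-transform) or `"r"`.
#' @param ci_method passed to [fisher_mean_ci()].
#' @return an `"agreement_result"` with an extra `per_cell` data.frame
#'   (participant_id, movie_id, r).
#' @export
mm1_continuous <- function(traces, average_space = c("z", "r"),
                           ci_method = "t") {
  average_space <- match.arg(average_space)
  if (!length(traces)) stop_param("no traces supplied")
  movie_of <- vapply(traces, function(t) as.character(t$movie_id), character(1))
  cells <- list()
  for (mv in unique(movie_of)) {
    sub <- traces[movie_of == mv]
    if (length(sub) < 2L) stop_param("movie ", mv, ": need >= 2 participants")
    lens <- vapply(sub, function(t) length(t$values), integer(1))
    if (length(unique(lens)) != 1L) {
      stop_param("movie ", mv, ": traces must be equal length")
    }
    mat <- vapply(sub, `[[`, numeric(lens[1]), "values")
    for (j in seq_along(sub)) {
      others <- rowMeans(mat[, -j, drop = FALSE])
      cells[[length(cells) + 1L]] <- data.frame(
        participant_id = as.character(sub[[j]]$participant_id),
        movie_id = mv, r = safe_cor(mat[, j], others),
        stringsAsFactors = FALSE)
    }
  }
  per_cell <- do.call(rbind, cells)
  if (anyNA(per_cell$r)) {
    warning("flat trace(s): ", sum(is.na(per_cell$r)),
            " (participant, movie) cell(s) excluded")
  }
  agg <- split(per_cell$r, per_cell$participant_id)
  r <- vapply(agg, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_real_)
    if (average_space == "z") tanh(mean(atanh(clip_r(v)$r))) else mean(v)
  }, numeric(1))
  out <- agreement_result(r, "MM1c", ci_method)
  out$per_cell <- per_cell
  out
}

#' Decompose rating variance into non-repeatable, shared and individual parts
#'
#' Uses the movies rated twice by every participant. A two-way
#' random-effects method-of-moments (ANOVA) decomposition partitions total
#' rating variance into non-repeatable (error) variance and repeatable
#' variance, and splits the repeatable part into a shared component (the
#' movie main effect, common taste) and an individual component
#' (participant-specific preference). Per-participant centering removes
#' scale-use offsets before estimation (the default); with
#' `center_participants = FALSE` such offsets count as individual taste.
#' Components are reported signed — sampling noise can push a fraction
#' outside \[0, 1\], which is flagged, never clipped.
#'
#' The shared and individual fractions are ratios of variance-component
#' estimates; with few repeated movies the movie main effect has few
#' degrees of freedom and the plug-in ratio acquires a small-sample
#' (Jensen) bias. By default a leave-one-movie-out jackknife correction is
#' applied when at least three repeated movies are available.
#'
#' @param table a [rating_table()] containing presentation-2 rows for the
#'   repeated movies.
#' @param center_participants subtract each participant's mean first?
#' @param debias apply the jackknife bias correction to the fractions?
#'   Default TRUE.
#' @return object of class `"taste_decomposition"`: `var_total`,
#'   `var_error`, `var_repeatable`, `var_shared`, `var_individual`,
#'   `shared_fraction`, `individual_fraction`, `n_participants`,
#'   `n_movies`, `unrepeatable`, `out_of_range` flags.
#' @export
decompose_taste <- function(table, center_participants = TRUE,
                            debias = TRUE) {
  table <- rating_table(as.data.frame(table))
  rep_movies <- intersect(unique(table$movie_id[table$presentation == 1L]),
                          unique(table$movie_id[table$presentation == 2L]))
  d <- table[table$movie_id %in% rep_movies, ]
  parts <- sort(unique(d$participant_id))
  P <- length(parts); M <- length(rep_movies)
  if (M < 2L) stop_param("need >= 2 movies with both presentations")
  # array r[p, m, k]
  arr <- array(NA_real_, c(P, M, 2L))
  arr[cbind(match(d$participant_id, parts),
            match(d$movie_id, rep_movies), d$presentation)] <- d$rating
  if (anyNA(arr)) stop_param("every participant needs both presentations of every repeated movie")
  if (center_participants) {
    arr <- arr - array(rep(rowMeans(arr, dims = 1), 2L * M), c(P, M, 2L))
  }
  cell_mean <- (arr[, , 1] + arr[, , 2]) / 2          # P x M
  # non-repeatable: within-cell mean square across the two presentations
  ve <- mean((arr[, , 1] - arr[, , 2])^2) / 2
  movie_mean <- colMeans(cell_mean)                   # over participants
  part_mean <- rowMeans(cell_mean)
  grand <- mean(cell_mean)
  ms_movie <- 2 * P * sum((movie_mean - grand)^2) / (M - 1)
  if (center_participants) {
    inter <- cell_mean - outer(part_mean, movie_mean, `+`) + grand
    ms_int <- 2 * sum(inter^2) / ((M - 1) * (P - 1))
  } else {
    inter <- cell_mean - matrix(movie_mean, P, M, byrow = TRUE)
    ms_int <- 2 * sum(inter^2) / ((P - 1) * M)
  }
  v_ind <- (ms_int - ve) / 2
  v_sh <- (ms_movie - ms_int) / (2 * P)
  vr <- v_sh + v_ind
  vt <- vr + ve
  unrepeatable <- vr <= 0
  sf <- if (unrepeatable) NA_real_ else v_sh / vr
  if (debias && !unrepeatable && M >= 3L) {
    f_loo <- vapply(rep_movies, function(m) {
      decompose_taste(table[table$movie_id != m, ],
                      center_participants = center_participants,
                      debias = FALSE)$shared_fraction
    }, numeric(1))
    if (!anyNA(f_loo)) sf <- M * sf - (M - 1) * mean(f_loo)
  }
  res <- list(var_total = vt, var_error = ve, var_repeatable = vr,
              var_shared = v_sh, var_individual = v_ind,
              shared_fraction = sf,
              individual_fraction = if (unrepeatable) NA_real_ else 1 - sf,
              n_participants = P, n_movies = M,
              unrepeatable = unrepeatable,
              out_of_range = !unrepeatable && (sf < 0 || sf > 1))
  class(res) <- "taste_decomposition"
  res
}

#' @export
print.taste_decomposition <- function(x, ...) {
  cat(sprintf("Taste decomposition (%d participants, %d repeated movies)\n",
              x$n_participants, x$n_movies))
  cat(sprintf("  total variance:        %.4f\n", x$var_total))
  cat(sprintf("  non-repeatable:        %.4f\n", x$var_error))
  cat(sprintf("  repeatable:            %.4f\n", x$var_repeatable))
  if (x$unrepeatable) {
    cat("  repeatable variance <= 0: shared/individual fractions undefined\n")
  } else {
    cat(sprintf("  shared taste:          %.1f%%\n", 100 * x$shared_fraction))
    cat(sprintf("  individual taste:      %.1f%%\n", 100 * x$individual_fraction))
    if (x$out_of_range) cat("  note: fraction outside [0, 1] (sampling noise), reported unclipped\n")
  }
  invisible(x)
}

#' Correlate ratings with a stimulus covariate
#'
#' Per-participant Pearson correlation between ratings and a covariate such
#' as motion energy: either overall ratings against one scalar per movie,
#' or continuous traces against one covariate trace per movie (averaged
#' across movies in Fisher-z space per participant). The group summary uses
#' [fisher_mean_ci()].
#'
#' @param ratings a [rating_table()] (scalar covariate) or a list of
#'   [rating_trace()] objects (trace covariate).
#' @param covariate named numeric vector (per movie) or named list of
#'   numeric vectors (per movie traces), names matching movie ids.
#' @param ci_method passed to [fisher_mean_ci()].
#' @return an `"agreement_result"` (statistic `"covariate_r"`).
#' @export
correlate_with_covariate <- function(ratings, covariate, ci_method = "t") {
  if (inherits(ratings, "rating_table") || is.data.frame(ratings)) {
    m <- rating_matrix(rating_table(as.data.frame(ratings)))
    cov <- covariate[rownames(m)]
    if (anyNA(cov)) stop_param("covariate missing for some movies")
    if (stats::sd(cov) == 0) stop_param("constant covariate: correlation undefined")
    r <- apply(m, 2, function(v) safe_cor(v, cov))
  } else {
    movie_of <- vapply(ratings, function(t) as.character(t$movie_id), character(1))
    rs <- vapply(ratings, function(t) {
      cv <- covariate[[as.character(t$movie_id)]]
      if (is.null(cv)) stop_param("covariate missing for movie ", t$movie_id)
      if (length(cv) != length(t$values)) {
        stop_param("covariate not aligned with trace for movie ", t$movie_id)
      }
      if (stats::sd(cv) == 0) stop_param("constant covariate: correlation undefined")
      safe_cor(t$values, cv)
    }, numeric(1))
    agg <- split(rs, vapply(ratings, function(t) as.character(t$participant_id),
                            character(1)))
    r <- vapply(agg, function(v) {
      v <- v[!is.na(v)]
      if (!length(v)) NA_real_ else tanh(mean(atanh(clip_r(v)$r)))
    }, numeric(1))
  }
  agreement_result(r, "covariate_r", ci_method)
}
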