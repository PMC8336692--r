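# Readers and writers for the tabular formats used throughout: ratings CSV,
# continuous-rating long TSV, events TSV (BIDS dialect), ROI timeseries TSV
# and fMRIPrep-style confounds TSV. All plain text, header row required,
# row order preserved.

read_table_checked <- function(path, required, sep = "\t") {
  if (!file.exists(path)) stop_param("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop_param(basename(path), ": missing column(s): ",
               paste(miss, collapse = ", "))
  }
  for (col in required) {
    bad <- which(is.na(df[[col]]))
    if (length(bad)) {
      stop_param(basename(path), ": NA in required column `", col,
                 "` at row ", bad[1])
    }
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the behavioral and imaging tables
#'
#' `read_ratings()` expects a CSV with columns `participant_id`,
#' `movie_id`, `presentation`, `rating`; `read_events()` a BIDS-style TSV
#' with `onset`, `duration`, `trial_type`, `trial_id`, `appeal_level`,
#' `run_id`; `read_roi_timeseries()` a TSV of scans x ROIs plus a `run`
#' column; `read_confounds()` an fMRIPrep-style TSV (the 24-parameter
#' motion block is derived from `trans_*` / `rot_*` automatically);
#' `read_continuous()` a long TSV with `participant_id`, `movie_id`,
#' `time_s`, `rating`. Validation errors name the missing column or the
#' offending row.
#'
#' @param path file path.
#' @return the validated object (see each reader).
#' @name io
NULL

#' @rdname io
#' @export
read_ratings <- function(path) {
  df <- read_table_checked(path, c("participant_id", "movie_id",
                                   "presentation", "rating"), sep = ",")
  rating_table(df)
}

#' @rdname io
#' @param table a [rating_table()].
#' @export
write_ratings <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_events <- function(path) {
  df <- read_table_checked(path, c("onset", "duration", "trial_type",
                                   "trial_id", "run_id"))
  if (!"appeal_level" %in% names(df)) df$appeal_level <- NA
  df
}

#' @rdname io
#' @param events an event table.
#' @export
write_events <- function(events, path) write_tsv(events, path)

#' @rdname io
#' @export
read_roi_timeseries <- function(path) {
  df <- read_table_checked(path, "run")
  run <- df$run
  ts <- as.matrix(df[setdiff(names(df), "run")])
  if (!is.numeric(ts)) stop_param(basename(path), ": non-numeric ROI values")
  list(ts = ts, run = as.integer(run))
}

#' @rdname io
#' @param ts scans x ROIs matrix; `run` run ids.
#' @export
write_roi_timeseries <- function(ts, run, path) {
  write_tsv(data.frame(run = run, ts, check.names = FALSE), path)
}

#' @rdname io
#' @export
read_confounds <- function(path) {
  df <- read_table_checked(path, c("trans_x", "trans_y", "trans_z",
                                   "rot_x", "rot_y", "rot_z"))
  df
}

#' @rdname io
#' @param confounds a confound data.frame.
#' @export
write_confounds <- function(confounds, path) write_tsv(confounds, path)

#' @rdname io
#' @export
read_continuous <- function(path) {
  df <- read_table_checked(path, c("participant_id", "movie_id",
                                   "time_s", "rating"))
  out <- list()
  for (key in unique(paste(df$participant_id, df$movie_id, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    d <- df[df$participant_id == parts[1] & df$movie_id == parts[2], ]
    dtv <- diff(d$time_s)
    if (length(dtv) && (max(dtv) - min(dtv)) > 1e-6) {
      stop_param(basename(path), ": non-constant sampling for ",
                 parts[1], " / ", parts[2])
    }
    rate <- if (length(dtv)) 1 / mean(dtv) else 1
    out[[length(out) + 1L]] <- rating_trace(parts[1], parts[2],
                                            round(rate, 6), d$rating)
  }
  out
}

#' @rdname io
#' @param traces list of [rating_trace()].
#' @export
write_continuous <- function(traces, path) {
  rows <- lapply(traces, function(t) {
    data.frame(participant_id = t$participant_id, movie_id = t$movie_id,
               time_s = (seq_along(t$values) - 1) / t$rate_hz,
               rating = t$values)
  })
  write_tsv(do.call(rbind, rows), path)
}
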