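#' Construct a uniformly sampled multivariate session
#'
#' A `ts_session` holds one recording session: a T x D matrix of channel
#' measurements sampled on a uniform clock. In dyadic interpersonal
#' applications the four channels are patient/therapist warmth and dominance
#' scored on \[-1000, 1000\] every 0.5 s, but any uniformly sampled
#' multivariate series is accepted.
#'
#' @param values numeric matrix (T rows, D columns) of channel measurements;
#'   a vector is treated as a single channel.
#' @param dt sampling interval in seconds.
#' @param t0 timestamp of the first sample (seconds).
#' @param times optional explicit timestamps; must be strictly increasing and
#'   uniformly spaced (tolerance `1e-9 * dt`). Overrides `dt`/`t0` when given
#'   (`dt` is then inferred).
#' @param channel_names optional character vector of D channel names.
#' @param session_id identifier string.
#' @return an object of class `ts_session` with fields `session_id`, `times`,
#'   `values`, `channel_names`, `dt`.
#' @export
time_series_session <- function(values, dt = 0.5, t0 = 0, times = NULL,
                                channel_names = NULL, session_id = "session") {
  if (is.vector(values) && is.numeric(values)) values <- matrix(values, ncol = 1L)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_data("'values' must be a numeric matrix or vector")
  }
  storage.mode(values) <- "double"
  n <- nrow(values)
  d <- ncol(values)
  if (n < 2L) stop_data("a session needs at least 2 time points, got ", n)
  if (d < 1L) stop_data("a session needs at least 1 channel")
  if (anyNA(values)) {
    bad <- which(apply(values, 1L, anyNA))[1L]
    stop_data("missing value in session at row ", bad)
  }
  if (is.null(times)) {
    if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
      stop_data("'dt' must be a positive scalar")
    }
    times <- t0 + dt * (seq_len(n) - 1L)
  } else {
    if (length(times) != n) stop_data("'times' length must match nrow(values)")
    dts <- diff(times)
    if (any(dts <= 0)) {
      stop_data("timestamps must be strictly increasing (first violation after index ",
                which(dts <= 0)[1L], ")")
    }
    dt <- dts[1L]
    off <- which(abs(dts - dt) > 1e-9 * dt)
    if (length(off)) {
      stop_data("non-uniform sampling interval: gap after time ",
                times[off[1L]], " is ", dts[off[1L]], ", expected ", dt)
    }
  }
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(d))
  if (length(channel_names) != d) stop_data("'channel_names' must have D entries")
  colnames(values) <- channel_names
  structure(
    list(session_id = as.character(session_id), times = as.double(times),
         values = values, channel_names = as.character(channel_names),
         dt = as.double(dt)),
    class = "ts_session"
  )
}

#' @export
print.ts_session <- function(x, ...) {
  cat(sprintf("<ts_session '%s': T=%d, D=%d, dt=%gs, span=%.1fs>\n",
              x$session_id, nrow(x$values), ncol(x$values), x$dt,
              x$times[length(x$times)] - x$times[1L]))
  invisible(x)
}

#' Number of time points in a session
#' @param session a `ts_session`.
#' @return integer T.
#' @export
n_points <- function(session) nrow(session$values)

#' Read a session time series from delimited text
#'
#' Reads a CSV/TSV file with a header, a time column (seconds) and one or
#' more numeric channel columns, and validates it into a [time_series_session()].
#' Rows are sorted by time; duplicate timestamps and non-uniform spacing are
#' rejected.
#'
#' @param path file path to delimited text (delimiter sniffed from the header:
#'   tab if present, else comma).
#' @param time_column name of the time column.
#' @param channel_columns character vector of channel column names; `NULL`
#'   uses every non-time column.
#' @param session_id identifier; defaults to the file name without extension.
#' @return a `ts_session`.
#' @export
read_session <- function(path, time_column = "time", channel_columns = NULL,
                         session_id = NULL) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sniff_sep(path),
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!time_column %in% names(df)) {
    stop_config("time column '", time_column, "' not found in ", path)
  }
  if (is.null(channel_columns)) {
    channel_columns <- setdiff(names(df), time_column)
  }
  missing_cols <- setdiff(channel_columns, names(df))
  if (length(missing_cols)) {
    stop_config("channel column(s) not found: ", paste(missing_cols, collapse = ", "))
  }
  for (cn in c(time_column, channel_columns)) {
    if (!is.numeric(df[[cn]])) stop_data("column '", cn, "' is not numeric")
  }
  ord <- order(df[[time_column]])
  df <- df[ord, , drop = FALSE]
  tms <- df[[time_column]]
  if (anyDuplicated(tms)) {
    stop_data("duplicate timestamp at time ", tms[which(duplicated(tms))[1L]])
  }
  vals <- as.matrix(df[, channel_columns, drop = FALSE])
  if (anyNA(vals)) {
    bad <- which(apply(vals, 1L, anyNA))[1L]
    stop_data("missing value at row ", bad, " of ", path)
  }
  if (is.null(session_id)) session_id <- sub("\\.[^.]*$", "", basename(path))
  time_series_session(vals, times = tms, channel_names = channel_columns,
                      session_id = session_id)
}

#' Write a session to CSV at full float precision
#'
#' Inverse of [read_session()]: `read_session(write_session(s, p))` recovers
#' times, values and channel names exactly.
#'
#' @param session a `ts_session`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  df <- data.frame(time = format_full(session$times), check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (j in seq_along(session$channel_names)) {
    df[[session$channel_names[j]]] <- format_full(session$values[, j])
  }
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct an interval-coded annotation track
#'
#' Piecewise-constant ratings (e.g., rupture intensity on a 1-5 scale) coded
#' over consecutive fixed-length intervals aligned to the session clock.
#'
#' @param ratings numeric vector, one rating per interval.
#' @param interval_starts strictly increasing interval start times (seconds),
#'   spaced by `interval_length`.
#' @param interval_length interval duration in seconds (30 in typical
#'   observer-coded rupture data).
#' @param track_name label, e.g. "confrontation".
#' @param scale_min,scale_max rating scale bounds; every rating must lie
#'   within them.
#' @return an object of class `annotation_track`.
#' @export
annotation_track <- function(ratings, interval_starts = NULL,
                             interval_length = 30, track_name = "annotation",
                             scale_min = 1, scale_max = 5) {
  ratings <- as.double(ratings)
  n <- length(ratings)
  if (n < 1L) stop_data("annotation track needs at least one interval")
  if (is.null(interval_starts)) {
    interval_starts <- interval_length * (seq_len(n) - 1L)
  }
  if (length(interval_starts) != n) {
    stop_data("'interval_starts' must match length(ratings)")
  }
  gaps <- diff(interval_starts)
  if (n > 1L) {
    if (any(gaps <= 0)) stop_data("interval starts must be strictly increasing")
    if (any(abs(gaps - interval_length) > 1e-9 * interval_length)) {
      stop_data("ragged intervals: spacing must equal interval_length (",
                interval_length, ")")
    }
  }
  if (anyNA(ratings)) stop_data("missing rating in annotation track")
  if (any(ratings < scale_min - 1e-12) || any(ratings > scale_max + 1e-12)) {
    stop_data("rating outside scale [", scale_min, ", ", scale_max, "]")
  }
  structure(
    list(track_name = as.character(track_name),
         interval_starts = as.double(interval_starts),
         interval_length = as.double(interval_length),
         ratings = ratings,
         scale_min = as.double(scale_min), scale_max = as.double(scale_max)),
    class = "annotation_track"
  )
}

#' Read an interval-coded annotation track from delimited text
#'
#' The file must have a header with an interval-start column and one or more
#' rater columns; per-interval ratings are reduced across raters by mean or
#' median. Interval length is inferred from the spacing of the start times.
#'
#' @param path CSV/TSV path.
#' @param track_name label for the track.
#' @param time_column name of the interval-start column.
#' @param rater_columns character vector of rater column names; `NULL` uses
#'   every non-time column.
#' @param rater_reduce "mean" (default) or "median".
#' @param scale_min,scale_max rating scale bounds (default 1-5).
#' @return an `annotation_track`.
#' @export
read_annotation <- function(path, track_name, time_column = "start",
                            rater_columns = NULL,
                            rater_reduce = c("mean", "median"),
                            scale_min = 1, scale_max = 5) {
  rater_reduce <- match.arg(rater_reduce)
  if (!file.exists(path)) stop_data("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sniff_sep(path),
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!time_column %in% names(df)) {
    stop_config("interval start column '", time_column, "' not found in ", path)
  }
  if (is.null(rater_columns)) rater_columns <- setdiff(names(df), time_column)
  missing_cols <- setdiff(rater_columns, names(df))
  if (length(missing_cols)) {
    stop_config("rater column(s) not found: ", paste(missing_cols, collapse = ", "))
  }
  ord <- order(df[[time_column]])
  df <- df[ord, , drop = FALSE]
  rmat <- as.matrix(df[, rater_columns, drop = FALSE])
  if (anyNA(rmat)) stop_data("missing rating in ", path)
  ratings <- switch(rater_reduce,
                    mean   = rowMeans(rmat),
                    median = apply(rmat, 1L, stats::median))
  starts <- df[[time_column]]
  if (length(starts) < 2L) {
    stop_data("cannot infer interval length from a single interval")
  }
  annotation_track(ratings, interval_starts = starts,
                   interval_length = diff(starts)[1L], track_name = track_name,
                   scale_min = scale_min, scale_max = scale_max)
}

#' Expand an annotation track to one value per session time point
#'
#' Step-function expansion: each time point receives the rating of the
#' half-open interval `[start, start + length)` containing it; time points
#' past the last interval inherit the final rating (sessions rarely end on an
#' interval boundary).
#'
#' @param track an `annotation_track`.
#' @param session the companion `ts_session`.
#' @return numeric vector of length T, named attribute `track_name`.
#' @export
expand_annotation <- function(track, session) {
  s0 <- track$interval_starts[1L]
  len <- track$interval_length
  if (session$times[1L] < s0 - 1e-9 * len) {
    stop_data("session starts at ", session$times[1L],
              ", before the first annotation interval (", s0, ")")
  }
  idx <- floor((session$times - s0 + 1e-9 * len) / len) + 1L
  idx <- pmin(idx, length(track$ratings))
  out <- track$ratings[idx]
  attr(out, "track_name") <- track$track_name
  out
}

#' Keep every factor-th sample of a session
#'
#' Downsampling by decimation: retains samples at indices 1, 1+factor,
#' 1+2*factor, ... and multiplies `dt` by `factor`. `factor = 1` is the
#' identity and the default throughout the pipeline.
#'
#' @param session a `ts_session`.
#' @param factor positive integer, must be smaller than T.
#' @return a decimated `ts_session`.
#' @export
decimate <- function(session, factor) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop_config("'factor' must be a positive integer")
  n <- n_points(session)
  if (factor >= n) stop_data("decimation factor ", factor, " >= series length ", n)
  keep <- seq.int(1L, n, by = factor)
  time_series_session(session$values[keep, , drop = FALSE],
                      times = session$times[keep],
                      channel_names = session$channel_names,
                      session_id = session$session_id)
}
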