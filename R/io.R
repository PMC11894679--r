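#' Read a PPG signal from CSV
#'
#' Two dialects are accepted: a two-column `t,ppg` file (time in seconds,
#' amplitude), from which the sampling frequency is inferred as
#' `1 / median(diff(t))`; or a single-column file of amplitudes, for which
#' `fs` must be supplied. A header row is detected automatically. Non-finite
#' samples are kept in place and flagged invalid in the validity mask.
#'
#' @param path Path to a CSV file.
#' @param fs Sampling frequency (Hz); required for the single-column dialect,
#'   ignored (with the file's time column taking precedence) otherwise.
#' @return A [ppg_signal()].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("0.0,1.0", "0.008,1.1", "0.016,1.2"), f)
#' read_signal_csv(f)$fs  # 125
#' @export
read_signal_csv <- function(path, fs = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  has_header <- grepl("[A-Za-z]", first)
  df <- utils::read.csv(path, header = has_header,
                        colClasses = "numeric", blank.lines.skip = TRUE)
  if (ncol(df) >= 2L) {
    t <- df[[1L]]
    x <- df[[2L]]
    dt <- diff(t)
    if (any(!is.finite(dt)) || any(dt <= 0)) {
      stop("time column must be finite and strictly increasing", call. = FALSE)
    }
    fs_inf <- 1 / stats::median(dt)
    ppg_signal(x, fs = fs_inf, t0 = t[1L])
  } else {
    if (is.null(fs)) {
      stop("`fs` must be supplied for a single-column signal file",
           call. = FALSE)
    }
    ppg_signal(df[[1L]], fs = fs)
  }
}

#' Write a PPG signal to CSV
#'
#' Writes the two-column `t,ppg` dialect read by [read_signal_csv()].
#'
#' @param signal A [ppg_signal()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(signal, path) {
  stopifnot(inherits(signal, "ppg_signal"))
  df <- data.frame(t = signal_times(signal), ppg = signal$samples)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write tidied beat fiducials to CSV
#'
#' Rows of `index` (1-based sample index), `time_s`, and `type` (one of
#' `onset`, `mid`, `peak`), sorted by time. Round-trips losslessly through
#' [read_beats_csv()].
#'
#' @param beats A tidied [beat_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_beats_csv <- function(beats, path) {
  stopifnot(inherits(beats, "beat_set"))
  if (!beats$tidied) stop("beats must be tidied before writing", call. = FALSE)
  validate_beat_set(beats)
  df <- data.frame(
    index = c(beats$onsets, beats$mids, beats$peaks),
    type = rep(c("onset", "mid", "peak"),
               c(length(beats$onsets), length(beats$mids),
                 length(beats$peaks))),
    stringsAsFactors = FALSE
  )
  df$time_s <- beats$t0 + (df$index - 1) / beats$fs
  df <- df[order(df$time_s, match(df$type, c("onset", "mid", "peak"))),
           c("index", "time_s", "type")]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read beat fiducials from CSV
#'
#' Inverse of [write_beats_csv()].
#'
#' @param path Path to a beats CSV.
#' @param fs Sampling frequency (Hz) of the indexed signal.
#' @param t0 Start time offset (s) of the indexed signal.
#' @return A tidied [beat_set()].
#' @export
read_beats_csv <- function(path, fs, t0 = 0) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("index", "time_s", "type")
  if (!all(need %in% names(df))) {
    stop("beats CSV must have columns index, time_s, type", call. = FALSE)
  }
  beat_set(
    onsets = sort(df$index[df$type == "onset"]),
    mids = sort(df$index[df$type == "mid"]),
    peaks = sort(df$index[df$type == "peak"]),
    fs = fs, t0 = t0, tidied = TRUE
  )
}

#' Read reference beat times from CSV
#'
#' Accepts a single column of times in seconds (with or without a header).
#'
#' @param path Path to CSV.
#' @return A [reference_beats()] vector.
#' @export
read_reference_csv <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("[A-Za-z]", first)
  df <- utils::read.csv(path, header = has_header)
  reference_beats(df[[1L]])
}

#' Flag flat-line and missing-value regions as invalid
#'
#' Periods of no usable PPG signal are excluded from analysis: runs of at
#' least `flat_min_s` seconds of identical consecutive samples, and any
#' non-finite samples, are marked invalid in the validity mask. All other
#' entries are left unchanged, so the operation is idempotent.
#'
#' @param signal A [ppg_signal()].
#' @param flat_min_s Minimum flat-run duration (s) to flag; default 1 s,
#'   longer than any physiological plateau at plausible heart rates.
#' @return The signal with an updated `valid_mask`.
#' @export
mark_invalid_regions <- function(signal, flat_min_s = 1) {
  stopifnot(inherits(signal, "ppg_signal"), flat_min_s > 0)
  x <- signal$samples
  mask <- signal$valid_mask & is.finite(x)
  n <- length(x)
  if (n >= 2L) {
    min_run <- flat_min_s * signal$fs
    same <- c(FALSE, x[-1L] == x[-n])  # same[i]: x[i] equals x[i-1]
    same[is.na(same)] <- FALSE
    r <- rle(same)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in seq_along(r$lengths)) {
      # a run of k TRUEs means k+1 identical samples starting one earlier
      if (r$values[j] && (r$lengths[j] + 1L) >= min_run) {
        mask[(starts[j] - 1L):ends[j]] <- FALSE
      }
    }
  }
  signal$valid_mask <- mask
  signal
}

#' Invalid sample regions as time intervals
#'
#' @param signal A [ppg_signal()].
#' @return Data frame with columns `start_s`, `end_s` (closed intervals of
#'   invalid time, sample-resolution).
#' @export
invalid_intervals <- function(signal) {
  stopifnot(inherits(signal, "ppg_signal"))
  bad <- !signal$valid_mask
  if (!any(bad)) return(data.frame(start_s = numeric(), end_s = numeric()))
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  t <- signal_times(signal)
  data.frame(start_s = t[starts[keep]], end_s = t[ends[keep]])
}
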