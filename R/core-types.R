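#' Construct a PPG signal object
#'
#' A `ppg_signal` holds a single-channel photoplethysmogram: a numeric vector
#' of sample amplitudes (arbitrary units), its sampling frequency, a start-time
#' offset, and a per-sample validity mask. The time of sample `i` (1-based) is
#' `t0 + (i - 1) / fs`.
#'
#' @param samples Numeric vector of amplitudes. Non-finite values are kept in
#'   place but flagged invalid in `valid_mask`.
#' @param fs Sampling frequency in Hz; must be a single positive number.
#' @param t0 Start time offset in seconds (default 0).
#' @param valid_mask Optional logical vector, one entry per sample
#'   (`TRUE` = usable). Defaults to finiteness of `samples`.
#' @return An object of class `ppg_signal` with fields `samples`, `fs`, `t0`,
#'   `valid_mask`.
#' @examples
#' sig <- ppg_signal(sin(2 * pi * 1.2 * seq(0, 10, by = 1 / 50)), fs = 50)
#' sig
#' @export
ppg_signal <- function(samples, fs, t0 = 0, valid_mask = NULL) {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  }
  if (is.null(valid_mask)) {
    valid_mask <- is.finite(samples)
  } else {
    valid_mask <- as.logical(valid_mask) & is.finite(samples)
  }
  if (length(valid_mask) != length(samples)) {
    stop("`valid_mask` must have one entry per sample", call. = FALSE)
  }
  structure(
    list(samples = samples, fs = as.numeric(fs), t0 = as.numeric(t0),
         valid_mask = valid_mask),
    class = "ppg_signal"
  )
}

#' @export
print.ppg_signal <- function(x, ...) {
  cat(sprintf("<ppg_signal> %d samples @ %g Hz (%.1f s), %d invalid\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              sum(!x$valid_mask)))
  invisible(x)
}

#' @export
length.ppg_signal <- function(x) length(x$samples)

#' Sample times of a PPG signal
#'
#' @param signal A [ppg_signal()].
#' @return Numeric vector of per-sample times in seconds.
#' @export
signal_times <- function(signal) {
  stopifnot(inherits(signal, "ppg_signal"))
  signal$t0 + (seq_along(signal$samples) - 1) / signal$fs
}

#' Duration of a PPG signal in seconds
#' @param signal A [ppg_signal()].
#' @return Duration in seconds (`n / fs`).
#' @export
signal_duration <- function(signal) {
  stopifnot(inherits(signal, "ppg_signal"))
  length(signal$samples) / signal$fs
}

#' Construct a set of beat fiducials
#'
#' A `beat_set` indexes pulse-wave onsets, systolic-upslope mid-points and
#' systolic peaks into one signal, using 1-based sample indices. A *tidied*
#' beat set satisfies the detector post-processing contract: onsets and peaks
#' strictly alternate, starting with an onset and ending with a peak, with
#' equal counts; each mid-point lies after its onset and at or before its peak.
#'
#' @param onsets,mids,peaks Ascending integer sample indices (1-based). `mids`
#'   may be empty even when tidied (mid-points are attached late in the
#'   pipeline).
#' @param fs Sampling frequency (Hz) of the indexed signal.
#' @param t0 Start time offset (s) of the indexed signal.
#' @param tidied Logical: does this set claim the tidied invariants? Checked
#'   by [validate_beat_set()].
#' @return Object of class `beat_set`.
#' @seealso [tidy_beats()], [midpoints()]
#' @export
beat_set <- function(onsets = integer(), mids = integer(), peaks = integer(),
                     fs, t0 = 0, tidied = FALSE) {
  bs <- structure(
    list(onsets = as.integer(onsets), mids = as.integer(mids),
         peaks = as.integer(peaks), fs = as.numeric(fs), t0 = as.numeric(t0),
         tidied = isTRUE(tidied)),
    class = "beat_set"
  )
  validate_beat_set(bs)
  bs
}

#' Validate beat-set invariants
#'
#' Checks ascending order and no repeats within each fiducial list; for tidied
#' sets additionally checks equal onset/peak counts, strict onset/peak
#' alternation (onset first, peak last), and that each mid satisfies
#' `onset < mid <= peak` for its pair.
#'
#' @param bs A [beat_set()].
#' @return `bs`, invisibly; stops on violation.
#' @export
validate_beat_set <- function(bs) {
  stopifnot(inherits(bs, "beat_set"))
  for (f in c("onsets", "mids", "peaks")) {
    v <- bs[[f]]
    if (anyNA(v)) stop(sprintf("`%s` contains NA", f), call. = FALSE)
    if (length(v) > 1L && any(diff(v) <= 0)) {
      stop(sprintf("`%s` must be strictly ascending", f), call. = FALSE)
    }
    if (length(v) && any(v < 1L)) {
      stop(sprintf("`%s` must be 1-based positive indices", f), call. = FALSE)
    }
  }
  if (bs$tidied) {
    if (length(bs$onsets) != length(bs$peaks)) {
      stop("tidied beat set must have equal onset and peak counts",
           call. = FALSE)
    }
    if (length(bs$onsets)) {
      if (!all(bs$onsets < bs$peaks)) {
        stop("tidied beats must alternate onset -> peak", call. = FALSE)
      }
      if (length(bs$peaks) > 1L &&
          !all(bs$peaks[-length(bs$peaks)] < bs$onsets[-1L])) {
        stop("tidied beats must alternate peak -> next onset", call. = FALSE)
      }
    }
    if (length(bs$mids)) {
      if (length(bs$mids) != length(bs$onsets)) {
        stop("tidied mids must pair one-to-one with onsets", call. = FALSE)
      }
      if (!all(bs$mids > bs$onsets & bs$mids <= bs$peaks)) {
        stop("each mid must satisfy onset < mid <= peak", call. = FALSE)
      }
    }
  }
  invisible(bs)
}

#' @export
print.beat_set <- function(x, ...) {
  cat(sprintf("<beat_set> %d onsets, %d mids, %d peaks @ %g Hz%s\n",
              length(x$onsets), length(x$mids), length(x$peaks), x$fs,
              if (x$tidied) " (tidied)" else ""))
  invisible(x)
}

#' Fiducial times in seconds
#'
#' Converts the 1-based sample indices of a beat set to times,
#' `t0 + (index - 1) / fs`.
#'
#' @param bs A [beat_set()].
#' @param which One of `"peaks"`, `"onsets"`, `"mids"`.
#' @return Numeric vector of times (s).
#' @export
beat_times_s <- function(bs, which = c("peaks", "onsets", "mids")) {
  stopifnot(inherits(bs, "beat_set"))
  which <- match.arg(which)
  bs$t0 + (bs[[which]] - 1) / bs$fs
}

#' Construct reference beat times
#'
#' Reference beats (in this framework typically derived from a simultaneous
#' ECG, or from synthetic ground truth) are consumed as a strictly increasing
#' vector of non-negative times in seconds.
#'
#' @param times Numeric vector of beat times (s).
#' @return Object of class `reference_beats` (a validated numeric vector).
#' @export
reference_beats <- function(times) {
  times <- as.numeric(times)
  if (anyNA(times)) stop("reference beat times contain NA", call. = FALSE)
  if (length(times) && any(times < 0)) {
    stop("reference beat times must be non-negative", call. = FALSE)
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("reference beat times must be strictly increasing", call. = FALSE)
  }
  structure(times, class = "reference_beats")
}
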