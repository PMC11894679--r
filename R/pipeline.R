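#' Framework configuration for beat detection around any detector
#'
#' The assessment framework segments records into 20 s windows with 5 s
#' overlap, band-pass filters each window between 0.67 and 8.00 Hz, runs the
#' detector, post-processes detections (de-duplication and tidying), attaches
#' systolic-upslope mid-points, and excludes periods of no usable signal.
#'
#' @param window_s Framework window duration (s); default 20.
#' @param overlap_s Overlap between consecutive windows (s); default 5.
#' @param band Two-element band edges (Hz); default `c(0.67, 8)`.
#' @param filter_order Butterworth pole pairs per band edge; default 4,
#'   applied forward-backward (zero phase) so fiducial timing is preserved.
#' @param flat_min_s Flat-line threshold (s) passed to
#'   [mark_invalid_regions()]; default 1.
#' @return A `framework_config`.
#' @export
framework_config <- function(window_s = 20, overlap_s = 5,
                             band = c(0.67, 8), filter_order = 4,
                             flat_min_s = 1) {
  stopifnot(window_s > overlap_s, overlap_s >= 0,
            length(band) == 2L, band[1] > 0, band[1] < band[2],
            filter_order >= 1, flat_min_s > 0)
  structure(
    list(window_s = window_s, overlap_s = overlap_s, band = band,
         filter_order = filter_order, flat_min_s = flat_min_s),
    class = "framework_config"
  )
}

#' Segment a signal into overlapping framework windows
#'
#' Windows start at 0, `window_s - overlap_s`, `2 (window_s - overlap_s)`,
#' ...; a trailing partial window is kept when at least `overlap_s` long.
#'
#' @param signal A [ppg_signal()].
#' @param window_s Window duration (s).
#' @param overlap_s Overlap (s), `0 <= overlap_s < window_s`.
#' @return List of elements `list(start_sample, signal)` where
#'   `start_sample` is the 1-based offset of the window in the record.
#' @export
segment_signal <- function(signal, window_s = 20, overlap_s = 5) {
  stopifnot(inherits(signal, "ppg_signal"), window_s > overlap_s,
            overlap_s >= 0)
  fs <- signal$fs
  n <- length(signal$samples)
  wlen <- as.integer(round(window_s * fs))
  stride <- as.integer(round((window_s - overlap_s) * fs))
  min_tail <- as.integer(ceiling(overlap_s * fs))
  out <- list()
  s0 <- 1L
  repeat {
    e0 <- min(n, s0 + wlen - 1L)
    len <- e0 - s0 + 1L
    full <- len == wlen
    if (s0 == 1L || full || len >= min_tail) {
      out[[length(out) + 1L]] <- list(
        start_sample = s0,
        signal = ppg_signal(signal$samples[s0:e0], fs = fs,
                            t0 = signal$t0 + (s0 - 1L) / fs,
                            valid_mask = signal$valid_mask[s0:e0])
      )
    }
    if (e0 >= n) break
    s0 <- s0 + stride
    if (s0 > n) break
  }
  out
}

#' Zero-phase band-pass filter
#'
#' Butterworth band-pass applied forward-backward ([signal::filtfilt()]),
#' preserving fiducial timing. Non-finite samples are linearly interpolated
#' before filtering (the validity mask still records them); the mask is
#' carried through unchanged.
#'
#' @param sig A [ppg_signal()].
#' @param low,high Band edges (Hz); `high` must be below the Nyquist
#'   frequency -- filter before decimating.
#' @param order Pole pairs per edge (default 4).
#' @return Filtered [ppg_signal()].
#' @export
bandpass <- function(sig, low = 0.67, high = 8, order = 4) {
  stopifnot(inherits(sig, "ppg_signal"), low > 0, low < high)
  fs <- sig$fs
  if (high >= fs / 2) {
    stop("band edge must be below Nyquist (filter before decimation)",
         call. = FALSE)
  }
  x <- sig$samples
  if (anyNA(x) || any(!is.finite(x))) {
    ok <- is.finite(x)
    if (sum(ok) >= 2L) {
      x[!ok] <- stats::approx(which(ok), x[ok], xout = which(!ok),
                              rule = 2)$y
    } else {
      x[!ok] <- 0
    }
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, x)
  ppg_signal(y, fs = fs, t0 = sig$t0, valid_mask = sig$valid_mask)
}

#' Tidy raw peak/onset detections into a consistent beat set
#'
#' Applies, in order: (1) duplicate detections removed; (2) indices detected
#' as both peak and onset keep only the peak; (3) runs of consecutive
#' same-type fiducials are collapsed so exactly one onset remains between
#' consecutive peaks (the lowest-amplitude candidate) and exactly one peak
#' between consecutive onsets (the highest-amplitude candidate), ties going
#' to the earlier index; (4) leading peaks before the first onset and
#' trailing onsets after the last peak are dropped, so the sequence starts
#' with an onset and ends with a peak. The result has equal onset and peak
#' counts and strict alternation, and the operation is idempotent.
#'
#' When no onsets are supplied (peak-only detectors), onsets are synthesised
#' as the minimum sample between consecutive peaks and before the first peak.
#'
#' @param peaks,onsets Integer sample indices (1-based, any order).
#' @param x Numeric sample vector the indices point into.
#' @param fs,t0 Sampling rate (Hz) and start offset (s) recorded on the
#'   returned beat set.
#' @return A tidied [beat_set()] (mids empty; see [midpoints()]).
#' @export
tidy_beats <- function(peaks, onsets, x, fs, t0 = 0) {
  peaks <- sort(unique(as.integer(peaks)))
  onsets <- sort(unique(as.integer(onsets)))
  stopifnot(all(peaks >= 1L), all(peaks <= length(x)),
            all(onsets >= 1L), all(onsets <= length(x)))
  if (length(onsets) == 0L && length(peaks) >= 1L) {
    onsets <- synth_onsets_between(peaks, x)
  }
  onsets <- setdiff(onsets, peaks)                      # rule (2)
  idx <- c(onsets, peaks)
  type <- rep(c(1L, 2L), c(length(onsets), length(peaks)))  # 1 onset, 2 peak
  o <- order(idx)
  idx <- idx[o]; type <- type[o]
  if (length(idx) == 0L) {
    return(beat_set(fs = fs, t0 = t0, tidied = TRUE))
  }
  # rule (3): collapse runs of same-type fiducials
  r <- rle(type)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- integer(length(r$lengths))
  for (j in seq_along(r$lengths)) {
    run <- starts[j]:ends[j]
    amp <- x[idx[run]]
    pick <- if (r$values[j] == 1L) which.min(amp) else which.max(amp)
    keep[j] <- run[pick]
  }
  idx <- idx[keep]; type <- type[keep]
  # rule (4): start with an onset, end with a peak
  first_on <- match(1L, type)
  last_pk <- length(type) + 1L - match(2L, rev(type))
  if (is.na(first_on) || is.na(last_pk) || first_on > last_pk) {
    return(beat_set(fs = fs, t0 = t0, tidied = TRUE))
  }
  sel <- first_on:last_pk
  beat_set(onsets = idx[sel][type[sel] == 1L],
           peaks = idx[sel][type[sel] == 2L],
           fs = fs, t0 = t0, tidied = TRUE)
}

# minimum sample between consecutive peaks, used when a detector reports
# peaks only; a lone peak gets no onset and is trimmed by rule (4)
synth_onsets_between <- function(peaks, x) {
  on <- integer()
  for (j in seq_along(peaks)[-1]) {
    lo <- peaks[j - 1L]
    hi <- peaks[j]
    if (hi - lo >= 2L) {
      seg <- (lo + 1L):(hi - 1L)
      on <- c(on, seg[which.min(x[seg])])
    }
  }
  sort(unique(on))
}

#' Systolic-upslope mid-points
#'
#' For each onset-peak pair of a tidied beat set, the mid-point is the first
#' sample after the onset at which the signal reaches half of the
#' onset-to-peak amplitude: the first `j` in `(onset, peak]` with
#' `x[j] >= (x[onset] + x[peak]) / 2`. This fiducial on the systolic upslope
#' is the preferred timing point for pulse-rate-variability analysis.
#'
#' @param x Numeric sample vector.
#' @param beats A tidied [beat_set()].
#' @return The beat set with its `mids` field filled (one mid per pair).
#' @export
midpoints <- function(x, beats) {
  stopifnot(inherits(beats, "beat_set"))
  if (!beats$tidied) stop("beats must be tidied first", call. = FALSE)
  n_pairs <- length(beats$onsets)
  mids <- integer(n_pairs)
  for (j in seq_len(n_pairs)) {
    on <- beats$onsets[j]
    pk <- beats$peaks[j]
    half <- (x[on] + x[pk]) / 2
    seg <- (on + 1L):pk
    hit <- seg[x[seg] >= half]
    mids[j] <- if (length(hit)) hit[1L] else pk
  }
  beats$mids <- mids
  validate_beat_set(beats)
  beats
}

#' Run the full beat-detection pipeline on a record
#'
#' Steps: flag invalid (flat/missing) regions; segment into framework
#' windows; band-pass filter each window; detect beats per window with the
#' configured detector; map detections to record coordinates; merge
#' near-duplicates from overlapping windows (indices within one sample merge
#' to the earlier); tidy; attach mid-points; and drop any beat whose
#' fiducials fall inside invalid regions.
#'
#' @param signal A [ppg_signal()].
#' @param cfg A `detector_config` (default `msptdfastv2` preset).
#' @param fw A [framework_config()].
#' @return A tidied [beat_set()] with mids, indexed at the original rate.
#' @examples
#' rec <- synth_ppg(30, fs = 64, hr_mean = 70, noise = noise_none(), seed = 1)
#' bs <- run_pipeline(rec$signal)
#' length(bs$peaks)
#' @export
run_pipeline <- function(signal, cfg = preset_config("msptdfastv2"),
                         fw = framework_config()) {
  stopifnot(inherits(signal, "ppg_signal"))
  signal <- mark_invalid_regions(signal, fw$flat_min_s)
  if (length(signal$samples) < 3L) {
    return(beat_set(fs = signal$fs, t0 = signal$t0, tidied = TRUE))
  }
  wins <- segment_signal(signal, fw$window_s, fw$overlap_s)
  peaks <- integer()
  onsets <- integer()
  for (w in wins) {
    if (length(w$signal$samples) < 3L) next
    filt <- bandpass(w$signal, fw$band[1], fw$band[2], fw$filter_order)
    det <- detect(filt, cfg)
    peaks <- c(peaks, det$peaks + w$start_sample - 1L)
    onsets <- c(onsets, det$onsets + w$start_sample - 1L)
  }
  peaks <- merge_near_duplicates(sort(unique(peaks)), 1L)
  onsets <- merge_near_duplicates(sort(unique(onsets)), 1L)
  # amplitudes for tidying taken from the record-wide filtered signal so
  # overlapping-window rule (3) comparisons are consistent
  ref <- tryCatch(bandpass(signal, fw$band[1], fw$band[2], fw$filter_order),
                  error = function(e) signal)
  bs <- tidy_beats(peaks, onsets, ref$samples, fs = signal$fs,
                   t0 = signal$t0)
  if (length(bs$onsets)) {
    bs <- midpoints(ref$samples, bs)
    ok <- signal$valid_mask[bs$onsets] & signal$valid_mask[bs$mids] &
      signal$valid_mask[bs$peaks]
    bs <- beat_set(onsets = bs$onsets[ok], mids = bs$mids[ok],
                   peaks = bs$peaks[ok], fs = signal$fs, t0 = signal$t0,
                   tidied = TRUE)
  }
  bs
}

# collapse ascending indices that differ by <= tol samples to the earliest
merge_near_duplicates <- function(idx, tol = 1L) {
  if (length(idx) < 2L) return(idx)
  keep <- logical(length(idx))
  keep[1L] <- TRUE
  last <- idx[1L]
  for (j in 2L:length(idx)) {
    if (idx[j] - last > tol) {
      keep[j] <- TRUE
      last <- idx[j]
    }
  }
  idx[keep]
}
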