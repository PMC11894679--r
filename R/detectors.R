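#' Preset detector configurations
#'
#' The four detectors in the multiscale peak-and-trough family share one
#' configuration record; the presets differ in window duration, downsampling,
#' scale truncation, and which extrema are detected:
#'
#' * `ampd`: 6 s windows, no downsampling, no scale truncation, peaks only
#'   (onsets are synthesised during tidying as the minimum between peaks).
#' * `msptd`: 6 s windows, no downsampling, no truncation, peaks and onsets.
#' * `msptdfastv1`: 8 s windows, downsample to >= 20 Hz, scales truncated at
#'   a 30 bpm minimum heart rate, peaks and onsets.
#' * `msptdfastv2`: as v.1 but with 6 s windows.
#'
#' @param variant One of `"ampd"`, `"msptd"`, `"msptdfastv1"`,
#'   `"msptdfastv2"` (case-insensitive).
#' @return A `detector_config`: list with fields `variant`, `window_s`,
#'   `window_overlap_frac`, `fs_min` (Hz or `NULL`), `hr_min` (bpm or
#'   `NULL`), `extrema_mode` (`"peaks"`, `"onsets"` or `"both"`),
#'   `lms_method`.
#' @examples
#' preset_config("msptdfastv2")$window_s  # 6
#' @export
preset_config <- function(variant = c("msptdfastv2", "msptd", "ampd",
                                      "msptdfastv1")) {
  variant <- tolower(variant[1L])
  base <- list(window_overlap_frac = 0.2, lms_method = "vectorised")
  cfg <- switch(
    variant,
    ampd = c(list(variant = "ampd", window_s = 6, fs_min = NULL,
                  hr_min = NULL, extrema_mode = "peaks"), base),
    msptd = c(list(variant = "msptd", window_s = 6, fs_min = NULL,
                   hr_min = NULL, extrema_mode = "both"), base),
    msptdfastv1 = c(list(variant = "msptdfastv1", window_s = 8, fs_min = 20,
                         hr_min = 30, extrema_mode = "both"), base),
    msptdfastv2 = c(list(variant = "msptdfastv2", window_s = 6, fs_min = 20,
                         hr_min = 30, extrema_mode = "both"), base),
    stop("unknown detector variant: ", variant, call. = FALSE)
  )
  structure(cfg, class = "detector_config")
}

#' Build a custom detector configuration
#'
#' Exposes the full configuration space explored when designing the fast
#' variants: which extrema to detect, loop vs vectorised scalograms, scale
#' truncation via a minimum heart rate, a downsampling floor, and the window
#' duration.
#'
#' @param variant Label for reports.
#' @param window_s Detector window duration (s, > 0).
#' @param window_overlap_frac Fraction of each detector window shared with
#'   the next (0 <= f < 1); default 0.2, preventing boundary-missed beats
#'   (duplicates are removed at merge).
#' @param fs_min Downsampling floor (Hz) or `NULL` to keep the original rate.
#' @param hr_min Minimum plausible heart rate (bpm) for scale truncation, or
#'   `NULL` for untruncated scalograms.
#' @param extrema_mode `"peaks"`, `"onsets"` or `"both"`.
#' @param lms_method `"vectorised"` or `"loops"` (identical output).
#' @return A `detector_config`.
#' @export
detector_config <- function(variant = "custom", window_s = 6,
                            window_overlap_frac = 0.2, fs_min = NULL,
                            hr_min = NULL,
                            extrema_mode = c("both", "peaks", "onsets"),
                            lms_method = c("vectorised", "loops")) {
  stopifnot(window_s > 0, window_overlap_frac >= 0, window_overlap_frac < 1,
            is.null(fs_min) || fs_min > 0, is.null(hr_min) || hr_min > 0)
  structure(
    list(variant = variant, window_s = window_s,
         window_overlap_frac = window_overlap_frac, fs_min = fs_min,
         hr_min = hr_min, extrema_mode = match.arg(extrema_mode),
         lms_method = match.arg(lms_method)),
    class = "detector_config"
  )
}

#' @export
print.detector_config <- function(x, ...) {
  cat(sprintf(
    "<detector_config> %s: window %gs (overlap %g), fs_min %s, hr_min %s, %s extrema, %s LMS\n",
    x$variant, x$window_s, x$window_overlap_frac,
    if (is.null(x$fs_min)) "none" else paste0(x$fs_min, " Hz"),
    if (is.null(x$hr_min)) "none" else paste0(x$hr_min, " bpm"),
    x$extrema_mode, x$lms_method))
  invisible(x)
}

#' Greatest integer downsampling factor keeping at least `fs_min`
#'
#' `m = max(1, floor(fs / fs_min))`, so the decimated rate `fs / m` is at
#' least `fs_min` whenever `fs >= fs_min`; signals slower than `fs_min` are
#' never upsampled.
#'
#' @param fs Original sampling frequency (Hz, > 0).
#' @param fs_min Downsampling floor (Hz, > 0).
#' @return Integer factor `m >= 1`.
#' @examples
#' downsample_factor(300, 20)  # 15
#' downsample_factor(64, 20)   # 3 (64/3 ~ 21.3 Hz; /4 would fall below 20)
#' @export
downsample_factor <- function(fs, fs_min) {
  stopifnot(fs > 0, fs_min > 0)
  max(1L, as.integer(floor(fs / fs_min)))
}

#' Decimate a PPG signal by plain subsampling
#'
#' Keeps every `m`-th sample starting at the first; the validity mask is
#' subsampled identically and the new rate is `fs / m`. No additional
#' anti-alias filter is applied: in the beat-detection pipeline the framework
#' band-pass (0.67-8 Hz) runs before detection, and 8 Hz is below the Nyquist
#' frequency of any decimated rate at or above 20 Hz.
#'
#' @param signal A [ppg_signal()].
#' @param m Integer factor >= 1 (1 is the identity).
#' @return Decimated [ppg_signal()].
#' @export
decimate_signal <- function(signal, m) {
  stopifnot(inherits(signal, "ppg_signal"), m >= 1)
  m <- as.integer(m)
  if (m == 1L) return(signal)
  keep <- seq.int(1L, length(signal$samples), by = m)
  ppg_signal(signal$samples[keep], fs = signal$fs / m, t0 = signal$t0,
             valid_mask = signal$valid_mask[keep])
}

#' Detect extrema in a single detector window
#'
#' The per-window detection pipeline: linear detrend; choose the number of
#' scales (truncated by `hr_min` when set); build the local maxima scalogram
#' for each requested polarity; select the scale with the most flagged
#' extrema; and extract samples flagged at every retained scale. Indices are
#' window-local at the supplied (possibly decimated) rate.
#'
#' @param x Numeric sample vector (length >= 3).
#' @param fs Sampling frequency of `x` (Hz).
#' @param cfg A `detector_config`.
#' @return List with ascending integer `peaks` and `onsets` (either may be
#'   empty; constant windows yield both empty).
#' @export
detect_window <- function(x, fs, cfg) {
  stopifnot(inherits(cfg, "detector_config"))
  n <- length(x)
  if (n < 3L) stop("window must have at least 3 samples", call. = FALSE)
  if (all(x == x[1L])) return(list(peaks = integer(), onsets = integer()))
  xd <- detrend_linear(x)
  L <- max_scale_for_hrmin(fs, cfg$hr_min, n)
  peaks <- integer()
  onsets <- integer()
  if (cfg$extrema_mode %in% c("peaks", "both")) {
    peaks <- lms_extrema(xd, L, "maxima", cfg$lms_method)
  }
  if (cfg$extrema_mode %in% c("onsets", "both")) {
    onsets <- lms_extrema(xd, L, "minima", cfg$lms_method)
  }
  list(peaks = peaks, onsets = onsets)
}

#' Detect beats across a whole record
#'
#' Decimates the signal (when the configuration sets a downsampling floor),
#' slices it into detector windows of `cfg$window_s` seconds with
#' `cfg$window_overlap_frac` overlap (a trailing partial window is processed
#' when at least 2 s long -- long enough to hold one beat at 30 bpm), runs
#' [detect_window()] per window, maps window-local decimated indices back to
#' original-rate sample indices, and merges the windows' detections with
#' exact duplicates removed.
#'
#' The result is untidied: peak/onset lists may disagree in count and
#' ordering until passed through [tidy_beats()] (done by [run_pipeline()]).
#'
#' @param signal A [ppg_signal()].
#' @param cfg A `detector_config` (default the `msptdfastv2` preset).
#' @return List with ascending original-rate integer `peaks` and `onsets`,
#'   plus `m` (the decimation factor used).
#' @export
detect <- function(signal, cfg = preset_config("msptdfastv2")) {
  stopifnot(inherits(signal, "ppg_signal"), inherits(cfg, "detector_config"))
  m <- if (is.null(cfg$fs_min)) 1L else downsample_factor(signal$fs, cfg$fs_min)
  dec <- decimate_signal(signal, m)
  n <- length(dec$samples)
  if (n < 3L) return(list(peaks = integer(), onsets = integer(), m = m))
  wlen <- max(3L, as.integer(round(cfg$window_s * dec$fs)))
  stride <- max(1L, as.integer(round(wlen * (1 - cfg$window_overlap_frac))))
  min_tail <- as.integer(ceiling(2 * dec$fs))  # >= 2 s
  starts <- seq.int(1L, max(1L, n), by = stride)
  peaks <- integer()
  onsets <- integer()
  for (s0 in starts) {
    e0 <- min(n, s0 + wlen - 1L)
    if (s0 > 1L && (e0 - s0 + 1L) < max(3L, min_tail)) next
    if (e0 - s0 + 1L < 3L) next
    res <- detect_window(dec$samples[s0:e0], dec$fs, cfg)
    peaks <- c(peaks, res$peaks + s0 - 1L)
    onsets <- c(onsets, res$onsets + s0 - 1L)
    if (e0 == n) break
  }
  # decimated index -> original-rate index
  list(peaks = sort(unique((peaks - 1L) * m + 1L)),
       onsets = sort(unique((onsets - 1L) * m + 1L)),
       m = m)
}
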