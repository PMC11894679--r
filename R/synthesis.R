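#' Heart-rate modulation specifications
#'
#' Helpers describing how interbeat intervals (IBIs) evolve over a synthetic
#' record: constant rate, sinusoidal modulation (e.g. respiratory sinus
#' arrhythmia), or atrial-fibrillation-like irregularity in which each IBI is
#' multiplied by an independent log-normal factor.
#'
#' @param amp Modulation amplitude (bpm).
#' @param period Modulation period (s).
#' @param jitter_sd Standard deviation of `log(IBI factor)`; the IBI
#'   coefficient of variation is approximately `jitter_sd` for small values.
#' @return A list tagging the modulation type and parameters.
#' @name hr_modulation
NULL

#' @rdname hr_modulation
#' @export
hr_mod_none <- function() list(type = "none")

#' @rdname hr_modulation
#' @export
hr_mod_sinusoidal <- function(amp = 5, period = 12) {
  stopifnot(amp >= 0, period > 0)
  list(type = "sinusoidal", amp = amp, period = period)
}

#' @rdname hr_modulation
#' @export
hr_mod_af <- function(jitter_sd = 0.2) {
  stopifnot(jitter_sd > 0)
  list(type = "af_like", jitter_sd = jitter_sd)
}

#' Simulate a train of beat times
#'
#' Draws interbeat intervals from the requested heart-rate profile, starting
#' at time 0 and continuing until the record duration is filled.
#'
#' @param duration_s Record duration (s).
#' @param hr_mean Mean heart rate (bpm), within the physiological range
#'   `[20, 220]`.
#' @param hr_modulation One of [hr_mod_none()], [hr_mod_sinusoidal()],
#'   [hr_mod_af()].
#' @param seed Integer seed; the same seed reproduces the times exactly.
#' @return Strictly increasing numeric vector of beat (pulse-onset) times (s).
#' @export
beat_times <- function(duration_s, hr_mean = 75, hr_modulation = hr_mod_none(),
                       seed = 1) {
  if (hr_mean < 20 || hr_mean > 220) {
    stop("hr_mean must lie in [20, 220] bpm", call. = FALSE)
  }
  stopifnot(duration_s > 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  ibi0 <- 60 / hr_mean
  times <- numeric(0)
  t <- 0
  while (t < duration_s) {
    ibi <- switch(
      hr_modulation$type,
      none = ibi0,
      sinusoidal = {
        hr_t <- hr_mean + hr_modulation$amp *
          sin(2 * pi * t / hr_modulation$period)
        60 / max(20, min(220, hr_t))
      },
      af_like = ibi0 * stats::rlnorm(1, meanlog = 0,
                                     sdlog = hr_modulation$jitter_sd),
      stop("unknown hr modulation type", call. = FALSE)
    )
    times <- c(times, t)
    t <- t + ibi
  }
  times
}

#' Pulse-wave shape constants
#'
#' The synthetic pulse is the sum of two Gaussians on one interbeat
#' interval: a systolic wave (amplitude 1.0, centre 0.25 IBI, width 0.09
#' IBI) and a diastolic wave (amplitude 0.35, centre 0.55 IBI, width 0.14
#' IBI). All constants are expressed as fractions of the IBI so the shape
#' scales with heart rate.
#'
#' The fractional constants are applied to an *effective* interval
#' `min(IBI, ref_ibi_s)`: at high heart rates the pulse compresses with the
#' IBI, while for long IBIs (slow heart rates) the systolic/dicrotic geometry
#' stays fixed at the reference-interval shape -- as in real pulse waves,
#' where ejection timing is roughly constant and diastole lengthens as a
#' quiescent runoff -- and the Gaussian tail decays over the remaining
#' diastole.
#'
#' @param sys_amp,sys_mu,sys_sd Systolic amplitude, centre, width.
#' @param dia_amp,dia_mu,dia_sd Diastolic amplitude, centre, width.
#' @param ref_ibi_s Reference interval (s) capping the shape geometry.
#' @return List of shape constants.
#' @export
pulse_shape <- function(sys_amp = 1.0, sys_mu = 0.25, sys_sd = 0.09,
                        dia_amp = 0.35, dia_mu = 0.55, dia_sd = 0.14,
                        ref_ibi_s = 1.0) {
  list(sys_amp = sys_amp, sys_mu = sys_mu, sys_sd = sys_sd,
       dia_amp = dia_amp, dia_mu = dia_mu, dia_sd = dia_sd,
       ref_ibi_s = ref_ibi_s)
}

#' One synthetic pulse waveform
#'
#' Samples the two-Gaussian pulse over one interbeat interval. The waveform
#' has a unique global maximum (the systolic peak, near 0.25 IBI from the
#' start) and its onset is the first sample.
#'
#' @param fs Sampling frequency (Hz); `fs * ibi_s` must be at least 4
#'   samples.
#' @param ibi_s Interbeat interval (s).
#' @param shape A [pulse_shape()].
#' @return Numeric waveform of `round(fs * ibi_s)` samples.
#' @export
pulse_template <- function(fs, ibi_s, shape = pulse_shape()) {
  n <- as.integer(round(fs * ibi_s))
  if (n < 4L) stop("IBI too short for this sampling frequency", call. = FALSE)
  pulse_eval((seq_len(n) - 1) / fs, ibi_s, shape)
}

# continuous-time pulse evaluation at offsets `t` (s) from the pulse onset
pulse_eval <- function(t, ibi_s, shape) {
  ibi_eff <- min(ibi_s, shape$ref_ibi_s %||% 1.0)
  shape$sys_amp * exp(-((t - shape$sys_mu * ibi_eff)^2) /
                        (2 * (shape$sys_sd * ibi_eff)^2)) +
    shape$dia_amp * exp(-((t - shape$dia_mu * ibi_eff)^2) /
                          (2 * (shape$dia_sd * ibi_eff)^2))
}

# continuous ground-truth fiducials of one pulse: peak time and the first
# half-amplitude crossing (mid), as offsets from the pulse onset; 1 ms grid
pulse_truth <- function(ibi_s, shape) {
  ibi_eff <- min(ibi_s, shape$ref_ibi_s %||% 1.0)
  tg <- seq(0, ibi_eff, by = 1e-3)
  v <- pulse_eval(tg, ibi_s, shape)
  pk <- which.max(v)
  half <- (v[1L] + v[pk]) / 2
  hit <- which(v[seq_len(pk)] >= half)[1L]
  list(t_peak = tg[pk], t_mid = tg[hit])
}

#' Noise specifications for synthetic records
#'
#' `noise_spec()` describes additive corruption: white measurement noise
#' (standard deviation in pulse-amplitude units, where the systolic peak is
#' 1.0), sinusoidal baseline wander (amplitude and frequency; the default
#' 0.25 Hz mimics respiration), and motion-artifact bursts (high-amplitude
#' noise episodes of 1-3 s at a Poisson rate per minute). `noise_none()` is
#' the clean limit.
#'
#' @param white_sd White-noise standard deviation; default 0.05 (a
#'   hospital-grade signal).
#' @param wander_amp Baseline-wander amplitude; default 0.2.
#' @param wander_freq Baseline-wander frequency (Hz); default 0.25.
#' @param burst_rate Expected motion bursts per minute; default 0.
#' @param burst_sd White-noise standard deviation inside a burst; default 2.
#' @return List of noise parameters.
#' @export
noise_spec <- function(white_sd = 0.05, wander_amp = 0.2, wander_freq = 0.25,
                       burst_rate = 0, burst_sd = 2) {
  stopifnot(white_sd >= 0, wander_amp >= 0, wander_freq >= 0,
            burst_rate >= 0, burst_sd >= 0)
  list(white_sd = white_sd, wander_amp = wander_amp,
       wander_freq = wander_freq, burst_rate = burst_rate,
       burst_sd = burst_sd)
}

#' @rdname noise_spec
#' @export
noise_none <- function() noise_spec(white_sd = 0, wander_amp = 0,
                                    wander_freq = 0, burst_rate = 0)

#' Generate a synthetic PPG record with ground truth
#'
#' Concatenates per-beat two-Gaussian pulse templates at the simulated beat
#' times, then adds baseline wander, white noise, and optional motion
#' bursts. Ground-truth fiducials (onset, systolic-upslope mid-point, and
#' systolic peak times) are recorded from the clean template geometry before
#' any noise is added, using the same half-amplitude mid-point rule as the
#' detection pipeline.
#'
#' @param duration_s Record duration (s).
#' @param fs Sampling frequency (Hz).
#' @param hr_mean Mean heart rate (bpm).
#' @param hr_modulation See [hr_modulation].
#' @param noise A [noise_spec()].
#' @param shape A [pulse_shape()].
#' @param seed Integer seed; regenerating with the same arguments and seed
#'   reproduces the record bit-exactly.
#' @return A `synthetic_record`: list with `signal` (a [ppg_signal()]),
#'   ground-truth `peaks_s`, `onsets_s`, `mids_s` (times in s),
#'   `hr_profile` (per-beat bpm), and the generating `params`.
#' @examples
#' rec <- synth_ppg(60, fs = 125, hr_mean = 60, noise = noise_none(), seed = 7)
#' length(rec$peaks_s)  # ~60 beats
#' @export
synth_ppg <- function(duration_s = 120, fs = 125, hr_mean = 75,
                      hr_modulation = hr_mod_none(), noise = noise_spec(),
                      shape = pulse_shape(), seed = 1) {
  params <- list(duration_s = duration_s, fs = fs, hr_mean = hr_mean,
                 hr_modulation = hr_modulation, noise = noise, shape = shape,
                 seed = seed)
  onsets_s <- beat_times(duration_s, hr_mean, hr_modulation, seed = seed)
  n <- as.integer(round(duration_s * fs))
  x <- numeric(n)
  peaks_s <- numeric(0)
  mids_s <- numeric(0)
  keep <- logical(length(onsets_s))
  ibis <- diff(c(onsets_s, duration_s))
  truth_cache <- list()
  for (j in seq_along(onsets_s)) {
    o <- onsets_s[j]
    ibi <- ibis[j]
    if (round(fs * ibi) < 4) next
    # pulse evaluated at exact continuous offsets (no sample-grid timing
    # jitter), with Gaussian tails overlap-added across beat boundaries so
    # the waveform is smooth
    ibi_eff <- min(ibi, shape$ref_ibi_s %||% 1.0)
    i0 <- max(1L, as.integer(ceiling((o - 0.3 * ibi_eff) * fs)) + 1L)
    i1 <- min(n, as.integer(ceiling((o + ibi + 0.9 * ibi_eff) * fs)))
    if (i0 > n || i1 < i0) next
    tt <- ((i0:i1) - 1) / fs - o
    x[i0:i1] <- x[i0:i1] + pulse_eval(tt, ibi, shape)
    key <- sprintf("%.6f", min(ibi, shape$ref_ibi_s %||% 1.0))
    if (is.null(truth_cache[[key]])) truth_cache[[key]] <- pulse_truth(ibi, shape)
    tr <- truth_cache[[key]]
    if (o + tr$t_peak >= duration_s) next
    keep[j] <- TRUE
    peaks_s <- c(peaks_s, o + tr$t_peak)
    mids_s <- c(mids_s, o + tr$t_mid)
  }
  onsets_s <- onsets_s[keep]
  hr_profile <- if (length(onsets_s) > 1L) 60 / diff(onsets_s) else numeric(0)
  # noise components drawn from a seed offset so the pulse train and the
  # noise are independently reproducible
  set.seed(as.integer(seed) + 1000003L)
  t <- (seq_len(n) - 1) / fs
  if (noise$wander_amp > 0 && noise$wander_freq > 0) {
    phase <- stats::runif(1, 0, 2 * pi)
    x <- x + noise$wander_amp * sin(2 * pi * noise$wander_freq * t + phase)
  }
  if (noise$white_sd > 0) {
    x <- x + stats::rnorm(n, sd = noise$white_sd)
  }
  if (noise$burst_rate > 0) {
    n_burst <- stats::rpois(1, noise$burst_rate * duration_s / 60)
    for (b in seq_len(n_burst)) {
      len_s <- stats::runif(1, 1, 3)
      start_s <- stats::runif(1, 0, max(0, duration_s - len_s))
      i0 <- as.integer(round(start_s * fs)) + 1L
      i1 <- min(n, i0 + as.integer(round(len_s * fs)) - 1L)
      x[i0:i1] <- x[i0:i1] + stats::rnorm(i1 - i0 + 1L, sd = noise$burst_sd)
    }
  }
  structure(
    list(signal = ppg_signal(x, fs = fs),
         peaks_s = peaks_s, onsets_s = onsets_s, mids_s = mids_s,
         hr_profile = hr_profile, params = params),
    class = "synthetic_record"
  )
}

#' @export
print.synthetic_record <- function(x, ...) {
  cat(sprintf(
    "<synthetic_record> %.0f s @ %g Hz, %d beats (mean HR %.1f bpm), white sd %g\n",
    x$params$duration_s, x$params$fs, length(x$peaks_s),
    if (length(x$hr_profile)) mean(x$hr_profile) else NA_real_,
    x$params$noise$white_sd))
  invisible(x)
}

#' Calibrate white noise to a target signal-to-noise ratio
#'
#' Rescales the record's white-noise standard deviation by bisection until
#' the median windowed SNR (per [snr_windows()]) is within 1 dB of the
#' target. The record is regenerated from its stored parameters at each
#' step, so the pulse train is unchanged and only the noise scales.
#'
#' @param record A [synth_ppg()] record.
#' @param target_snr_db Target median SNR (dB), within `[-10, 40]`.
#' @param tol_db Convergence tolerance (dB); default 1.
#' @param max_iter Bisection iterations; default 40.
#' @return The regenerated `synthetic_record` at the calibrated noise level,
#'   with `achieved_snr_db` recorded.
#' @export
calibrate_noise_to_snr <- function(record, target_snr_db, tol_db = 1,
                                   max_iter = 40L) {
  stopifnot(inherits(record, "synthetic_record"),
            target_snr_db >= -10, target_snr_db <= 40)
  p <- record$params
  gen <- function(sd) {
    ns <- p$noise
    ns$white_sd <- sd
    synth_ppg(p$duration_s, p$fs, p$hr_mean, p$hr_modulation, ns, p$shape,
              seed = p$seed)
  }
  med_snr <- function(rec) stats::median(snr_windows(rec$signal)$snr_db)
  lo <- 1e-4
  hi <- 10
  snr_lo <- med_snr(gen(lo))  # high SNR end
  if (snr_lo < target_snr_db - tol_db) {
    stop(sprintf(
      "target SNR %.1f dB unreachable: clean-limit median SNR is %.1f dB",
      target_snr_db, snr_lo), call. = FALSE)
  }
  if (abs(snr_lo - target_snr_db) <= tol_db) {
    out <- gen(lo)
    out$achieved_snr_db <- snr_lo
    return(out)
  }
  snr_hi <- med_snr(gen(hi))
  it <- 0L
  while (snr_hi > target_snr_db - tol_db && it < 10L) {
    hi <- hi * 4
    snr_hi <- med_snr(gen(hi))
    it <- it + 1L
  }
  if (snr_hi > target_snr_db + tol_db) {
    stop("target SNR unreachable within the noise search range",
         call. = FALSE)
  }
  for (i in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)  # bisect on log scale: SNR ~ -20 log10(sd)
    snr_mid <- med_snr(gen(mid))
    if (abs(snr_mid - target_snr_db) <= tol_db * 0.5) {
      out <- gen(mid)
      out$achieved_snr_db <- snr_mid
      return(out)
    }
    if (snr_mid > target_snr_db) lo <- mid else hi <- mid
  }
  mid <- sqrt(lo * hi)
  out <- gen(mid)
  out$achieved_snr_db <- med_snr(out)
  if (abs(out$achieved_snr_db - target_snr_db) > tol_db) {
    stop(sprintf("SNR calibration did not converge (achieved %.2f dB)",
                 out$achieved_snr_db), call. = FALSE)
  }
  out
}
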