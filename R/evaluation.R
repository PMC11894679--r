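#' Align detected beats to reference beats under clock drift
#'
#' PPG and reference (ECG) clocks are not perfectly synchronised and may
#' drift. For each 300 s chunk of the reference timeline, lags between -10
#' and +10 s (0.02 s grid) are trialled and the lag maximising the number of
#' reference beats with a shifted detection within `tol` is chosen. Ties on
#' the count (inevitable on clean data, where any lag within the tolerance
#' window of the truth matches every beat) are broken by the smallest mean
#' absolute time difference of the matched pairs, then by the smallest
#' `|lag|`, then negative. Detections in each chunk are shifted by that
#' chunk's lag.
#'
#' @param det_times,ref_times Ascending beat times (s).
#' @param max_lag Largest |lag| trialled (s); default 10.
#' @param lag_step Lag grid step (s); default 0.02.
#' @param chunk_s New lags are estimated every `chunk_s` seconds; default 300.
#' @param tol Agreement tolerance (s); default 0.15.
#' @return List with `det_aligned` (shifted detection times, re-sorted) and
#'   `trace`: data frame of `chunk_start_s`, `chunk_end_s`, `lag_s`,
#'   `matched`.
#' @export
align_beats <- function(det_times, ref_times, max_lag = 10, lag_step = 0.02,
                        chunk_s = 300, tol = 0.15) {
  det_times <- as.numeric(det_times)
  ref_times <- as.numeric(ref_times)
  if (!length(det_times) || !length(ref_times)) {
    return(list(det_aligned = det_times,
                trace = data.frame(chunk_start_s = numeric(),
                                   chunk_end_s = numeric(),
                                   lag_s = numeric(), matched = integer())))
  }
  lags <- seq(-max_lag, max_lag, by = lag_step)
  lags <- round(lags / lag_step) * lag_step  # exact grid
  t_end <- max(ref_times)
  chunk_starts <- seq(0, t_end, by = chunk_s)
  out_det <- numeric(0)
  trace <- data.frame(chunk_start_s = numeric(), chunk_end_s = numeric(),
                      lag_s = numeric(), matched = integer())
  for (cs in chunk_starts) {
    ce <- cs + chunk_s
    ref_c <- ref_times[ref_times >= cs & ref_times < ce]
    det_c <- det_times[det_times >= cs & det_times < ce]
    if (!length(ref_c) || !length(det_c)) {
      out_det <- c(out_det, det_c)
      trace <- rbind(trace, data.frame(chunk_start_s = cs, chunk_end_s = ce,
                                       lag_s = 0, matched = 0L))
      next
    }
    counts <- vapply(lags, function(tau) {
      sum(nearest_distance(ref_c, det_times + tau) <= tol + 1e-12)
    }, integer(1))
    best <- max(counts)
    cand <- lags[counts == best]
    if (length(cand) > 1L) {
      mad <- vapply(cand, function(tau) {
        d <- nearest_distance(ref_c, det_times + tau)
        mean(d[d <= tol + 1e-12])
      }, numeric(1))
      cand <- cand[abs(mad - min(mad)) <= 1e-12]
      cand <- cand[abs(abs(cand) - min(abs(cand))) <= 1e-12]
      tau <- min(cand)  # prefer negative on +/- tie
    } else {
      tau <- cand
    }
    out_det <- c(out_det, det_c + tau)
    trace <- rbind(trace, data.frame(chunk_start_s = cs, chunk_end_s = ce,
                                     lag_s = tau, matched = best))
  }
  list(det_aligned = sort(out_det), trace = trace)
}

# distance from each point of `a` to its nearest point in sorted `b`
nearest_distance <- function(a, b) {
  if (!length(b)) return(rep(Inf, length(a)))
  i <- findInterval(a, b)
  lo <- pmax(i, 1L)
  hi <- pmin(i + 1L, length(b))
  pmin(abs(a - b[lo]), abs(a - b[hi]))
}

#' Match detected beats to reference beats within a tolerance
#'
#' A reference beat is correctly identified when its closest detection lies
#' within `tol` seconds; each detection is credited to at most one reference
#' beat (greedily, by ascending reference time).
#'
#' @param det_times,ref_times Ascending beat times (s).
#' @param tol Matching tolerance (s); default 0.15 (i.e. +/-150 ms).
#' @return A `match_result`: list with counts `n_ref`, `n_det`, `n_correct`,
#'   the `tolerance`, and `matched` (logical per reference beat).
#' @export
match_beats <- function(det_times, ref_times, tol = 0.15) {
  det_times <- as.numeric(det_times)
  ref_times <- as.numeric(ref_times)
  n_ref <- length(ref_times)
  n_det <- length(det_times)
  if (!n_ref || !n_det) {
    return(structure(list(n_ref = n_ref, n_det = n_det, n_correct = 0L,
                          tolerance = tol,
                          matched = rep(FALSE, n_ref)),
                     class = "match_result"))
  }
  i <- findInterval(ref_times, det_times)
  lo <- pmax(i, 1L)
  hi <- pmin(i + 1L, n_det)
  use_lo <- abs(ref_times - det_times[lo]) <= abs(ref_times - det_times[hi])
  closest <- ifelse(use_lo, lo, hi)
  dist <- abs(ref_times - det_times[closest])
  matched <- dist <= tol + 1e-12
  # one-to-one credit: only in-tolerance reference beats consume a detection
  cand <- which(matched)
  matched[cand[duplicated(closest[cand])]] <- FALSE
  structure(list(n_ref = n_ref, n_det = n_det,
                 n_correct = as.integer(sum(matched)), tolerance = tol,
                 matched = matched),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d/%d reference beats matched (%d detections, tol %g s)\n",
              x$n_correct, x$n_ref, x$n_det, x$tolerance))
  invisible(x)
}

#' Sensitivity, positive predictive value and F1-score
#'
#' `Se = 100 n_correct / n_ref`, `PPV = 100 n_correct / n_det`, and the
#' F1-score is their harmonic mean `2 Se PPV / (Se + PPV)` (computed once on
#' the percentage scale -- the single x100 scaling is applied to the
#' fraction-valued counts, not compounded). Zero denominators yield 0.
#'
#' @param m A [match_beats()] result, or a list with `n_ref`, `n_det`,
#'   `n_correct`.
#' @return List with `se`, `ppv`, `f1` (all percentages in `[0, 100]`).
#' @examples
#' beat_scores(list(n_ref = 100, n_det = 90, n_correct = 81))
#' @export
beat_scores <- function(m) {
  stopifnot(m$n_correct <= m$n_ref, m$n_correct <= m$n_det)
  se <- if (m$n_ref > 0) 100 * m$n_correct / m$n_ref else 0
  ppv <- if (m$n_det > 0) 100 * m$n_correct / m$n_det else 0
  f1 <- if (se + ppv > 0) 2 * se * ppv / (se + ppv) else 0
  list(se = se, ppv = ppv, f1 = f1)
}

#' Heart-rate mean absolute percentage error
#'
#' Heart rates are computed per non-overlapping window (default 10 s) from
#' the mean interbeat interval of beats falling inside the window
#' (`HR = 60 / mean(IBI)`); windows with fewer than two beats in either
#' stream are unusable. The MAPE is the mean over usable windows of
#' `100 |HR_det - HR_ref| / HR_ref`.
#'
#' @param det_times,ref_times Ascending beat times (s).
#' @param window_s Heart-rate window duration (s); default 10.
#' @param duration_s Record duration (s); defaults to the last reference
#'   beat time.
#' @return MAPE in percent, or `NA_real_` when no window is usable.
#' @export
hr_mape <- function(det_times, ref_times, window_s = 10,
                    duration_s = NULL) {
  det_times <- as.numeric(det_times)
  ref_times <- as.numeric(ref_times)
  if (is.null(duration_s)) {
    duration_s <- if (length(ref_times)) max(ref_times) else 0
  }
  starts <- seq(0, duration_s, by = window_s)
  starts <- starts[starts + window_s <= duration_s + 1e-9]
  if (!length(starts)) return(NA_real_)
  errs <- numeric(0)
  for (ws in starts) {
    we <- ws + window_s
    hd <- window_hr(det_times, ws, we)
    hr <- window_hr(ref_times, ws, we)
    if (is.na(hd) || is.na(hr)) next
    errs <- c(errs, 100 * abs(hd - hr) / hr)
  }
  if (!length(errs)) return(NA_real_)
  mean(errs)
}

# HR (bpm) from beats inside [ws, we); NA when < 2 beats
window_hr <- function(times, ws, we) {
  tt <- times[times >= ws & times < we]
  if (length(tt) < 2L) return(NA_real_)
  60 / mean(diff(tt))
}

#' Signal-to-noise ratio per 10 s window
#'
#' Each non-overlapping window (default 10 s) is band-pass filtered between
#' 0.5 and 12 Hz with a zero-phase order-4 Chebyshev II filter, and a
#' Hann-windowed periodogram is computed. The cardiac fundamental is the
#' largest spectral peak between 0.5 and 3.0 Hz; signal power is the power
#' at the fundamental and its harmonics 2f..5f (each integrated over the
#' windowed main lobe, +/- 3 bins about the local spectral peak),
#' and noise power is the remaining spectrum excluding DC. The SNR is
#' `10 log10(Ps / Pn)`.
#'
#' @param sig A [ppg_signal()] with `fs > 24` Hz for the nominal 12 Hz band
#'   edge (the edge is capped below Nyquist otherwise).
#' @param window_s Window duration (s); default 10; shorter trailing windows
#'   are dropped.
#' @param band Nominal band edges (Hz) for the pre-filter.
#' @return Data frame with `start_s`, `snr_db`, `f0_hz` per window.
#' @export
snr_windows <- function(sig, window_s = 10, band = c(0.5, 12)) {
  stopifnot(inherits(sig, "ppg_signal"))
  fs <- sig$fs
  high <- min(band[2], 0.45 * fs)
  cf <- signal::cheby2(4, 20, c(band[1], high) / (fs / 2), type = "pass")
  n <- length(sig$samples)
  wlen <- as.integer(round(window_s * fs))
  starts <- seq.int(1L, n - wlen + 1L, by = wlen)
  out <- data.frame(start_s = numeric(), snr_db = numeric(),
                    f0_hz = numeric())
  for (s0 in starts) {
    x <- sig$samples[s0:(s0 + wlen - 1L)]
    if (any(!is.finite(x))) {
      ok <- is.finite(x)
      if (sum(ok) < 2L) next
      x[!ok] <- stats::approx(which(ok), x[ok], xout = which(!ok), rule = 2)$y
    }
    xf <- signal::filtfilt(cf, x)
    sn <- harmonic_snr(xf, fs)
    out <- rbind(out, data.frame(start_s = sig$t0 + (s0 - 1L) / fs,
                                 snr_db = sn$snr_db, f0_hz = sn$f0))
  }
  out
}

# harmonic SNR of one windowed segment via Hann periodogram
harmonic_snr <- function(x, fs, f_lo = 0.5, f_hi = 3.0, n_harm = 5L) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))  # Hann
  xw <- (x - mean(x)) * w
  nf <- floor(n / 2) + 1L
  p <- Mod(stats::fft(xw))[1:nf]^2
  freqs <- (seq_len(nf) - 1L) * fs / n
  in_fund <- freqs >= f_lo & freqs <= f_hi
  if (!any(in_fund)) return(list(snr_db = NA_real_, f0 = NA_real_))
  k0 <- which(in_fund)[which.max(p[in_fund])]
  f0 <- freqs[k0]
  lobes <- list()
  for (h in seq_len(n_harm)) {
    kh <- which.min(abs(freqs - h * f0))
    if (freqs[kh] > fs / 2) break
    # the bin-quantised f0 estimate drifts off the true harmonic by up to
    # h/2 bins; re-centre on the local spectral peak near h * f0
    search <- max(2L, kh - 3L):min(nf, kh + 3L)
    kh <- search[which.max(p[search])]
    # +/- 3 bins covers the Hann main lobe at worst-case (half-bin) offset;
    # narrower capture misclassifies harmonic leakage as noise and caps the
    # measurable SNR well below clean-signal levels
    lobes[[h]] <- max(2L, kh - 3L):min(nf, kh + 3L)
  }
  sig_bins <- unique(unlist(lobes))
  noise_bins <- setdiff(2:nf, sig_bins)
  # each captured lobe also sits on the local noise floor: estimate that
  # floor from the nearest flanking noise bins and reassign it from signal
  # to noise power, so lobes over pure noise contribute nothing
  ps <- 0
  reassigned <- 0
  for (lb in lobes) {
    lb <- setdiff(lb, setdiff(sig_bins, lb))
    if (!length(lb)) next
    below <- rev(noise_bins[noise_bins < min(lb)])
    above <- noise_bins[noise_bins > max(lb)]
    flank <- c(utils::head(below, 2L), utils::head(above, 2L))
    local_floor <- if (length(flank)) mean(p[flank]) else 0
    ps <- ps + max(sum(p[lb]) - length(lb) * local_floor, 0)
    reassigned <- reassigned + length(lb) * local_floor
  }
  pn <- sum(p[noise_bins]) + reassigned
  list(snr_db = 10 * log10(max(ps, .Machine$double.xmin) /
                             max(pn, .Machine$double.xmin)),
       f0 = f0)
}

#' Execution time as a percentage of signal duration
#'
#' @param elapsed_s Algorithm run time (s).
#' @param signal_duration_s Signal duration (s, > 0).
#' @return `100 * elapsed_s / signal_duration_s`.
#' @export
execution_time_pct <- function(elapsed_s, signal_duration_s) {
  stopifnot(signal_duration_s > 0, elapsed_s >= 0)
  100 * elapsed_s / signal_duration_s
}

#' Compare a metric between two groups of records
#'
#' Two-sided Wilcoxon rank sum test (normal approximation when ties are
#' present). Degenerate identical groups return p = 1.
#'
#' @param metric_a,metric_b Numeric per-record metric values (each >= 2
#'   values).
#' @param alpha Significance level; default 0.05.
#' @return List with `p`, `significant`.
#' @export
group_compare <- function(metric_a, metric_b, alpha = 0.05) {
  stopifnot(length(metric_a) >= 2L, length(metric_b) >= 2L)
  if (length(unique(c(metric_a, metric_b))) == 1L) {
    return(list(p = 1, significant = FALSE))
  }
  p <- suppressWarnings(
    stats::wilcox.test(metric_a, metric_b, alternative = "two.sided")$p.value
  )
  list(p = p, significant = p < alpha)
}

#' Holm-Sidak step-down correction for multiple comparisons
#'
#' With the raw p-values sorted ascending, the i-th adjusted value is
#' `1 - (1 - p_(i))^(m - i + 1)`, enforced monotone non-decreasing down the
#' list (step-down), and reported in the original order.
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values in the input order.
#' @examples
#' holm_sidak(c(0.01, 0.03, 0.04))  # 0.0297, 0.0591, 0.0591
#' @export
holm_sidak <- function(p) {
  m <- length(p)
  if (!m) return(numeric(0))
  o <- order(p)
  ps <- p[o]
  adj <- 1 - (1 - ps)^(m - seq_len(m) + 1)
  adj <- cummax(pmin(adj, 1))
  out <- numeric(m)
  out[o] <- adj
  out
}
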