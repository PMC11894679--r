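test_that("a constant clock offset is recovered on the lag grid", {
  ref <- beat_times(400, 75, hr_mod_af(0.1), seed = 21)
  det <- ref + 1.34
  al <- align_beats(det, ref)
  expect_equal(al$trace$lag_s, rep(-1.34, nrow(al$trace)), tolerance = 1e-9)
  m <- match_beats(al$det_aligned, ref)
  expect_equal(m$n_correct, length(ref))
})

test_that("identical streams align at zero lag", {
  ref <- beat_times(100, 60, seed = 3)
  al <- align_beats(ref, ref)
  expect_equal(al$trace$lag_s, 0)
  expect_equal(al$det_aligned, as.numeric(ref))
})

test_that("per-chunk lags track a drifting clock", {
  ref <- beat_times(600, 75, hr_mod_af(0.1), seed = 22)
  det <- ifelse(ref < 300, ref + 0.50, ref + 0.64)
  al <- align_beats(sort(det), ref)
  expect_equal(al$trace$lag_s[1:2], c(-0.50, -0.64), tolerance = 1e-9)
  m <- match_beats(al$det_aligned, ref)
  expect_gte(m$n_correct, length(ref) - 2L)  # chunk-boundary beats excepted
})

test_that("alignment never reduces the matched count", {
  withr::local_seed(31)
  for (rep in 1:5) {
    ref <- beat_times(200, 80, hr_mod_af(0.15), seed = 30 + rep)
    det <- ref + runif(1, -2, 2) + rnorm(length(ref), sd = 0.02)
    det <- sort(det)
    plain <- match_beats(det, ref)$n_correct
    aligned <- match_beats(align_beats(det, ref)$det_aligned, ref)$n_correct
    expect_gte(aligned, plain)
  }
})

test_that("empty streams yield zero-lag identity alignment", {
  al <- align_beats(numeric(0), c(1, 2))
  expect_length(al$det_aligned, 0L)
  expect_equal(nrow(al$trace), 0L)
})

test_that("matching is within-tolerance, one-to-one, greedy by time", {
  m <- match_beats(c(1.0, 2.0, 3.1), c(1.0, 2.1, 3.0))
  expect_equal(m$n_correct, 3L)

  expect_equal(match_beats(numeric(0), c(1, 2))$n_correct, 0L)

  # one detection cannot satisfy two reference beats
  m2 <- match_beats(1.0, c(1.0, 1.1))
  expect_equal(m2$n_correct, 1L)
  expect_equal(m2$matched, c(TRUE, FALSE))

  # an out-of-tolerance reference beat does not consume a detection
  m3 <- match_beats(c(1.0), c(0.2, 1.05))
  expect_equal(m3$matched, c(FALSE, TRUE))
})

test_that("matching is invariant under time translation", {
  withr::local_seed(17)
  ref <- cumsum(runif(50, 0.5, 1.5))
  det <- ref + rnorm(50, sd = 0.1)
  det <- sort(det)
  base <- match_beats(det, ref)$n_correct
  for (c0 in c(-100, 3.7, 2000)) {
    expect_equal(match_beats(det + c0, ref + c0)$n_correct, base)
  }
})

test_that("Se, PPV and F1 follow the published formulas", {
  sc <- beat_scores(list(n_ref = 100, n_det = 90, n_correct = 81))
  expect_equal(sc$se, 81)
  expect_equal(sc$ppv, 90)
  expect_equal(sc$f1, 14580 / 171)  # 85.263...

  perfect <- beat_scores(list(n_ref = 10, n_det = 10, n_correct = 10))
  expect_equal(unlist(perfect), c(se = 100, ppv = 100, f1 = 100))

  none <- beat_scores(list(n_ref = 10, n_det = 10, n_correct = 0))
  expect_equal(unlist(none), c(se = 0, ppv = 0, f1 = 0))
})

test_that("F1 lies between Se and PPV (harmonic mean)", {
  withr::local_seed(5)
  for (rep in 1:50) {
    n_ref <- sample(1:200, 1)
    n_det <- sample(1:200, 1)
    n_cor <- sample(0:min(n_ref, n_det), 1)
    sc <- beat_scores(list(n_ref = n_ref, n_det = n_det, n_correct = n_cor))
    expect_gte(sc$f1, min(sc$se, sc$ppv) - 1e-12)
    expect_lte(sc$f1, max(sc$se, sc$ppv) + 1e-12)
  }
})

test_that("heart-rate MAPE matches hand-computed cases", {
  ref <- seq(0, 100, by = 1)            # 60 bpm
  expect_equal(hr_mape(ref, ref), 0)

  det <- seq(0, 100, by = 60 / 66)      # 66 bpm everywhere
  expect_equal(hr_mape(det, ref, duration_s = 100), 10, tolerance = 0.2)

  # losing every other beat halves the apparent rate
  det2 <- ref[seq(1, length(ref), by = 2)]
  expect_equal(hr_mape(det2, ref, duration_s = 100), 50, tolerance = 0.5)

  # no usable windows is reported as missing, not zero
  expect_true(is.na(hr_mape(c(1, 2), c(1, 2), duration_s = 5)))
})

test_that("SNR is high for pure tones and tracks added noise", {
  fs <- 125
  t <- (0:(fs * 30 - 1)) / fs
  pure <- ppg_signal(sin(2 * pi * 1.5 * t), fs)
  sw <- snr_windows(pure)
  expect_equal(nrow(sw), 3L)
  expect_equal(sw$f0_hz, rep(1.5, 3))
  expect_gte(min(sw$snr_db), 40)

  # noise scaled so that, through the measurement band-pass, its power
  # equals the tone's: the power-ratio SNR must then sit near 0 dB
  withr::local_seed(12)
  cf <- signal::cheby2(4, 20, c(0.5, 12) / (fs / 2), type = "pass")
  tone <- sin(2 * pi * 1.5 * t)
  noise <- rnorm(length(t))
  scale <- sqrt(mean(signal::filtfilt(cf, tone)^2) /
                  mean(signal::filtfilt(cf, noise)^2))
  noisy <- ppg_signal(tone + scale * noise, fs)
  mid <- median(snr_windows(noisy)$snr_db)
  expect_lt(abs(mid), 3)

  # SNR decreases as white-noise variance grows
  snrs <- vapply(c(0.05, 0.2, 0.8), function(sd) {
    withr::with_seed(13, {
      sig <- ppg_signal(sin(2 * pi * 1.5 * t) + rnorm(length(t), sd = sd), fs)
      median(snr_windows(sig)$snr_db)
    })
  }, numeric(1))
  expect_true(all(diff(snrs) < 0))
})

test_that("windows shorter than 10 s are dropped from the SNR table", {
  fs <- 64
  sig <- ppg_signal(sin(2 * pi * (0:(fs * 25 - 1)) / fs), fs)
  expect_equal(nrow(snr_windows(sig)), 2L)
})

test_that("execution time percentage is elapsed over duration", {
  expect_equal(execution_time_pct(0.3, 600), 0.05)
  expect_equal(execution_time_pct(0, 600), 0)
  expect_error(execution_time_pct(1, 0), "duration")
})

test_that("rank-sum comparison flags shifted groups and not identical ones", {
  withr::local_seed(8)
  a <- rnorm(20)
  gc <- group_compare(a, a + 3)
  expect_lt(gc$p, 0.01)
  expect_true(gc$significant)

  same <- group_compare(rep(1, 5), rep(1, 6))
  expect_equal(same$p, 1)
  expect_false(same$significant)
})

test_that("Holm-Sidak adjustment reproduces the worked example", {
  adj <- holm_sidak(c(0.01, 0.03, 0.04))
  expect_equal(adj, c(0.029701, 0.0591, 0.0591), tolerance = 1e-6)

  # a single comparison is unchanged
  expect_equal(holm_sidak(0.2), 0.2)
  # order of input is preserved
  adj2 <- holm_sidak(c(0.04, 0.01, 0.03))
  expect_equal(adj2, c(0.0591, 0.029701, 0.0591), tolerance = 1e-6)
  # monotone in the sorted order and never above 1
  withr::local_seed(2)
  p <- runif(10)
  a <- holm_sidak(p)
  expect_true(all(diff(a[order(p)]) >= -1e-12))
  expect_true(all(a <= 1))
})
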