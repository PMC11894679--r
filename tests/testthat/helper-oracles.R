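# Independent brute-force oracle for multiscale extremum detection: tests the
# definition directly for every sample and scale, with no shared code with
# compute_lms()/extract_extrema().
bf_flag <- function(y, i, k) {
  n <- length(y)
  (i - k) >= 1 && (i + k) <= n && y[i] > y[i - k] && y[i] > y[i + k]
}

bf_extrema <- function(x, L, polarity = "maxima") {
  y <- if (polarity == "minima") -x else x
  n <- length(y)
  gamma <- vapply(seq_len(L), function(k) {
    sum(vapply(seq_len(n), function(i) bf_flag(y, i, k), logical(1)))
  }, numeric(1))
  lambda <- which.max(gamma)
  keep <- vapply(seq_len(n), function(i) {
    all(vapply(seq_len(lambda), function(k) bf_flag(y, i, k), logical(1)))
  }, logical(1))
  which(keep)
}

# random ragged index lists for tidy property tests
random_ragged <- function(n_max, x_len) {
  list(
    peaks = sample.int(x_len, sample.int(n_max, 1), replace = TRUE),
    onsets = sample.int(x_len, sample.int(n_max, 1), replace = TRUE)
  )
}

clean_record <- function(duration_s = 60, fs = 125, hr = 60, seed = 1) {
  synth_ppg(duration_s, fs = fs, hr_mean = hr, noise = noise_none(),
            seed = seed)
}

pipeline_f1 <- function(rec, variant = "msptdfastv2") {
  bs <- run_pipeline(rec$signal, preset_config(variant))
  beat_scores(match_beats(beat_times_s(bs, "peaks"), rec$peaks_s))$f1
}
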