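test_that("ppg_signal validates inputs and computes times", {
  sig <- ppg_signal(c(1, 2, 3), fs = 100)
  expect_equal(length(sig), 3L)
  expect_equal(signal_times(sig), c(0, 0.01, 0.02))
  expect_equal(signal_duration(sig), 0.03)
  expect_error(ppg_signal(1:3, fs = 0), "positive")
  sig2 <- ppg_signal(c(1, NaN, 3), fs = 10)
  expect_equal(sig2$valid_mask, c(TRUE, FALSE, TRUE))
})

test_that("signal CSV reader infers fs from a time column", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0.0,1.0", "0.008,1.1", "0.016,1.2"), f)
  sig <- read_signal_csv(f)
  expect_equal(sig$fs, 125)
  expect_equal(sig$samples, c(1.0, 1.1, 1.2))
})

test_that("single-column reader requires fs and flags NaN rows invalid", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1", "2", "3"), f)
  expect_error(read_signal_csv(f), "fs")
  sig <- read_signal_csv(f, fs = 100)
  expect_equal(sig$fs, 100)
  expect_equal(length(sig), 3L)

  writeLines(c("1", "NaN", "3"), f)
  sig <- read_signal_csv(f, fs = 100)
  expect_equal(sig$valid_mask, c(TRUE, FALSE, TRUE))
})

test_that("non-monotonic time column is rejected", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0.0,1.0", "0.3,1.1", "0.2,1.2"), f)
  expect_error(read_signal_csv(f), "increasing")
})

test_that("signal CSV round-trips", {
  sig <- clean_record(10, fs = 50, seed = 3)$signal
  f <- withr::local_tempfile(fileext = ".csv")
  write_signal_csv(sig, f)
  back <- read_signal_csv(f)
  expect_equal(back$fs, sig$fs, tolerance = 1e-9)
  expect_equal(back$samples, sig$samples, tolerance = 1e-6)
})

test_that("beats CSV writes typed rows sorted by time and round-trips", {
  bs <- beat_set(onsets = 3, mids = 5, peaks = 7, fs = 10, tidied = TRUE)
  f <- withr::local_tempfile(fileext = ".csv")
  write_beats_csv(bs, f)
  df <- read.csv(f)
  expect_equal(df$index, c(3, 5, 7))
  expect_equal(df$time_s, c(0.2, 0.4, 0.6))
  expect_equal(df$type, c("onset", "mid", "peak"))
  back <- read_beats_csv(f, fs = 10)
  expect_equal(back$onsets, bs$onsets)
  expect_equal(back$mids, bs$mids)
  expect_equal(back$peaks, bs$peaks)
})

test_that("empty beat set writes a header-only file", {
  bs <- beat_set(fs = 10, tidied = TRUE)
  f <- withr::local_tempfile(fileext = ".csv")
  write_beats_csv(bs, f)
  expect_length(readLines(f), 1L)
  back <- read_beats_csv(f, fs = 10)
  expect_length(back$peaks, 0L)
})

test_that("untidied beats are refused by the writer", {
  bs <- beat_set(onsets = c(1, 5), peaks = 3, fs = 10, tidied = FALSE)
  f <- withr::local_tempfile(fileext = ".csv")
  expect_error(write_beats_csv(bs, f), "tidied")
})

test_that("beat_set invariants are enforced when tidied", {
  expect_error(beat_set(onsets = c(2, 1), peaks = c(3, 4), fs = 1),
               "ascending")
  expect_error(beat_set(onsets = c(1, 3), peaks = c(2, 2), fs = 1,
                        tidied = TRUE), "ascending")
  expect_error(beat_set(onsets = 1, peaks = c(2, 4), fs = 1, tidied = TRUE),
               "equal")
  expect_error(beat_set(onsets = 3, peaks = 2, fs = 1, tidied = TRUE),
               "alternate")
  expect_silent(beat_set(onsets = c(1, 4), mids = c(2, 5),
                         peaks = c(3, 6), fs = 1, tidied = TRUE))
})

test_that("reference beat times must be increasing and non-negative", {
  expect_silent(reference_beats(c(0.5, 1.2, 2)))
  expect_error(reference_beats(c(1, 1)), "increasing")
  expect_error(reference_beats(-1), "non-negative")
})

test_that("flat runs of at least the threshold duration are invalidated", {
  # 1.5 s of identical samples at fs 10 with a 1 s threshold
  x <- c(sin(1:20), rep(0.7, 15), sin(1:20))
  sig <- mark_invalid_regions(ppg_signal(x, fs = 10), flat_min_s = 1)
  expect_false(any(sig$valid_mask[21:35]))
  expect_true(all(sig$valid_mask[c(1:20, 36:55)]))

  # 0.5 s flat run is below threshold: mask unchanged
  x2 <- c(sin(1:20), rep(0.7, 5), sin(1:20))
  sig2 <- mark_invalid_regions(ppg_signal(x2, fs = 10), flat_min_s = 1)
  expect_true(all(sig2$valid_mask))

  # strictly increasing ramp untouched
  sig3 <- mark_invalid_regions(ppg_signal(seq(0, 5, by = 0.1), fs = 10))
  expect_true(all(sig3$valid_mask))
})

test_that("mark_invalid_regions flags non-finite samples and is idempotent", {
  x <- c(1, 2, NA, 4, rep(9, 25), 5)
  sig <- mark_invalid_regions(ppg_signal(x, fs = 10), flat_min_s = 2)
  expect_false(sig$valid_mask[3])
  expect_false(any(sig$valid_mask[5:29]))
  twice <- mark_invalid_regions(sig, flat_min_s = 2)
  expect_identical(twice$valid_mask, sig$valid_mask)
  iv <- invalid_intervals(sig)
  expect_equal(nrow(iv), 2L)
})
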