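# msptdfast

Beat detection in photoplethysmogram (PPG) signals with the multiscale
peak-and-trough detector family — AMPD, MSPTD, and the efficient
MSPTDfast (v.1/v.2) configurations — plus the evaluation framework used to
benchmark PPG beat detectors and a seeded synthetic-PPG generator with
analytic ground truth.

It is aimed at physiological-signal researchers who need (i) a fast,
well-tested beat detector for PPG time series, (ii) the standard metrics
for comparing detectors against ECG-derived reference beats, or (iii) a
reproducible synthetic test bench for either.

## The algorithm

All detectors in the family locate pulse peaks (and troughs, on the
negated signal) with a *local maxima scalogram* (LMS): for scales
`k = 1..L`, sample `i` of a detrended window is flagged when
`x[i] > x[i-k]` and `x[i] > x[i+k]`. With `gamma[k]` the number of flags
in row `k`, the selected scale `lambda = argmax gamma` adapts to the beat
period, and the detected extrema are the samples flagged at **every**
scale `k <= lambda`. MSPTD applies this to both polarities to get peaks
and onsets; MSPTDfast v.2 additionally

* downsamples to ≥ 20 Hz by the greatest integer factor
  (`m = floor(fs / 20)`), and
* truncates the scalogram to scales corresponding to heart rates above
  30 bpm (`L <= ceiling(fs * 60 / (2 * 30))`, i.e. at most 21 rows at
  20 Hz),

shrinking the scalogram — the dominant cost — by roughly two orders of
magnitude at 125 Hz while leaving detections on clean signals unchanged.

Around any detector, `run_pipeline()` applies the standard assessment
framework: 20 s windows with 5 s overlap, a zero-phase 0.67–8 Hz
band-pass, de-duplication and tidying of the fiducial sequence
(alternating onset/peak, equal counts), half-amplitude systolic
mid-points, and exclusion of flat or missing-signal periods. The
evaluation module adds drifting-clock alignment (±10 s lag grid, 0.02 s
step, re-estimated every 300 s), ±150 ms one-to-one beat matching,
sensitivity / positive predictive value / F1, windowed heart-rate MAPE,
harmonic signal-to-noise stratification, and rank-sum group comparison
with Holm–Sidak correction.

## Worked example

```r
library(msptdfast)

# a two-minute synthetic record: 75 bpm, hospital-grade noise
rec <- synth_ppg(duration_s = 120, fs = 125, hr_mean = 75, seed = 42)
rec
#> <synthetic_record> 120 s @ 125 Hz, 150 beats (mean HR 75.0 bpm), white sd 0.05

beats <- run_pipeline(rec$signal, preset_config("msptdfastv2"))
beats
#> <beat_set> 149 onsets, 149 mids, 149 peaks @ 125 Hz (tidied)

m <- match_beats(beat_times_s(beats, "peaks"), rec$peaks_s)
m
#> <match_result> 149/150 reference beats matched (149 detections, tol 0.15 s)
round(unlist(beat_scores(m)), 2)
#>     se    ppv     f1
#>  99.33 100.00  99.67

round(hr_mape(beat_times_s(beats, "peaks"), rec$peaks_s, duration_s = 120), 3)
#> [1] 0.146
round(median(snr_windows(rec$signal)$snr_db), 1)
#> [1] 24.2
```

The detector recovers 149 of 150 beats (the record's very first beat sits
closer to the edge than the selected scale and cannot be flagged at all
scales — see the methods vignette) with no false positives: sensitivity
99.33%, PPV 100%, F1 99.67%. Heart rates computed from the detected
beats differ from ground truth by 0.146% on average, and the record's
median windowed SNR is 24.2 dB.

A shell entry point wrapping the same functions is installed with the
package (`exec/ppgbeats`), with sub-commands `detect`, `evaluate`,
`simulate` and `bench`:

```sh
Rscript "$(Rscript -e 'cat(system.file("exec/ppgbeats", package="msptdfast"))' )" \
    detect --input rec_signal.csv --out beats.csv --variant msptdfastv2
```

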