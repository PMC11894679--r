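---
title: "Multiscale PPG beat detection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale PPG beat detection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msptdfast)
```

## The detection problem

A photoplethysmogram (PPG) records blood-volume changes optically; each
heartbeat produces one pulse wave with a steep systolic upslope, a systolic
peak, and usually a smaller diastolic (dicrotic) wave. Heart-rate and
rhythm analyses need the individual beats, so the first processing step is
a beat detector that returns, for every pulse, its onset (the pre-systolic
minimum), its systolic peak, and a mid-point on the systolic upslope used
as the timing fiducial for pulse-rate-variability work.

This package implements the multiscale peak-and-trough family of
detectors -- AMPD, MSPTD, and the faster MSPTDfast v.1 and v.2
configurations -- together with the evaluation framework used to benchmark
such detectors and a seeded synthetic-PPG generator, so the entire stack
can be exercised and tested without clinical recordings.

## The local maxima scalogram

All four detectors share one primitive. For a window $x_1,\dots,x_N$ and a
*scale* $k$ (a neighbour separation in samples), sample $i$ is flagged when

$$x_i > x_{i-k} \quad\text{and}\quad x_i > x_{i+k},$$

with strict inequalities, so plateaus and flat segments never flag. The
local maxima scalogram (LMS) is the boolean matrix of these flags over
scales $k = 1..L$ and samples $i = 1..N$; troughs (pulse onsets) use the
same test on the negated signal. With $\gamma_k$ the number of flagged
samples in row $k$, the selected scale $\lambda$ is the row with maximal
$\gamma_k$, and the detected extrema are the samples flagged on *every*
row $k \le \lambda$. For a quasi-periodic pulse train of period $T$
samples, $\gamma_k$ peaks near $T/2$, so $\lambda$ adapts to the beat
period and sub-beat wiggles are rejected by the AND over rows.

Design notes:

* **Tie-break for $\lambda$**: the smallest scale with maximal count.
  This matches the argmax-first behaviour of the reference
  implementations and is deterministic. On perfectly clean synthetic
  signals, exact ties between a sub-beat scale and the beat scale can
  occur; we evaluated breaking ties toward the largest tied scale and
  found it changed almost nothing in practice, so the conventional choice
  is kept.
* **Default scale count**: $L = \lceil N/2 \rceil - 1$, i.e. separations
  up to half the window.
* **Loops vs vectorised construction**: both are provided and produce
  bit-identical matrices (this is property-tested). In R the vectorised
  formulation is much faster, so the presets use it; the nested-loop
  variant mirrors the construction found in scalar-language
  implementations and serves as a cross-check.
* AMPD's original random-valued scalogram is represented with the boolean
  matrix: the random entries never change which samples survive the
  row-wise AND, so outputs are identical and deterministic.

## The detector presets

| preset | window | downsample floor | HR$_\min$ truncation | extrema |
|---|---|---|---|---|
| `ampd` | 6 s | none | none | peaks only |
| `msptd` | 6 s | none | none | peaks + onsets |
| `msptdfastv1` | 8 s | 20 Hz | 30 bpm | peaks + onsets |
| `msptdfastv2` | 6 s | 20 Hz | 30 bpm | peaks + onsets |

The two "fast" ingredients both shrink the scalogram. Downsampling by the
greatest integer factor that keeps at least 20 Hz (`downsample_factor`)
shortens the columns; truncating scales to
$L = \min(\lceil N/2\rceil - 1,\ \lceil f_s \cdot 60 / (2\,\mathrm{HR}_\min)\rceil)$
removes rows that only matter for rhythms slower than HR$_\min$ = 30 bpm
(a period of $T$ samples needs scales up to $T/2$, and
$T \le f_s \cdot 60/\mathrm{HR}$). At 20 Hz and 30 bpm this caps the LMS at
21 rows regardless of window length. Decimation is plain subsampling --
the framework band-pass (0.67-8 Hz) runs first, and 8 Hz is below the
Nyquist frequency of every decimated rate at or above 20 Hz, so no extra
anti-alias filter is needed.

Detector-internal windows overlap by 20% of the window duration so beats
near a window edge (which the scalogram cannot flag within $\lambda$
samples of a boundary) are recovered by the neighbouring window; trailing
partial windows of at least 2 s (one beat at 30 bpm) are processed.
Detected indices are mapped back to original-rate coordinates
(`(i - 1) m + 1`) and exact duplicates are removed at the merge.

## The framework around a detector

`run_pipeline()` reproduces the standard assessment chain: flag unusable
periods (runs of at least 1 s of bitwise-identical samples -- longer than
any physiological plateau at plausible heart rates -- and non-finite
samples); segment into 20 s windows with 5 s overlap; band-pass each
window; detect; merge; tidy; attach mid-points; and drop beats whose
fiducials fall in flagged regions.

* **Band-pass realisation.** The band is 0.67-8.00 Hz. We use a
  Butterworth design with four pole pairs applied forward-backward
  (`signal::filtfilt`), i.e. zero-phase, so fiducial timing is not skewed;
  the double pass gives roughly 28 dB attenuation at 12 Hz and far more at
  0.1 Hz for 125 Hz signals. Filtering is per framework window, accepting
  edge transients because windows overlap by 5 s.
* **Near-duplicate merge.** Overlapping windows can re-detect the same
  beat one sample apart; indices within one original-rate sample merge to
  the earlier one. Remaining disagreements are resolved by tidying.
* **Tidying** enforces logical consistency: duplicates removed; an index
  detected as both peak and onset keeps only the peak; runs of
  consecutive same-type fiducials collapse to one (the lowest-amplitude
  onset, the highest-amplitude peak -- the physiological extremum each
  fiducial names -- with ties to the earlier index); and the sequence is
  trimmed to start with an onset and end with a peak, which forces equal
  counts and strict alternation. The operation is idempotent and is
  property-tested on random ragged inputs. For peak-only detectors
  (AMPD), onsets are synthesised as the minimum sample between
  consecutive peaks before tidying; a lone peak therefore yields no beat.
* **Mid-points** use the half-amplitude definition: the first sample
  after the onset at which the signal reaches the mean of the onset and
  peak amplitudes. On a two-sample upslope this is the peak itself, so
  the contract is `onset < mid <= peak`.

## Evaluation

* **Clock alignment.** Reference (ECG-derived) and PPG clocks drift; per
  300 s chunk of the reference timeline, lags in $[-10, 10]$ s on a
  0.02 s grid are trialled and the lag maximising the number of reference
  beats with a detection within 0.15 s wins. On clean data whole ranges
  of lags tie at the maximal count, so ties are broken by the smallest
  mean absolute time difference of the matched pairs, then the smallest
  $|\tau|$, then the negative sign. This recovers an injected constant
  lag exactly on the grid, which a count-only rule cannot do.
* **Matching** is within +/-150 ms, one detection credited to at most one
  reference beat, greedily in ascending time.
* **Scores.** Se $= 100\,n_\mathrm{correct}/n_\mathrm{ref}$, PPV
  $= 100\,n_\mathrm{correct}/n_\mathrm{det}$, and F1 is their harmonic
  mean. The percentage scaling is applied exactly once -- composing
  published per-quantity "$\times 100$" factors literally would
  double-scale F1.
* **Heart-rate MAPE.** Heart rates are compared per non-overlapping 10 s
  window as $60/\overline{\mathrm{IBI}}$ over beats inside the window
  (at least two beats required in each stream); the MAPE is the mean of
  $100\,|HR_\mathrm{det}-HR_\mathrm{ref}|/HR_\mathrm{ref}$ over usable
  windows, reported as missing when none is usable.
* **SNR.** Per 10 s window the signal is band-pass filtered 0.5-12 Hz
  with a zero-phase order-4 Chebyshev II design (20 dB stopband ripple;
  the band edges are stopband edges, following the usual convention for
  this design), and a Hann periodogram is computed. The cardiac
  fundamental is the largest peak in 0.5-3 Hz; the power at the
  fundamental and harmonics 2-5 is integrated over each lobe (+/-3 bins
  about the locally re-centred peak, the Hann main-lobe width at
  worst-case half-bin offset), the local noise floor under each lobe
  (estimated from flanking bins) is reassigned to the noise side, and
  SNR $= 10\log_{10}(P_s/P_n)$ excluding DC. Narrower lobe capture
  misattributes window leakage to noise and caps the measurable SNR far
  below clean-signal levels; without the floor reassignment, lobes sitting
  on pure noise inflate the signal power. The measure saturates near
  $-8$ dB for noise-dominated windows (the "fundamental" is then just the
  largest noise peak) and near 34 dB for the cleanest synthetic records.
* **Group comparison.** Two-sided Wilcoxon rank sum per pair, with
  Holm-Sidak step-down adjustment
  $1 - (1 - p_{(i)})^{m-i+1}$ across a family of $m$ comparisons.

## The synthetic generator

`synth_ppg()` builds each record from first principles so every module has
analytic ground truth:

* **Beat times** start at 0 and advance by IBIs from the heart-rate
  profile: constant, sinusoidally modulated (respiratory-sinus-arrhythmia
  style), or AF-like (each IBI multiplied by an independent log-normal
  factor; the IBI coefficient of variation approximately equals the
  log-sd).
* **Pulse shape** is a two-Gaussian template on each IBI: systolic wave
  of amplitude 1.0 centred at 0.25 and width 0.09, diastolic wave of
  amplitude 0.35 centred at 0.55 and width 0.14, all as fractions of an
  *effective* interval $\min(\mathrm{IBI}, 1\ \mathrm{s})$. The cap
  matters: real systolic/dicrotic timing is set by the ejection duration
  and changes little as the heart slows, while diastole lengthens as a
  quiescent runoff. Scaling the whole geometry with the IBI would, at
  40 bpm, place a large diastolic wave half a period after systole --
  a morphology no detector in this family (nor, we expect, any other)
  should be asked to disambiguate. At IBIs of 1 s and below the template
  equals the uncapped one.
* Pulses are evaluated at **continuous time offsets** and their Gaussian
  tails are overlap-added across beat boundaries. Placing templates on
  the sample grid instead adds +/-half-sample timing jitter whose
  phase-noise sidebands cap record SNR near 30 dB, and truncating tails
  at beat boundaries adds per-beat discontinuities with a similar effect;
  both would make the cleanest SNR bins unreachable.
* **Ground truth** (onset, mid, peak times) is computed from the
  continuous template on a 1 ms grid, with the same half-amplitude
  mid-point rule as the pipeline, so clean-record F1 can approach 100%.
* **Noise** adds sinusoidal baseline wander (default amplitude 0.2,
  0.25 Hz -- a respiratory rate), white noise (default sd 0.05, a
  hospital-grade signal), and optional 1-3 s motion bursts at a Poisson
  rate. `calibrate_noise_to_snr()` rescales the white-noise sd by
  bisection (regenerating from the stored parameters, so only the noise
  scales) until the median windowed SNR is within 1 dB of a target.

What the generator does **not** emulate: beat-to-beat morphology
variability, amplitude modulation with respiration, sensor-specific
transfer functions, realistic motion artifacts (bursts are white-noise
episodes), or arrhythmias beyond IBI jitter. Passing tests on this data
therefore demonstrate algorithmic correctness and the framework's
behaviour, not clinical performance.

## Test problem sizes

The test-suite records are 120 s at 64-300 Hz across 40-180 bpm for the
clean-fidelity grid, five 120 s records per SNR bin for the robustness
curve, and one 10 min record at 125 Hz for relative timing. These sizes
keep every property measurable (about 80-360 beats per record, 11 usable
heart-rate windows) while the full suite runs in a couple of minutes.

## Known limitations

* **Very low heart rates.** Below about 40 bpm the pulse fundamental
  falls under the framework's 0.67 Hz high-pass edge. The filtered
  signal is zero-mean over each beat, so a long diastole must carry a
  compensating positive lobe, which the scalogram detectors report as an
  extra beat: at 35 bpm the pipeline's positive predictive value drops to
  about 50% for MSPTD and MSPTDfast v.2 alike (their outputs remain
  identical, i.e. the scale truncation itself is safe -- this equality is
  what the test suite asserts at 35 bpm). This is a property of the
  framework's filter, not of the fast configuration.
* **Record-edge beats.** A beat within $\lambda$ samples of the start or
  end of the record cannot be flagged at all scales and is usually lost;
  on a 120 s record this costs at most one beat.
* **Beat-time resolution.** v.2 reports beats on the decimated (about
  20 Hz) grid. The resulting heart-rate quantisation floor is about
  0.15-0.2% MAPE, which is why the noise-robustness curve in the
  acceptance checks uses MSPTD at the native rate: near the floor,
  sub-resolution dithering effects of order 0.01 percentage points would
  otherwise dominate the comparison between the two cleanest SNR bins.
* **Execution-time ratios** are measured on whatever machine runs the
  suite and reflect this R implementation, not intrinsic complexity; the
  v.2-to-MSPTD ratio at 125 Hz is nevertheless robustly far below one
  half, since v.2 computes roughly 1-2% of the scalogram entries.
* Sample indices are 1-based throughout the R API (times in seconds at
  the I/O edges); CSV beat files store the 1-based index alongside the
  time.
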