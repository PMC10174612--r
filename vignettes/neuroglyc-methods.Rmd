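---
title: "Methods: linking intracranial powerband activity to interstitial glucose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking intracranial powerband activity to interstitial glucose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroglyc)
```

## The problem

Glucose-responsive neuronal populations exist in the hypothalamus and
several corticolimbic regions, and population-level intracranial activity
may therefore carry information about ongoing — and upcoming — peripheral
glucose dynamics.  `neuroglyc` implements a complete analysis chain for
multi-day recordings in which stereo-EEG depth electrodes and a continuous
glucose monitor (CGM, 5-minute interstitial sampling) run simultaneously:

1.  raw voltage → smoothed powerband amplitude envelopes,
2.  alignment of envelopes and glucose on a shared 5-minute grid,
3.  lag-resolved correlation with a block-permutation null,
4.  wavelet coherence, circadian phase lags and circadian/ultradian
    decomposition,
5.  stimulation-evoked potential (CCEP) summaries as an effective
    connectivity covariate,
6.  a sparse linear (LASSO) decoder of glucose from the full
    spectro-spatial feature set, with circadian controls and bootstrap
    channel importance.

Because the recordings this kind of study uses cannot be redistributed, the
package ships a synthetic generator (`simulate_study()`) that emits the
same data products with fully known circadian/ultradian structure, coupling
lags and noise.  Every analysis stage has a parameter-recovery test against
that ground truth; the test suite and `scripts/acceptance.R` are built
entirely on it.

## Preprocessing model

Voltages are notch-filtered (60/120/180 Hz, 2nd-order Butterworth
band-stop, 4 Hz wide), re-referenced with a Laplacian scheme (each contact
minus the mean of its shaft neighbours; shaft ends fall back to bipolar),
restricted to gray-matter contacts, band-passed per powerband (delta 1–4,
theta 4–8, alpha 8–12, beta 15–25, gamma 25–70 Hz at order 4; HFA 70–170 Hz
at order 8), converted to amplitude by the magnitude of the analytic
(Hilbert) signal, and averaged over non-overlapping 60-s windows, so each
envelope sample is a one-minute mean.

Numerical choices:

* **Zero-phase filtering.**  All filters run forward–backward
  (`signal::filtfilt`).  The analyses concern lags of hours; group delay of
  a causal filter would inject a systematic (if tiny) lag, and zero-phase
  filtering removes the concern entirely.  The stated band order is the
  order of the designed filter; the forward–backward pass doubles the
  effective order.
* **Tiled, not sliding, smoothing windows.**  The 60-s boxcar averages
  non-overlapping windows centred on multiples of 60 s from the recording
  start, so envelope timestamps land exactly on the CGM grid and each
  output sample is an average of one minute of recording.
* **Edge masking.**  The first and last smoothing window contain the filter
  edge transients and are masked `NA`.

## Timebase and alignment

Glucose series live on a nominal 5-minute grid; gaps of at most three
consecutive points are filled linearly between flanking measurements and
flagged `interpolated`; longer gaps stay missing and are excluded pairwise
downstream.  The glucose derivative is the backward difference in
mg/dL/min, assigned to the later timestamp (a causal convention; the
choice is documented because either convention is defensible).  For every
glucose timestamp, `align_series()` takes the envelope sample whose window
centre is nearest within ±1 s; unmatched points are dropped from both
sides symmetrically, and an error is raised if fewer than half the points
match (a clock-misalignment guard).

## Lag-resolved coupling

`cross_correlogram()` computes the Pearson correlation of `x(t + l)` with
`y(t)` on every 5-minute lag step within ±12 h, excluding masked samples
pairwise; lags with fewer than 100 overlapping samples are undefined.
**Negative lag means the neural series leads.**  The best lag maximises
|r| (the rectified criterion) while the signed r is reported; exact ties
break toward the smaller |lag|, so a flat correlogram yields lag 0.

Significance uses a block-permutation null: the glucose series is cut into
contiguous 30-minute blocks, the block order is permuted (identity
excluded), and the correlogram is recomputed per iteration (1000 by
default).  The p-value compares the observed max-|r| across lags against
the permutation distribution of the same max statistic — a max-statistic
correction for the lag search, which is stricter than testing the best lag
against a per-lag null (an anti-conservative shortcut we deliberately
avoid; a per-lag band is still reported for plotting).

Two properties of this null deserve emphasis:

* Under exchangeability at the block scale the test is calibrated; the
  acceptance suite verifies the empirical type-I rate on uncoupled AR(1)
  pairs whose dependence horizon (~15 min; an AR coefficient of 0.44 at
  the 5-min grid, the compounding of a published ~0.85-per-minute CGM
  sensor-error autocorrelation) sits inside one block.
* When the noise correlation time approaches the 30-minute block length,
  block shuffling destroys cross-block autocorrelation that the observed
  series retains, and the test becomes anti-conservative.  This is a known
  limitation of block permutation, not of this implementation; with
  strongly autocorrelated noise, longer blocks should be configured
  (`coupling_config(shuffle_segment_min = ...)`).

State-stratified correlations shift the neural series by the chosen lag
first and then restrict to samples whose state mask (evaluated at the
glucose timestamp) is true; states with fewer than 50 samples are
undefined.  Region-level summaries report mean ± SEM per region and state,
a paired sleep-vs-wake t-test per region, and a one-way ANOVA across
regions (skipped with a note for a single region; defined as F = 0 when
the correlations are exactly constant).

## Wavelet coherence and rhythms

The Morlet continuous wavelet transform (centre frequency
`omega0 = 6`, Fourier period `4*pi*s/(omega0 + sqrt(2 + omega0^2))`) is
computed on a log-spaced period grid (0.5–48 h, 12 voices per octave).
Raw wavelet cross- and auto-spectra are degenerate (coherence ≡ 1), so
both are smoothed — a Gaussian in time with width equal to the scale, and
a boxcar over ~0.6 octave across scales — before forming the
magnitude-squared coherence (a magnitude option exists; the squared form
is the default because the toolbox conventions this follows report it).
The cone of influence (periods beyond `0.73 x` the distance to the nearest
edge) is excluded from all time-averaged summaries by default; including
it inflates circadian coherence on multi-day series, where 24–36 h periods
lose substantial edge area.

*Circadian coherence* is the mean coherence over 24 h ± 33% (16–32 h); a
narrow 20–28 h variant is exposed because both windows are in common use,
and the two agree closely on circadian-dominated signals (a property the
test suite checks).  Significance reuses the 30-minute block-shuffle null
on the band mean.  *Circadian phase lag* is the coherence-weighted
circular mean of the cross-spectral phase over the band (COI excluded),
converted to hours via the 24-h band-centre period; positive values mean
the neural circadian component peaks before glucose.  Offsets near ±12 h
are flagged wraparound-ambiguous — at a 24-h period, a 12-h lead and a
12-h lag are the same phase.

*Decomposition.*  `decompose_bands()` splits a series into circadian
(periods 18–36 h), ultradian (below 18 h) and residual (above 36 h, trend
and mean) components.  The binding contract is the reconstruction
identity — the three components must sum back to the input — so the split
is implemented as a zero-phase spectral partition of unity: raised-cosine
crossovers in log-frequency at the 18 h and 36 h cutoffs, applied to the
linearly detrended series (the trend joins the residual).  The identity
then holds at machine precision by construction, and two-tone separation
(24 h vs 4 h) leaks under 5% RMS.  An inverse-CWT reconstruction was
considered and rejected: its admissibility-constant reconstruction error
(percents) would have violated the identity that downstream
variance-partition arguments rely on.

*Phase lag vs temporal lag.*  Across channels, the circadian phase lead is
correlated with the correlational temporal lead (`-best_lag`), both in
hours with positive = neural leads.  Correlating the raw signed
conventions (phase positive = leads, temporal negative = leads) would pin
the sign of R at −1 by construction; using two leads makes the expected
relation positive and the reported R directly interpretable.

*Ultradian coupling* reruns the full coupling analysis on the ultradian
components.  By default it searches for its own best lag; a fixed lag
(typically the raw-series best lag, where the lag is most identifiable)
can be supplied — the component-wise series are noisier and, on strongly
periodic data, their rectified correlogram can have near-tied mirror peaks
(see *Limitations*).

## CCEP analysis

Stimulation epochs are 2-s windows centred on each pulse; pulses too close
to a recording edge are dropped and counted.  The immediate artifact
(0–10 ms) is blanked with a linear bridge — the quantification window
deliberately starts at 10 ms, so blanking cannot bias it.  Each epoch is
baseline-corrected by subtracting its mean over −150…+50 ms, making the
corrected baseline-window mean exactly zero.  The CCEP magnitude is the
signed mean of the pulse-averaged waveform over 10–150 ms (the signed mean
is the literal reading; a rectified option exists, and the window is
configurable because a 10–100 ms variant is also in circulation — the two
are deliberately not reconciled).  Coupled and uncoupled channel groups
are compared with a two-sample t-test, and magnitude is correlated with
the per-channel lag-corrected glucose coupling.

## The glucose decoder

The channels × bands × time envelope array is flattened to a rows ×
(6·N) feature table restricted to gray-matter contacts; the feature row at
time `t` is paired with the target at `t - shift` (negative shift =
features precede the target: proactive decoding).  Rows are split 80/20
into training and test (random rows by default, replicating common
practice; a blocked-by-time option exists because random splits of
autocorrelated series inflate R — reports should name the mode).  Feature
columns are standardised with training-set statistics only.

The L1 path is solved with glmnet over 50 log-spaced penalties spanning
four decades down from the smallest empty-model penalty.  Five-fold CV on
the training rows scores each penalty by the mean Pearson R between actual
and predicted target; the default selection takes the sparsest penalty
within one standard error of the best mean R (the standard one-SE rule).
The literal argmax (`lambda_rule = "max"`) is exposed, but on the nearly
flat CV curves that strong signals produce the argmax is decided by noise
in the fourth decimal and lands at the over-selection boundary, making the
selected support unstable; the one-SE rule is the stability-oriented
standard for exactly this situation.  Glucose values at or above
160 mg/dL are clipped to the threshold (with a parallel hyperglycaemia
flag), so the decoder identifies hyperglycaemic periods rather than
resolving their exact level.

*Shift sweep.*  Decoding is repeated across a grid of temporal shifts.
Fold-assignment noise on autocorrelated rows is comparable to the shift
effect itself, so each shift is scored by repeated cross-validation
(8 split draws by default) whose seeds are shared across shifts — shifts
are compared on a paired resampling plan, and the argmax is flagged when
it sits on the sweep boundary.

*Circadian controls*, evaluated at the optimal shift: (i) the full model;
(ii) a negative control decoding glucose shuffled in 1-h blocks; (iii) a
time-of-day control predicting measured glucose from the same-time-of-day
mean alone; (iv) the full model decoding the circadian component of
glucose; (v) the full model decoding the deviation of glucose from its
time-of-day mean.  The time-of-day profile is computed leave-one-day-out:
each point is predicted from the other days' same-time bins.  Computing
it from the whole series leaks each point's own noise into its prediction
and biases the control upward; restricting it to training folds handicaps
it with estimation error.  Per-fold R values are compared across
conditions by two-sample t-tests.

*Bootstrap importance.*  Rows are resampled with replacement (1000 trials
by default; the suite scales to 200) and the decoder refit at the penalty
chosen on the original split — re-nesting the full CV inside every trial
would multiply cost a thousandfold for no change in the selected-support
question.  A column is significant when selected in ≥ 99% of trials; its
median coefficient counts unselected trials as zero, and channels roll up
as significant when any of their bands is.

## What the generator emulates — and what it does not

`synth_config()` defaults define the study conditions: 6-day recordings
(9 days for experiments that need a well-estimated time-of-day profile,
matching the longest recording such studies report), 5-min glucose / 1-min
envelope cadences, a 24-h circadian component (glucose amplitude
12 mg/dL around a 110 mg/dL baseline; envelope amplitude 2 µV around
10 µV), shared ultradian sinusoids at 0.7, 1.8 and 7.8 h (glucose
amplitudes 2/3/5 mg/dL), per-channel temporal lags (default −2.8 h,
neural leading), AR(1) glucose noise (sd 4 mg/dL, coefficient 0.8 — CGM
noise is autocorrelated, and the permutation machinery should be exercised
against that), white envelope noise (sd 0.5 µV), a 23:00–07:00 sleep
schedule with three daily meals, and two smooth hyperglycaemia bumps
crossing 160 mg/dL to exercise the saturation rule.  Emitted series are
exactly the sum of their stored ground-truth components.  A raw-voltage
mode (amplitude-modulated in-band carrier) exists solely to test the
spectral chain, and `simulate_ccep()` emits damped-oscillation evoked
responses with configurable coupled/uncoupled amplitudes.

The generator is deliberately simple: its rhythms are phase-locked
sinusoids, its sleep schedule is exact, and its noise is stationary.
Passing recovery tests on it demonstrates that the estimators are
correct and calibrated under known structure — not that real recordings
satisfy that structure.  Real ultradian rhythms drift in phase and
amplitude, real sleep is fragmented, and real CGM noise is neither
stationary nor Gaussian.

## Known limitations

* **Mirror peaks on sinusoidal fixtures.**  The default period set
  (24 / 7.8 / 1.8 / 0.7 h) happens to share a near-common half-period
  alignment around an 11.6-h lag offset, so the rectified correlogram of a
  strongly coupled pair has a mirror peak at ~98.8% of the true peak's
  |r|.  Under sampling noise a small fraction of runs flip to the mirror —
  a property of phase-locked sinusoids that would defeat any estimator,
  and the reason the lag-recovery acceptance check can report isolated
  ~11.6-h errors.  Real quasi-periodic signals decorrelate at distant lags
  and do not exhibit this degeneracy.
* **Block-null anti-conservativeness** under noise whose correlation time
  approaches the block length (see above).
* **Phase wrap** at half the circadian period: ±12-h offsets are reported
  with an ambiguity flag, not resolved.
* **Hyperglycaemia transients** are broadband and perturb circadian-scale
  phase estimates; rhythm-recovery experiments therefore use episode-free
  fixtures, while decoder and coupling fixtures keep episodes on.
* The equality comparison between the full decoder and the time-of-day
  control on circadian-only data tests a ~0.01 difference in R against
  fold noise of similar size; its p-value is intrinsically seed-sensitive.

## Reproducibility

Every stochastic stage takes an explicit seed; `run_all()` derives all
stage seeds from one master seed and writes a manifest with config and
output checksums, so reruns with the same configuration are
byte-identical.  The acceptance script
(`Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json`)
recomputes the package's headline quantities — oracle agreement of the
correlogram, permutation-null calibration, lag/phase recovery, the
decomposition identity, ablation and wake-gating effects, decoder
support recovery, shift-sweep argmax, control ordering, bootstrap
importance separation, and CCEP detection power — from scratch at the
problem sizes named above.
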