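# neuroglyc

Tools for linking multichannel intracranial neural activity to continuous
interstitial glucose.  Multi-day stereo-EEG recordings are reduced to
smoothed Hilbert powerband envelopes (delta through 70–170 Hz
high-frequency activity), aligned with 5-minute continuous glucose monitor
(CGM) series, and analysed for:

* **lag-resolved coupling** — a rectified cross-correlogram over ±12 h
  (negative lag = neural leads) with a 30-minute block-permutation null and
  sleep/wake/meal-state stratification;
* **rhythms** — Morlet wavelet coherence, circadian-band (24 h ± 33%)
  coherence and phase lag, and an exact circadian (18–36 h) / ultradian
  (< 18 h) signal decomposition;
* **effective connectivity** — stimulation-evoked potential (CCEP)
  magnitudes compared between glucose-coupled and uncoupled channels;
* **decoding** — a sparse linear (LASSO) model predicting glucose, now or
  hours ahead, from the flattened channels × bands feature table, with a
  temporal-shift sweep, circadian/shuffled controls, state-stratified RMSE
  and bootstrap channel importance.

For a feature series `x` and glucose `y` on a common 5-min grid, the
coupling statistic is the Pearson correlation `r(ℓ) = cor(x(t+ℓ), y(t))`
maximised in |r| over lags ℓ ∈ [−12 h, +12 h]; the decoder solves

```
min_β  ‖y − Xβ − β₀‖² / 2n  +  λ‖β‖₁
```

with λ chosen by 5-fold cross-validated Pearson R (one-standard-error
rule), features standardised on training rows only, and glucose clipped at
160 mg/dL so hyperglycaemic periods are identified rather than resolved.

Since recordings of this kind cannot be redistributed, the package includes
a synthetic generator (`simulate_study()`) emitting envelopes, glucose,
state annotations and CCEP epochs with fully known circadian/ultradian
structure, coupling lags and noise; all tests are parameter-recovery tests
against that ground truth.

## Worked example

```r
library(neuroglyc)

sim     <- simulate_study(synth_config(duration_days = 6, n_channels = 8,
                                       coupled_channels = 1:6, seed = 1))
aligned <- align_series(sim$envelopes, sim$glucose, sim$states)
aligned
#> <aligned_pair> 8 channels x 1 bands x 1728 grid points @ 300s

## lag-resolved coupling of channel 1 HFA with glucose
res <- couple(aligned$features[1, 1, ], aligned$glucose,
              cfg = coupling_config(n_permutations = 200),
              masks = aligned$masks, seed = 1)
res
#> <coupling_result> best lag -2.83 h, r = 0.756 (p = 0.004975)
```

The channel's envelope leads glucose by 2.8 h (the generator's programmed
lag) with r = 0.76 at that lag, significant against the block-permutation
null; the state-stratified correlations are r = 0.56 asleep and r = 0.71
awake.

```r
cc <- circadian_coherence(aligned$features[1, 1, ], aligned$glucose,
                          dt_h = 1/12, n_permutations = 200, seed = 1)
pl <- circadian_phase_lag(wavelet_coherence(aligned$features[1, 1, ],
                                            aligned$glucose, dt_h = 1/12))
#> circadian coherence = 0.93 (p = 0.005); phase lead = 2.90 h

## proactive decoding: features 2.8 h ahead of the glucose they predict
ft    <- build_features(aligned, "level", shift_h = -2.8333)
ft$y  <- saturate_target(ft$y)$values
fit   <- fit_lasso_lar(ft, decoder_config(seed = 1))
fit
#> <decoder_result> lambda = 8.022, 2 nonzero of 8 features, test R = 0.833 (RMSE 10.44)
```

The circadian phase lead (2.9 h) matches the temporal lag, and the sparse
decoder predicts held-out glucose 2.8 h ahead with R = 0.83 from 2 of the
8 channel features.  `run_all(run_config(out_dir = "out"))` chains every
stage (coupling table, rhythm table, shift sweep, controls, importance,
predictions) and writes tidy CSVs plus a seed-stamped JSON manifest;
`inst/scripts/neuroglyc.R` wraps `simulate` and `run-all` for the shell.

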