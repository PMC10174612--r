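dt_h <- 1 / 12
t6 <- (0:(1728 - 1)) * dt_h                      # six days at 5-min cadence

test_that("coherence is 1 with zero phase for identical circadian signals", {
  x <- cos(2 * pi * t6 / 24)
  cr <- wavelet_coherence(x, x, dt_h)
  expect_true(all(cr$coh >= 0 & cr$coh <= 1))
  band <- cr$periods_h >= 16 & cr$periods_h <= 32
  expect_gt(mean(cr$coh[band, ]), 0.999)
  pl <- circadian_phase_lag(cr)
  expect_lt(abs(pl$lag_h), 0.05)
})

test_that("a six-hour circadian offset maps to phase pi/2 and six hours", {
  x <- cos(2 * pi * t6 / 24)                      # x leads y by 6 h
  y <- cos(2 * pi * (t6 - 6) / 24)
  cr <- wavelet_coherence(x, y, dt_h)
  pl <- circadian_phase_lag(cr)
  expect_lt(abs(pl$phase_rad - pi / 2), 0.05)
  expect_lt(abs(pl$lag_h - 6), 0.2)
  expect_false(pl$wrap_ambiguous)
  ## a 12-h offset is flagged as wraparound-ambiguous
  y12 <- cos(2 * pi * (t6 - 12) / 24)
  pl12 <- circadian_phase_lag(wavelet_coherence(x, y12, dt_h))
  expect_true(pl12$wrap_ambiguous)
})

test_that("coherence is invariant to affine rescaling of the inputs", {
  set.seed(20)
  x <- cos(2 * pi * t6 / 24) + 0.3 * rnorm(length(t6))
  y <- cos(2 * pi * (t6 - 2) / 24) + 0.3 * rnorm(length(t6))
  a <- wavelet_coherence(x, y, dt_h)
  b <- wavelet_coherence(10 - 4 * x, 0.02 * y + 7, dt_h)
  expect_equal(a$coh, b$coh, tolerance = 1e-9)
})

test_that("circadian coherence: significance, narrow-band agreement, null case", {
  sim <- simulate_study(synth_config(duration_days = 6, n_channels = 2,
                                     coupled_channels = 1, hyper_count = 0,
                                     channel_circ_amp = c(2, 0), seed = 30))
  al <- align_series(sim$envelopes, sim$glucose, sim$states)
  cc <- circadian_coherence(al$features[1, 1, ], al$glucose, dt_h,
                            n_permutations = 100, seed = 1)
  expect_true(cc$significant)
  ## default 16-32 h band and narrow 20-28 h band agree within 10%
  cc_n <- circadian_coherence(al$features[1, 1, ], al$glucose, dt_h,
                              band_h = c(20, 28), n_permutations = 0)
  expect_lt(abs(cc_n$coherence - cc$coherence) / cc$coherence, 0.10)
  ## channel 2 has no circadian term and independent ultradian phases
  cc0 <- circadian_coherence(al$features[2, 1, ], al$glucose, dt_h,
                             n_permutations = 100, seed = 2)
  expect_false(cc0$significant)
  ## undefined phase lag when coherence is not significant
  cr0 <- wavelet_coherence(al$features[2, 1, ], al$glucose, dt_h)
  expect_warning(pl0 <- circadian_phase_lag(cr0, significant = FALSE),
                 "not significant")
  expect_true(is.na(pl0$lag_h))
})

test_that("band decomposition separates tones and reconstructs exactly", {
  ## pure 24-h tone: all circadian
  x24 <- 3 * cos(2 * pi * t6 / 24)
  d <- decompose_bands(x24, dt_h)
  expect_lt(sqrt(mean(d$ultradian^2)) / sqrt(mean(x24^2)), 0.01)
  expect_lt(sqrt(mean((d$circadian - x24)^2)) / sqrt(mean(x24^2)), 0.01)
  ## 24-h + 4-h mix: cross-leakage under 5% RMS
  u4 <- 1.5 * cos(2 * pi * t6 / 4)
  d2 <- decompose_bands(x24 + u4, dt_h)
  expect_lt(sqrt(mean((d2$circadian - x24)^2)) / sqrt(mean(x24^2)), 0.05)
  expect_lt(sqrt(mean((d2$ultradian - u4)^2)) / sqrt(mean(u4^2)), 0.05)
  ## reconstruction identity on arbitrary input
  set.seed(21)
  z <- cumsum(rnorm(length(t6))) + x24 + u4
  d3 <- decompose_bands(z, dt_h)
  err <- d3$circadian + d3$ultradian + d3$residual - z
  expect_lt(sqrt(mean(err^2)) / sqrt(mean((z - mean(z))^2)), 1e-10)
})

test_that("removing the circadian component reduces coupling as programmed", {
  sim <- simulate_study(synth_config(duration_days = 6, n_channels = 1,
                                     coupled_channels = 1, seed = 31))
  al <- align_series(sim$envelopes, sim$glucose, sim$states)
  x <- al$features[1, 1, ]; g <- al$glucose
  r_raw <- abs(best_lag_correlation(
    cross_correlogram(x, g, 144, dt_h = dt_h))$r)
  uc <- ultradian_coupling(x, g, 300)
  expect_lt(abs(uc$r_at_best), r_raw)
})

test_that("phase lag vs temporal lag handles degenerate inputs", {
  pv <- phase_vs_temporal_lag(rep(2, 12), rnorm(12))
  expect_true(is.na(pv$r))
  expect_match(pv$note, "zero variance")
  pv2 <- phase_vs_temporal_lag(rnorm(5), rnorm(5))
  expect_true(is.na(pv2$r))
  expect_match(pv2$note, "too few")
  set.seed(22)
  ph <- runif(20, -6, 6)
  pv3 <- phase_vs_temporal_lag(ph, -ph + rnorm(20, sd = 0.01))
  expect_gt(pv3$r, 0.99)
})
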