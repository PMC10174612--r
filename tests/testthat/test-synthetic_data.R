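test_that("the same seed reproduces identical output; seeds differ only in noise", {
  a <- quick_sim(seed = 7)
  b <- quick_sim(seed = 7)
  expect_identical(a$envelopes$values, b$envelopes$values)
  expect_identical(a$glucose$value, b$glucose$value)
  d <- quick_sim(seed = 8)
  expect_false(identical(a$glucose$value, d$glucose$value))
  ## structural parameters unchanged across seeds
  expect_identical(a$truth$lag_h, d$truth$lag_h)
  expect_identical(a$truth$coupled, d$truth$coupled)
})

test_that("emitted series equal the sum of their ground-truth components", {
  sim <- quick_sim(seed = 3, nch = 3)
  tr <- sim$truth
  g <- tr$glucose
  expect_equal(g$baseline + g$circadian + g$ultradian + g$episodes + g$noise,
               sim$glucose$value, tolerance = 1e-12)
  for (ch in 1:3) {
    cc <- tr$channels[[ch]]
    rec <- cc$base + cc$band_gain[1] * (cc$circadian + cc$ultradian) + cc$noise[1, ]
    expect_equal(rec, sim$envelopes$values[ch, 1, ], tolerance = 1e-12)
  }
})

test_that("a noise-free pair peaks at the injected lag", {
  sim <- simulate_study(synth_config(duration_days = 6, n_channels = 1,
                                     coupled_channels = 1, lag_h = -2.8,
                                     noise_sd_channel = 0, noise_sd_glucose = 0,
                                     hyper_count = 0, seed = 3))
  al <- align_series(sim$envelopes, sim$glucose, sim$states)
  best <- best_lag_correlation(
    cross_correlogram(al$features[1, 1, ], al$glucose, 144, dt_h = 1 / 12))
  expect_lt(abs(best$lag_h - (-2.8)), 1 / 12 + 1e-9)
  ## with zero ultradian amplitude, glucose minus circadian truth is pure noise
  sim2 <- simulate_study(synth_config(duration_days = 4, n_channels = 1,
                                      glucose_ultra_amp = c(0, 0, 0),
                                      channel_ultra_amp = c(0, 0, 0),
                                      hyper_count = 0, seed = 4))
  resid <- sim2$glucose$value - sim2$truth$glucose$baseline -
    sim2$truth$glucose$circadian
  expect_equal(resid, sim2$truth$glucose$noise, tolerance = 1e-12)
})

test_that("simulated CCEP epochs match their analytic template", {
  ## noise-free: measured magnitude equals amplitude times the template mean,
  ## corrected for the template's own baseline-window mean
  ep <- simulate_ccep(n_channels = 4, coupled = 1:2, amp_coupled = 50,
                      amp_uncoupled = 0, noise_sd = 0, amp_jitter = 0, seed = 1)
  epc <- ccep_baseline(ep)
  mag <- ccep_magnitude(epc)
  bsel <- ep$rel_time >= -0.150 & ep$rel_time <= 0.050
  expected <- 50 * (ep$truth$window_mean - mean(ep$truth$template[bsel]))
  expect_equal(unname(mag[1]), expected, tolerance = 1e-10)
  expect_equal(unname(mag[3]), 0, tolerance = 1e-10)
})

test_that("averaging across pulses shrinks noise like one over sqrt(n)", {
  sd_of_mean <- function(n_pulses, seed) {
    ep <- simulate_ccep(n_channels = 1, coupled = integer(0), amp_coupled = 1e-9,
                        amp_uncoupled = 0, n_pulses = n_pulses, noise_sd = 5,
                        amp_jitter = 0, seed = seed)
    stats::sd(ccep_mean_waveform(ep)[1, ])
  }
  r <- mean(vapply(1:5, function(s) sd_of_mean(1, s), 1)) /
    mean(vapply(1:5, function(s) sd_of_mean(50, s + 10), 1))
  expect_gt(r, sqrt(50) * 0.8)
  expect_lt(r, sqrt(50) * 1.25)
})

test_that("sparse feature fixture has the advertised structure", {
  ft <- simulate_sparse_features(n_rows = 400, seed = 2)
  expect_equal(ncol(ft$X), 60L)
  expect_length(ft$truth$active, 3L)
  sig <- as.numeric(ft$X %*% ft$truth$beta)
  expect_equal(stats::sd(ft$y - sig - mean(ft$y - sig)) * 20,
               stats::sd(sig), tolerance = 0.15)
})
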