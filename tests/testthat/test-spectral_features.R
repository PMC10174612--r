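test_that("notch attenuates the line frequency and spares the passband", {
  fs <- 512
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  rec <- neural_recording(rbind(sin(2 * pi * 60 * t),
                                sin(2 * pi * 10 * t),
                                rep(1, length(t))), fs)
  out <- notch_filter(rec)
  mid <- 5000:25000                               # away from filter edges
  expect_lt(stats::sd(out$samples[1, mid]) / stats::sd(rec$samples[1, mid]), 0.10)
  expect_gt(stats::sd(out$samples[2, mid]) / stats::sd(rec$samples[2, mid]), 0.95)
  ## DC unchanged
  expect_equal(out$samples[3, mid], rec$samples[3, mid], tolerance = 1e-6)
  expect_error(notch_filter(neural_recording(matrix(rnorm(100), 1), fs = 100),
                            freqs = 49), "Nyquist")
})

test_that("Laplacian re-referencing follows the neighbour arithmetic", {
  set.seed(6)
  x <- rnorm(50); y <- rnorm(50); z <- rnorm(50)
  ch <- channel_meta(c("a1", "a2", "a3"), electrode = "a", contact_index = 1:3)
  rec <- neural_recording(rbind(x, y, z), fs = 10, channels = ch)
  out <- rereference_laplacian(rec)
  expect_equal(out$samples[2, ], y - (x + z) / 2, ignore_attr = TRUE)
  expect_equal(out$samples[1, ], x - y, ignore_attr = TRUE)   # bipolar fallback
  expect_equal(out$samples[3, ], z - y, ignore_attr = TRUE)
  ## identical signals: interior contact cancels exactly
  rec2 <- neural_recording(rbind(x, x, x), fs = 10, channels = ch)
  expect_equal(max(abs(rereference_laplacian(rec2)$samples[2, ])), 0)
  ## contacts [0, x, 0] -> interior output = x
  rec3 <- neural_recording(rbind(0 * x, x, 0 * x), fs = 10, channels = ch)
  expect_equal(rereference_laplacian(rec3)$samples[2, ], x, ignore_attr = TRUE)
  ## single-contact electrode passes through with a warning
  rec4 <- neural_recording(matrix(x, 1), fs = 10,
                           channels = channel_meta("solo"))
  expect_warning(rereference_laplacian(rec4), "single-contact")
})

test_that("band envelope recovers amplitude in-band and rejects out-of-band", {
  fs <- 512
  t <- seq(0, 300 - 1 / fs, by = 1 / fs)
  hfa <- band_definition("hfa", 70, 170, 8)
  ## sinusoid at band centre, amplitude 2.5
  rec <- neural_recording(matrix(2.5 * sin(2 * pi * 100 * t), 1), fs)
  v <- band_envelope(rec, hfa)$values[1, 1, ]
  v <- v[is.finite(v)]
  expect_true(all(abs(v - 2.5) / 2.5 < 0.05))
  ## far outside the band: near-zero envelope
  rec2 <- neural_recording(matrix(2.5 * sin(2 * pi * 10 * t), 1), fs)
  v2 <- band_envelope(rec2, hfa)$values[1, 1, ]
  expect_lt(max(v2[is.finite(v2)]), 0.01)
  ## linearity: scaling the input scales the envelope
  rec3 <- neural_recording(matrix(7.5 * sin(2 * pi * 100 * t), 1), fs)
  v3 <- band_envelope(rec3, hfa)$values[1, 1, ]
  expect_equal(v3[is.finite(v3)], 3 * v, tolerance = 1e-9)
  ## non-negativity
  expect_true(all(v >= 0))
  expect_error(band_envelope(rec, band_definition("x", 200, 300, 4)), "Nyquist")
})

test_that("an amplitude-modulated carrier is demodulated to its envelope", {
  fs <- 512
  t <- seq(0, 600 - 1 / fs, by = 1 / fs)
  A <- 2 + sin(2 * pi * t / 150)                 # 2.5-min modulation
  rec <- neural_recording(matrix(A * sin(2 * pi * 100 * t), 1), fs)
  env <- band_envelope(rec, band_definition("hfa", 70, 170, 8))
  keep <- is.finite(env$values[1, 1, ])
  centers <- as.numeric(env$time - rec$start_time, units = "secs")[keep]
  target <- vapply(centers, function(ct) mean(A[t >= ct - 30 & t < ct + 30]), 1)
  expect_gt(stats::cor(env$values[1, 1, keep], target), 0.99)
})

test_that("the full chain recovers a programmed envelope on synthetic voltage", {
  sim <- simulate_raw_voltage(duration_s = 1500, seed = 11)
  cfg <- spectral_config(reference = "none",
                         bands = list(band_definition("hfa", 70, 170, 8)))
  env <- compute_envelopes(sim$rec, cfg)
  sec <- round(as.numeric(env$time - sim$rec$start_time, units = "secs"))
  idx <- match(sim$center_s, sec)
  v <- env$values[1, 1, idx]
  ok <- is.finite(v)
  expect_gt(stats::cor(v[ok], sim$true_env[ok]), 0.95)
})

test_that("white-matter contacts are excluded before analysis", {
  set.seed(8)
  ch <- channel_meta(c("g1", "g2", "w1"), electrode = "e", contact_index = 1:3,
                     tissue = c("gray", "gray", "white"))
  rec <- neural_recording(matrix(rnorm(3 * 512 * 130), nrow = 3), fs = 512,
                          channels = ch)
  env <- compute_envelopes(rec, spectral_config(reference = "none",
                                                bands = list(band_definition("gamma", 25, 70, 4))))
  expect_equal(dim(env$values)[1], 2L)
  expect_equal(env$channels$name, c("g1", "g2"))
})
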