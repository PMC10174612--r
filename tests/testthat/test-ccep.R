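test_that("epoching drops edge pulses and baseline-corrects exactly", {
  fs <- 256
  set.seed(40)
  n <- fs * 60
  x <- matrix(rnorm(2 * n, sd = 3), nrow = 2) + c(10, -5)   # channel offsets
  rec <- neural_recording(x, fs)
  pulses <- c(0.2, seq(5, 55, by = 1), 59.9)                # 2 pulses too close
  ep <- epoch_ccep(rec, pulses)
  expect_equal(ep$n_dropped, 2L)
  expect_equal(dim(ep$epochs)[2], length(pulses) - 2L)
  expect_equal(abs(diff(range(ep$rel_time))), 2 - 1 / fs, tolerance = 1e-9)
  ## baseline-window mean is zero per epoch to machine precision
  bsel <- ep$rel_time >= -0.150 & ep$rel_time <= 0.050
  for (ch in 1:2) {
    m <- matrix(ep$epochs[ch, , ], nrow = dim(ep$epochs)[2])
    expect_lt(max(abs(rowMeans(m[, bsel]))), 1e-10)
  }
})

test_that("a constant-offset channel is exactly zero after correction", {
  fs <- 256
  rec <- neural_recording(matrix(7.5, nrow = 1, ncol = fs * 20), fs)
  ep <- epoch_ccep(rec, c(5, 10, 15))
  expect_lt(max(abs(ep$epochs)), 1e-12)
})

test_that("magnitude is the window mean and is linear in amplitude", {
  ep <- simulate_ccep(n_channels = 2, coupled = 1, amp_coupled = 12,
                      amp_uncoupled = 0, noise_sd = 0, amp_jitter = 0, seed = 2)
  epc <- ccep_baseline(ep)
  ## rectangular pulse covering half the window averages to half its height
  sel <- epc$rel_time >= 0.010 & epc$rel_time <= 0.150
  half <- epc$rel_time >= 0.010 & epc$rel_time <= 0.080
  epc$epochs[2, , ] <- 0
  epc$epochs[2, , half] <- 50
  mag <- ccep_magnitude(epc)
  expect_equal(unname(mag[2]), 50 * sum(half) / sum(sel), tolerance = 1e-12)
  ## linearity in template amplitude
  ep2 <- simulate_ccep(n_channels = 2, coupled = 1, amp_coupled = 36,
                       amp_uncoupled = 0, noise_sd = 0, amp_jitter = 0, seed = 2)
  mag2 <- ccep_magnitude(ccep_baseline(ep2))
  expect_equal(unname(mag2[1]), 3 * unname(ccep_magnitude(ccep_baseline(
    simulate_ccep(n_channels = 2, coupled = 1, amp_coupled = 12,
                  amp_uncoupled = 0, noise_sd = 0, amp_jitter = 0,
                  seed = 2)))[1]), tolerance = 1e-9)
  ## magnitude requires baseline correction first
  expect_error(ccep_magnitude(ep), "baseline")
})

test_that("coupled-vs-uncoupled comparison detects programmed differences", {
  ep <- simulate_ccep(amp_coupled = 30, amp_uncoupled = 10, seed = 5)
  mag <- ccep_magnitude(ccep_baseline(ep))
  st <- compare_by_coupling(mag, ep$truth$coupled)
  expect_lt(st$p, 0.05)
  expect_gt(st$mean_coupled, st$mean_uncoupled)
  ## magnitudes proportional to coupling r give a strong correlation
  r_ch <- ep$truth$amp / max(ep$truth$amp)
  st2 <- compare_by_coupling(mag, ep$truth$coupled, coupling_r = r_ch)
  expect_gt(st2$cor_r, 0.9)
  ## degenerate group sizes -> undefined t
  st3 <- compare_by_coupling(mag, c(TRUE, rep(FALSE, 19)))
  expect_true(is.na(st3$t))
})
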