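test_that("cross-correlogram matches the naive shifted-Pearson oracle", {
  set.seed(10)
  for (n in c(200, 500)) {
    x <- as.numeric(arima.sim(list(ar = 0.6), n))
    y <- as.numeric(arima.sim(list(ar = 0.6), n))
    cc <- cross_correlogram(x, y, max_lag = 20, min_overlap = 10)
    expect_lt(max(abs(cc$r - naive_xcf(x, y, 20))), 1e-12)
  }
  ## and with missing values excluded pairwise
  x <- rnorm(300); y <- rnorm(300)
  x[c(5, 60:64)] <- NA; y[200:210] <- NA
  cc <- cross_correlogram(x, y, 10, min_overlap = 10)
  l <- 3
  ok <- is.finite(x[(1 + l):300]) & is.finite(y[1:(300 - l)])
  expect_equal(cc$r[cc$lags == l],
               stats::cor(x[(1 + l):300][ok], y[1:(300 - l)][ok]))
})

test_that("correlogram symmetry and affine invariance hold exactly", {
  set.seed(11)
  x <- rnorm(250); y <- rnorm(250)
  a <- cross_correlogram(x, y, 15, min_overlap = 10)
  b <- cross_correlogram(y, x, 15, min_overlap = 10)
  expect_equal(a$r, rev(b$r))
  c2 <- cross_correlogram(5 - 3 * x, 0.1 * y + 40, 15, min_overlap = 10)
  expect_equal(abs(c2$r), abs(a$r), tolerance = 1e-12)
  expect_error(cross_correlogram(rep(1, 100), rnorm(100), 5), "constant")
})

test_that("best lag follows the rectified criterion with its tie-breaks", {
  cc <- structure(list(lags = c(-24L, 12L), r = c(-0.6, 0.5),
                       lag_h = c(-2, 1), n = c(100L, 100L)),
                  class = "cross_correlogram")
  best <- best_lag_correlation(cc)
  expect_equal(best$lag_h, -2)
  expect_equal(best$r, -0.6)
  ## flat correlogram -> lag 0
  flat <- structure(list(lags = -5:5, r = rep(0.3, 11), lag_h = (-5:5) / 12,
                         n = rep(100L, 11)), class = "cross_correlogram")
  expect_equal(best_lag_correlation(flat)$lag, 0L)
})

test_that("block permutation excludes the identity and nails extreme cases", {
  set.seed(12)
  x <- as.numeric(arima.sim(list(ar = 0.5), 400))
  y <- c(x[31:400], x[1:30])                 # circularly shifted copy
  cfg <- coupling_config(max_lag_h = 3, n_permutations = 100)
  pn <- permutation_null(x, y, cfg, dt_s = 300, seed = 1)
  expect_lte(pn$p, 1 / 100)
  expect_true(pn$significant)
  expect_true(all(pn$null_max < pn$obs_max))
  expect_error(permutation_null(x[1:50], y[1:50],
                                coupling_config(max_lag_h = 1,
                                                n_permutations = 100),
                                dt_s = 300), "blocks")
})

test_that("state stratification uses the lag-corrected overlap", {
  set.seed(13)
  n <- 400
  x <- rnorm(n); y <- 0.8 * x + rnorm(n, sd = 0.5)
  masks <- list(all = rep(TRUE, n), none = rep(FALSE, n),
                half = seq_len(n) <= n / 2)
  sr <- suppressWarnings(stratified_correlation(x, y, 0L, masks))
  expect_equal(sr[["all"]], stats::cor(x, y))
  expect_true(is.na(sr[["none"]]))
  expect_equal(sr[["half"]], stats::cor(x[1:200], y[1:200]))
  expect_warning(stratified_correlation(x, y, 0L, list(tiny = c(TRUE, rep(FALSE, n - 1)))),
                 "fewer than")
})

test_that("wake-gated ultradian coupling is stronger awake than asleep", {
  sim <- simulate_study(synth_config(duration_days = 6, n_channels = 1,
                                     coupled_channels = 1,
                                     wake_gated_ultradian = TRUE,
                                     hyper_count = 0, seed = 91))
  al <- align_series(sim$envelopes, sim$glucose, sim$states)
  true_lag <- as.integer(round(sim$truth$lag_h[1] * 12))
  uc <- ultradian_coupling(al$features[1, 1, ], al$glucose, 300,
                           masks = al$masks, lag = true_lag)
  expect_gt(uc$state_r[["wake"]], uc$state_r[["sleep"]])
})

test_that("regional summary aggregates, pairs and compares regions", {
  set.seed(14)
  tbl <- data.frame(channel = sprintf("c%d", 1:12),
                    region = rep(c("hypothalamus", "insula"), each = 6),
                    r_best = c(rnorm(6, 0.5, 0.03), rnorm(6, 0.2, 0.03)),
                    r_sleep = rnorm(12, 0.5, 0.05),
                    r_wake = rnorm(12, 0.3, 0.05))
  rs <- regional_summary(tbl)
  expect_equal(nrow(rs$region_table), 6L)
  expect_lt(rs$anova$p, 0.05)
  expect_equal(rs$paired_tests$region, c("hypothalamus", "insula"))
  ## identical correlations: zero SEM, ANOVA F ~ 0
  tbl2 <- tbl; tbl2$r_best <- 0.4
  rs2 <- regional_summary(tbl2)
  expect_equal(rs2$region_table$sem_r[rs2$region_table$state == "all"], c(0, 0))
  expect_true(is.na(rs2$anova$F) || rs2$anova$F < 1e-10)  # 0/0 with no variance
  ## single region: ANOVA skipped with a note
  rs3 <- regional_summary(tbl[tbl$region == "insula", ])
  expect_null(rs3$anova)
  expect_match(rs3$note, "single region")
})
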