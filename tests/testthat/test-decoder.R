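test_that("feature building flattens bands, shifts targets and standardises", {
  sim <- simulate_study(synth_config(duration_days = 4, n_channels = 5,
                                     n_bands = 6, seed = 50))
  al <- align_series(sim$envelopes, sim$glucose, sim$states)
  ft <- build_features(al, "level")
  expect_equal(ncol(ft$X), 30L)                  # 6 bands x 5 channels
  expect_equal(nrow(ft$col_meta), 30L)
  ## shift arithmetic: -2 h on a 5-min grid offsets the target by 24 rows
  ft_s <- build_features(al, "level", shift_h = -2)
  i <- 100L
  expect_equal(ft_s$y[i], al$glucose[match(ft_s$time[i], al$time)])
  expect_equal(as.numeric(ft_s$time[i] - al$time[1]) ,
               as.numeric(ft$time[i + 24] - al$time[1]))
  ## training-column standardisation is exact on the training rows
  cfg <- decoder_config(seed = 3)
  fit <- fit_lasso_lar(ft, cfg)
  Xs <- sweep(sweep(ft$X, 2, fit$standardization$mu, "-"),
              2, fit$standardization$sd, "/")
  tr <- fit$split$train
  expect_lt(max(abs(colMeans(Xs[tr, ]))), 1e-10)
  expect_lt(max(abs(apply(Xs[tr, ], 2, sd) - 1)), 1e-10)
  expect_error(build_features(al, "level", shift_h = -80), "usable rows")
})

test_that("the saturation rule clips at the threshold and flags hyperglycaemia", {
  s <- saturate_target(c(150, 160, 190))
  expect_equal(s$values, c(150, 160, 160))
  expect_equal(s$hyper, c(FALSE, TRUE, TRUE))
  expect_equal(saturate_target(c(80, 120))$values, c(80, 120))
  expect_equal(saturate_target(c(80, 500), threshold = Inf)$values, c(80, 500))
})

test_that("a sparse linear ground truth is recovered with near-perfect R", {
  ft <- simulate_sparse_features(n_rows = 1500, seed = 11)
  fit <- fit_lasso_lar(ft, decoder_config(seed = 12))
  expect_identical(unname(which(abs(fit$coef) > 0)),
                   as.integer(ft$truth$active))
  expect_true(all(sign(fit$coef[ft$truth$active]) ==
                  sign(ft$truth$beta[ft$truth$active])))
  expect_gt(fit$test_r, 0.99)
})

test_that("no leakage: a shuffled target decodes to chance", {
  ft <- simulate_sparse_features(n_rows = 1500, seed = 13)
  set.seed(14)
  ft$y <- sample(ft$y)
  fit <- fit_lasso_lar(ft, decoder_config(seed = 15))
  expect_lt(abs(fit$test_r), 0.15)
})

test_that("sparsity is monotone along the penalty path; huge penalty empties the model", {
  ft <- simulate_sparse_features(n_rows = 600, seed = 16)
  fit <- fit_lasso_lar(ft, decoder_config(seed = 17))
  g <- glmnet::glmnet(scale(ft$X), ft$y, lambda = fit$lambda_grid,
                      standardize = FALSE)
  nz <- vapply(seq_along(fit$lambda_grid), function(i)
    sum(abs(as.numeric(stats::coef(g, s = fit$lambda_grid[i]))[-1]) > 0), 0L)
  expect_true(all(diff(nz) >= 0))                # grid is decreasing in lambda
  ## at or above this matrix's own lambda_max the model is empty
  g0 <- glmnet::glmnet(scale(ft$X), ft$y, standardize = FALSE)
  expect_equal(sum(abs(as.numeric(stats::coef(g0, s = g0$lambda[1]))[-1]) > 0), 0L)
  expect_error(fit_lasso_lar(feature_table(ft$X, rep(1, nrow(ft$X)),
                                           ft$time, ft$col_meta)),
               "constant")
})

test_that("prediction is invariant to affine rescaling of a feature column", {
  ft <- simulate_sparse_features(n_rows = 500, seed = 18)
  fit <- fit_lasso_lar(ft, decoder_config(seed = 19))
  ft2 <- ft
  ft2$X[, 5] <- ft2$X[, 5] * 40 - 7
  fit2 <- fit_lasso_lar(ft2, decoder_config(seed = 19))
  expect_equal(fit2$predictions$predicted, fit$predictions$predicted,
               tolerance = 1e-6)
})

test_that("bootstrap importance flags true columns and respects n_trials = 1", {
  ft <- simulate_sparse_features(n_rows = 800, seed = 20)
  imp <- bootstrap_importance(ft, decoder_config(seed = 21), n_trials = 25)
  expect_true(all(imp$frequency[ft$truth$active] == 1))
  expect_true(all(imp$frequency >= 0 & imp$frequency <= 1))
  ## never-selected columns have zero median coefficient
  expect_true(all(imp$median_coef[imp$frequency == 0] == 0))
  imp1 <- bootstrap_importance(ft, decoder_config(seed = 22), n_trials = 1)
  expect_true(all(imp1$frequency %in% c(0, 1)))
})

test_that("stratified RMSE reports per-state error relative to the whole test set", {
  sim <- simulate_study(synth_config(duration_days = 6, n_channels = 4, seed = 52))
  al <- align_series(sim$envelopes, sim$glucose, sim$states)
  ft <- build_features(al, "level")
  fit <- fit_lasso_lar(ft, decoder_config(seed = 53))
  sr <- stratified_rmse(fit, ft)
  expect_true(all(c("sleep", "wake") %in% sr$state))
  ok <- is.finite(sr$rmse)
  expect_true(any(ok))
  overall <- attr(sr, "overall_rmse")
  expect_equal(sr$pct_diff[ok], 100 * (sr$rmse[ok] - overall) / overall)
})

test_that("the derivative-target pipeline runs end to end", {
  sim <- simulate_study(synth_config(duration_days = 6, n_channels = 4, seed = 54))
  al <- align_series(sim$envelopes, sim$glucose, sim$states)
  ft <- build_features(al, "derivative", shift_h = 0)
  fit <- fit_lasso_lar(ft, decoder_config(seed = 55))
  expect_true(is.finite(fit$test_r))
  expect_true(abs(fit$test_r) <= 1)
})
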