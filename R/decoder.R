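## glucose_decoder: spectro-spatial sparse linear decoding of glucose from
## powerband envelopes.  The L1 path is solved with glmnet; feature
## standardisation, the cross-validated penalty choice by Pearson R, the
## temporal shift sweep, circadian controls, state-stratified RMSE and the
## bootstrap channel-importance analysis are implemented here.

#' Decoder configuration
#'
#' @param test_fraction held-out fraction of rows (default 0.20).
#' @param cv_folds folds for the penalty search (default 5).
#' @param n_lambda,lambda_decades penalty grid: `n_lambda` log-spaced values
#'   from the smallest penalty giving an empty model down `lambda_decades`
#'   decades.
#' @param hyper_threshold hyperglycaemia threshold in mg/dL (default 160)
#'   for [saturate_target()].
#' @param split `"random"` row sampling (replicates the common practice for
#'   this analysis) or `"blocked"` contiguous-in-time splits; random splits
#'   of autocorrelated series inflate R, so reports should name the mode.
#' @param lambda_rule `"1se"` (default) picks the sparsest penalty whose
#'   mean cross-validated R is within one standard error of the best —
#'   the standard one-SE rule, which stabilises the selected support when
#'   the CV curve is flat; `"max"` picks the literal argmax.
#' @param seed master seed for split, folds, shuffles and bootstrap draws.
#' @export
decoder_config <- function(test_fraction = 0.20, cv_folds = 5L,
                           n_lambda = 50L, lambda_decades = 4,
                           hyper_threshold = 160,
                           split = c("random", "blocked"),
                           lambda_rule = c("1se", "max"), seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1) stop("test_fraction in (0,1)")
  list(test_fraction = test_fraction, cv_folds = as.integer(cv_folds),
       n_lambda = as.integer(n_lambda), lambda_decades = lambda_decades,
       hyper_threshold = hyper_threshold, split = match.arg(split),
       lambda_rule = match.arg(lambda_rule), seed = as.integer(seed))
}

#' Feature table container
#'
#' @param X rows x columns numeric matrix (time points x channel-band
#'   features).
#' @param y target vector (glucose level or derivative), same rows.
#' @param time row timestamps.
#' @param col_meta data.frame with `channel` and `band` per column.
#' @param masks optional named list of per-row logical state masks.
#' @export
feature_table <- function(X, y, time, col_meta, masks = NULL) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("X rows and target length differ")
  if (nrow(col_meta) != ncol(X)) stop("col_meta rows must match X columns")
  colnames(X) <- paste(col_meta$channel, col_meta$band, sep = ".")
  structure(list(X = X, y = as.numeric(y), time = time,
                 col_meta = col_meta, masks = masks),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d rows x %d columns\n", nrow(x$X), ncol(x$X)))
  invisible(x)
}

#' Build the flattened spectro-spatial feature table
#'
#' Flattens the channels x bands x time envelope array of an aligned pair
#' into a rows-by-(bands x channels) matrix restricted to gray-matter
#' channels, pairs each feature row at time `t` with the target at
#' `t - shift_h` (negative shift = features precede the target, i.e.
#' proactive decoding), and drops rows with any missing entry.
#'
#' @param aligned an [align_series()] result.
#' @param target `"level"` (glucose) or `"derivative"` (backward difference,
#'   mg/dL/min).
#' @param shift_h temporal shift in hours (negative = neural leads).
#' @param min_rows minimum usable rows (default 200).
#' @return a [feature_table()].
#' @export
build_features <- function(aligned, target = c("level", "derivative"),
                           shift_h = 0, min_rows = 200L) {
  target <- match.arg(target)
  gray <- aligned$channels$tissue == "gray"
  feats <- aligned$features[gray, , , drop = FALSE]
  nc <- dim(feats)[1L]; nb <- dim(feats)[2L]; nt <- dim(feats)[3L]
  X <- matrix(NA_real_, nrow = nt, ncol = nc * nb)
  meta <- data.frame(channel = character(nc * nb), band = character(nc * nb),
                     stringsAsFactors = FALSE)
  k <- 0L
  for (ch in seq_len(nc)) for (b in seq_len(nb)) {
    k <- k + 1L
    X[, k] <- feats[ch, b, ]
    meta$channel[k] <- aligned$channels$name[gray][ch]
    meta$band[k] <- aligned$bands[b]
  }
  y_full <- aligned$glucose
  if (target == "derivative") {
    step_min <- aligned$dt_s / 60
    y_full <- c(NA_real_, diff(aligned$glucose) / step_min)
  }
  shift_steps <- as.integer(round(shift_h * 3600 / aligned$dt_s))
  rows <- seq_len(nt)
  tgt <- rows - shift_steps
  ok <- tgt >= 1L & tgt <= nt
  rows <- rows[ok]; tgt <- tgt[ok]
  keep <- stats::complete.cases(X[rows, , drop = FALSE]) & is.finite(y_full[tgt])
  rows <- rows[keep]; tgt <- tgt[keep]
  if (length(rows) < min_rows)
    stop("fewer than ", min_rows, " usable rows after masking")
  masks <- lapply(aligned$masks, function(m) m[tgt])   # states at target times
  feature_table(X = X[rows, , drop = FALSE], y = y_full[tgt],
                time = aligned$time[tgt], col_meta = meta, masks = masks)
}

#' Saturate a glucose target at the hyperglycaemia threshold
#'
#' Values at or above the threshold are clipped to it (the decoder is asked
#' to identify hyperglycaemic periods rather than resolve their exact
#' level); a parallel boolean hyperglycaemia flag is retained.
#'
#' @param y glucose values (mg/dL).
#' @param threshold saturation threshold (default 160 mg/dL).
#' @return list with `values` (clipped) and `hyper` (logical flags).
#' @export
saturate_target <- function(y, threshold = 160) {
  if (threshold <= 0) stop("threshold must be positive")
  list(values = pmin(y, threshold), hyper = !is.na(y) & y >= threshold)
}

safe_r <- function(a, b) {
  if (length(a) < 2L || stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  pearson_r(a, b)
}

split_rows <- function(n, cfg) {
  n_test <- max(1L, round(cfg$test_fraction * n))
  if (cfg$split == "random") {
    test <- sort(sample.int(n, n_test))
  } else {
    s0 <- sample.int(n - n_test + 1L, 1L)
    test <- s0:(s0 + n_test - 1L)
  }
  train <- setdiff(seq_len(n), test)
  fold_id <- if (cfg$split == "random") {
    sample(rep_len(seq_len(cfg$cv_folds), length(train)))
  } else {
    as.integer(cut(seq_along(train), cfg$cv_folds, labels = FALSE))
  }
  list(train = train, test = test, fold_id = fold_id)
}

standardize_train <- function(X, train) {
  mu <- colMeans(X[train, , drop = FALSE])
  sd_ <- apply(X[train, , drop = FALSE], 2L, stats::sd)
  sd_[sd_ == 0 | !is.finite(sd_)] <- 1
  Xs <- sweep(sweep(X, 2L, mu, "-"), 2L, sd_, "/")
  list(X = Xs, mu = mu, sd = sd_)
}

lambda_path <- function(Xs, y, cfg) {
  lmax <- max(abs(crossprod(Xs, y - mean(y)))) / length(y)
  if (lmax <= 0) lmax <- 1e-3
  logspace(lmax * 1.001, lmax * 10^(-cfg$lambda_decades), cfg$n_lambda)
}

#' Fit the sparse spectro-spatial glucose decoder
#'
#' Rows are split into training and held-out test sets; features are
#' standardised with training-set statistics only; for each penalty on a
#' log-spaced grid, k-fold cross-validation on the training rows scores the
#' mean Pearson R between actual and predicted target, the penalty with the
#' highest mean R is chosen (exact ties resolved toward the sparser model),
#' the model is refit on the full training set and evaluated on the test
#' rows.
#'
#' @param ft a [feature_table()].
#' @param cfg a [decoder_config()].
#' @return an object of class `decoder_result`: chosen `lambda`, the CV
#'   curve, nonzero coefficients with column metadata, per-fold R at the
#'   chosen penalty, test-set `test_r` and `test_rmse`, and a predictions
#'   data.frame.
#' @export
fit_lasso_lar <- function(ft, cfg = decoder_config()) {
  y <- ft$y
  if (stats::sd(y) == 0) stop("degenerate (constant) target")
  set.seed(cfg$seed)
  n <- nrow(ft$X)
  sp <- split_rows(n, cfg)
  st <- standardize_train(ft$X, sp$train)
  Xs <- st$X
  lambdas <- lambda_path(Xs[sp$train, , drop = FALSE], y[sp$train], cfg)
  fold_r <- matrix(NA_real_, nrow = cfg$cv_folds, ncol = length(lambdas))
  for (f in seq_len(cfg$cv_folds)) {
    tr <- sp$train[sp$fold_id != f]
    ho <- sp$train[sp$fold_id == f]
    fit <- glmnet::glmnet(Xs[tr, , drop = FALSE], y[tr], family = "gaussian",
                          lambda = lambdas, standardize = FALSE)
    pred <- stats::predict(fit, newx = Xs[ho, , drop = FALSE])
    fold_r[f, seq_len(ncol(pred))] <-
      vapply(seq_len(ncol(pred)), function(j) safe_r(pred[, j], y[ho]),
             numeric(1))
  }
  cv_mean <- colMeans(fold_r)
  cv_se <- apply(fold_r, 2L, stats::sd) / sqrt(cfg$cv_folds)
  i_max <- which.max(cv_mean)
  thr <- if ((cfg$lambda_rule %||% "1se") == "1se")
    cv_mean[i_max] - cv_se[i_max] else cv_mean[i_max] - 1e-10
  best <- which(cv_mean >= thr)[1L]       # grid is decreasing: sparsest first
  lambda <- lambdas[best]
  fit <- glmnet::glmnet(Xs[sp$train, , drop = FALSE], y[sp$train],
                        family = "gaussian", lambda = lambdas,
                        standardize = FALSE)
  beta <- as.numeric(stats::coef(fit, s = lambda))[-1L]
  intercept <- as.numeric(stats::coef(fit, s = lambda))[1L]
  pred_test <- as.numeric(stats::predict(fit, newx = Xs[sp$test, , drop = FALSE],
                                         s = lambda))
  nz <- which(abs(beta) > 0)
  structure(list(lambda = lambda, lambda_grid = lambdas,
                 cv_mean_r = cv_mean, cv_fold_r = fold_r,
                 fold_r = fold_r[, best],
                 coef = stats::setNames(beta, colnames(ft$X)),
                 intercept = intercept,
                 nonzero = cbind(ft$col_meta[nz, , drop = FALSE],
                                 coef = beta[nz]),
                 test_r = safe_r(pred_test, y[sp$test]),
                 test_rmse = sqrt(mean((pred_test - y[sp$test])^2)),
                 predictions = data.frame(row = sp$test,
                                          actual = y[sp$test],
                                          predicted = pred_test),
                 split = sp, standardization = list(mu = st$mu, sd = st$sd),
                 cfg = cfg),
            class = "decoder_result")
}

#' @export
print.decoder_result <- function(x, ...) {
  cat(sprintf("<decoder_result> lambda = %.4g, %d nonzero of %d features, test R = %.3f (RMSE %.2f)\n",
              x$lambda, nrow(x$nonzero), length(x$coef), x$test_r, x$test_rmse))
  invisible(x)
}

#' Temporal shift sweep of decoder performance
#'
#' Refits the full decoding pipeline at each temporal shift (negative =
#' neural features lead, i.e. proactive decoding) and reports the mean
#' cross-validated R with its SEM per shift plus the argmax shift (flagged
#' when it sits on the sweep boundary).  Because fold-assignment noise on
#' autocorrelated series is comparable to the shift effect itself, the CV
#' is repeated over `n_repeats` split draws whose seeds are shared across
#' shifts, so shifts are compared on a paired resampling plan.
#'
#' @param aligned an [align_series()] result.
#' @param cfg a [decoder_config()].
#' @param shifts_h shifts to evaluate (hours).
#' @param target forwarded to [build_features()].
#' @param n_repeats repeated-CV draws per shift (default 8).
#' @return an object of class `shift_sweep`: data.frame `sweep` with
#'   `shift_h`, `mean_r`, `sem_r`, plus `best_shift_h` and `boundary`.
#' @export
shift_sweep <- function(aligned, cfg = decoder_config(),
                        shifts_h = seq(-6, 6, by = 0.5),
                        target = "level", n_repeats = 8L) {
  rep_seeds <- vapply(seq_len(n_repeats), function(r)
    child_seed(cfg$seed, paste0("rep", r)), integer(1))
  res <- lapply(seq_along(shifts_h), function(i) {
    ft <- try(build_features(aligned, target, shift_h = shifts_h[i]),
              silent = TRUE)
    if (inherits(ft, "try-error")) return(c(NA_real_, NA_real_))
    fr <- unlist(lapply(rep_seeds, function(s) {
      cfg_i <- cfg; cfg_i$seed <- s
      fit_lasso_lar(ft, cfg_i)$fold_r
    }))
    c(mean(fr), stats::sd(fr) / sqrt(length(fr)))
  })
  m <- do.call(rbind, res)
  sweep_df <- data.frame(shift_h = shifts_h, mean_r = m[, 1L], sem_r = m[, 2L])
  best <- which.max(sweep_df$mean_r)
  structure(list(sweep = sweep_df, best_shift_h = shifts_h[best],
                 boundary = best == 1L || best == length(shifts_h)),
            class = "shift_sweep")
}

## time-of-day mean predictor: average target in 5-min-of-day bins over the
## reference rows, evaluated at arbitrary rows
tod_mean_predictor <- function(time, y, ref_rows, dt_s) {
  tod <- as.integer(round(as.numeric(time) %% 86400 / dt_s))
  means <- tapply(y[ref_rows], tod[ref_rows], mean)
  out <- unname(means[as.character(tod)])
  out[is.na(out)] <- mean(y[ref_rows])
  out
}

## leave-one-day-out time-of-day profile: each point is predicted from the
## same-time-of-day mean of the OTHER days, so its own noise never enters
## its prediction
tod_mean_predictor_lodo <- function(time, y, dt_s) {
  tnum <- as.numeric(time)
  tod <- as.integer(round(tnum %% 86400 / dt_s))
  key <- as.character(tod)
  sums <- tapply(y, key, sum); cnts <- tapply(y, key, length)
  out <- (unname(sums[key]) - y) / pmax(unname(cnts[key]) - 1L, 1L)
  lone <- unname(cnts[key]) <= 1L
  out[lone] <- mean(y)
  out
}

#' Circadian-dependency controls for the decoder
#'
#' Quantifies how much of decoder performance is attributable to circadian
#' structure alone: (i) the full model; (ii) a negative control decoding
#' glucose shuffled in 1-h blocks; (iii) a circadian control predicting
#' measured glucose from the time-of-day mean alone; (iv) the full model
#' decoding the circadian component of glucose; (v) the full model decoding
#' the deviation of glucose from its time-of-day mean.  Per-fold Pearson R
#' values are compared across conditions by two-sample t-tests.
#'
#' @param aligned an [align_series()] result covering at least 3 full days.
#' @param cfg a [decoder_config()].
#' @param shift_h temporal shift applied to all conditions.
#' @param rhythm_cfg a [rhythm_config()] for the circadian decomposition.
#' @return list with `table` (condition, mean_r, sem_r), `fold_r` (matrix),
#'   and `tests` (p-values of full vs each control).
#' @export
circadian_controls <- function(aligned, cfg = decoder_config(), shift_h = 0,
                               rhythm_cfg = rhythm_config()) {
  span_d <- as.numeric(max(aligned$time) - min(aligned$time), units = "days")
  if (span_d < 3) stop("circadian controls need at least 3 full days of data")
  ft <- build_features(aligned, "level", shift_h = shift_h)
  n <- nrow(ft$X)
  if (any(!is.finite(aligned$glucose)))
    stop("circadian controls require a gap-free glucose series")
  dcmp <- decompose_bands(aligned$glucose, aligned$dt_s / 3600,
                          rhythm_cfg$decomp_split_h)
  idx <- match(as.numeric(ft$time), as.numeric(aligned$time))
  circ_target <- dcmp$circadian[idx] + mean(aligned$glucose)
  dev_target <- ft$y - tod_mean_predictor(ft$time, ft$y, seq_len(n), aligned$dt_s)

  set.seed(child_seed(cfg$seed, "shuffle"))
  blocks <- make_blocks(n, max(1L, as.integer(round(3600 / aligned$dt_s))))
  y_shuf <- ft$y[unlist(blocks[sample.int(length(blocks))], use.names = FALSE)]

  fit_cond <- function(yv, tag) {
    ft2 <- ft; ft2$y <- yv
    cfg2 <- cfg; cfg2$seed <- cfg$seed          # identical split across conditions
    fit_lasso_lar(ft2, cfg2)
  }
  full <- fit_cond(ft$y, "full")
  shuf <- fit_cond(y_shuf, "shuffled")
  circ <- fit_cond(circ_target, "circadian_component")
  devi <- fit_cond(dev_target, "ultradian_deviation")

  ## time-of-day control, evaluated on the same folds as the full model.
  ## The profile is descriptive (an average over the series, not a fitted
  ## model), but each point is predicted from the other days' same-time
  ## bins so its own noise never enters its prediction.
  sp <- full$split
  tod_pred <- tod_mean_predictor_lodo(ft$time, ft$y, aligned$dt_s)
  tod_r <- vapply(seq_len(cfg$cv_folds), function(f) {
    ho <- sp$train[sp$fold_id == f]
    safe_r(tod_pred[ho], ft$y[ho])
  }, numeric(1))

  fold_r <- rbind(full = full$fold_r, shuffled = shuf$fold_r,
                  tod_circadian = tod_r,
                  circadian_component = circ$fold_r,
                  ultradian_deviation = devi$fold_r)
  tab <- data.frame(condition = rownames(fold_r),
                    mean_r = rowMeans(fold_r),
                    sem_r = apply(fold_r, 1L, stats::sd) / sqrt(ncol(fold_r)))
  tt <- function(a, b) {
    if (stats::sd(a) == 0 && stats::sd(b) == 0) return(NA_real_)
    stats::t.test(a, b, var.equal = TRUE)$p.value
  }
  tests <- list(full_vs_shuffled = tt(fold_r["full", ], fold_r["shuffled", ]),
                full_vs_tod = tt(fold_r["full", ], fold_r["tod_circadian", ]),
                full_vs_circadian_component = tt(fold_r["full", ],
                                                 fold_r["circadian_component", ]),
                full_vs_ultradian_deviation = tt(fold_r["full", ],
                                                 fold_r["ultradian_deviation", ]))
  list(table = tab, fold_r = fold_r, tests = tests, fits = list(full = full))
}

#' State-stratified decoder RMSE
#'
#' RMSE of the held-out test predictions per behavioural state, with the
#' percent difference relative to the all-test-rows RMSE.  States with
#' fewer than `min_rows` test rows are reported as `NA`.
#'
#' @param result a [fit_lasso_lar()] result.
#' @param ft the [feature_table()] the result was fit on (carries the
#'   per-row state masks).
#' @param min_rows minimum test rows per state (default 30).
#' @return data.frame with `state`, `n`, `rmse`, `pct_diff`.
#' @export
stratified_rmse <- function(result, ft, min_rows = 30L) {
  if (is.null(ft$masks)) stop("feature table carries no state masks")
  rows <- result$predictions$row
  err <- result$predictions$predicted - result$predictions$actual
  overall <- sqrt(mean(err^2))
  out <- do.call(rbind, lapply(names(ft$masks), function(nm) {
    sel <- ft$masks[[nm]][rows]
    if (sum(sel) < min_rows)
      return(data.frame(state = nm, n = sum(sel), rmse = NA_real_,
                        pct_diff = NA_real_))
    r <- sqrt(mean(err[sel]^2))
    data.frame(state = nm, n = sum(sel), rmse = r,
               pct_diff = 100 * (r - overall) / overall)
  }))
  attr(out, "overall_rmse") <- overall
  out
}

#' Bootstrap channel-importance analysis
#'
#' Rows are resampled with replacement (same size) `n_trials` times; the
#' decoder is refit at the penalty chosen on the original split, and the
#' selected columns are recorded.  A column is flagged significant when it
#' is selected in at least 99% of trials; the median coefficient counts
#' trials in which the column was not selected as zero.
#'
#' @param ft a [feature_table()].
#' @param cfg a [decoder_config()].
#' @param n_trials bootstrap trials (default 1000).
#' @param lambda fixed penalty; defaults to the penalty chosen by a
#'   reference [fit_lasso_lar()] run.
#' @param freq_threshold selection frequency needed for significance.
#' @return an `importance_table` data.frame (channel, band, frequency,
#'   median_coef, significant) with a per-channel roll-up in
#'   `attr(, "channel_table")`.
#' @export
bootstrap_importance <- function(ft, cfg = decoder_config(), n_trials = 1000L,
                                 lambda = NULL, freq_threshold = 0.99) {
  if (is.null(lambda)) lambda <- fit_lasso_lar(ft, cfg)$lambda
  set.seed(child_seed(cfg$seed, "bootstrap"))
  n <- nrow(ft$X); p <- ncol(ft$X)
  sel_count <- numeric(p)
  coefs <- matrix(0, nrow = n_trials, ncol = p)
  lam_seq <- sort(unique(c(lambda * c(8, 4, 2), lambda)), decreasing = TRUE)
  for (i in seq_len(n_trials)) {
    idx <- sample.int(n, n, replace = TRUE)
    st <- standardize_train(ft$X[idx, , drop = FALSE], seq_along(idx))
    fit <- glmnet::glmnet(st$X, ft$y[idx], family = "gaussian",
                          lambda = lam_seq, standardize = FALSE)
    b <- as.numeric(stats::coef(fit, s = lambda, exact = FALSE))[-1L]
    nz <- abs(b) > 0
    sel_count[nz] <- sel_count[nz] + 1
    coefs[i, ] <- b
  }
  freq <- sel_count / n_trials
  out <- data.frame(ft$col_meta,
                    frequency = freq,
                    median_coef = apply(coefs, 2L, stats::median),
                    significant = freq >= freq_threshold)
  ch_tab <- stats::aggregate(significant ~ channel, data = out, FUN = any)
  attr(out, "channel_table") <- ch_tab
  class(out) <- c("importance_table", class(out))
  out
}
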