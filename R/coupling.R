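## coupling_analysis: lag-resolved Pearson correlation between a neural
## feature series and glucose (or its derivative), with a 30-min
## block-permutation null and behavioural-state stratification.
##
## Lag convention (used consistently across the package): r(l) is the
## Pearson correlation of x(t + l) with y(t), so a NEGATIVE best lag means
## the neural series x leads the glucose series y.

#' Coupling analysis configuration
#'
#' @param max_lag_h lag window half-width in hours (default 12).
#' @param shuffle_segment_min permutation block length in minutes (default
#'   30): long enough to preserve local temporal structure, short enough to
#'   give many blocks to permute.
#' @param n_permutations permutation iterations (default 1000).
#' @param alpha significance level (default 0.05).
#' @param min_overlap minimum overlapping samples for a lag to be defined.
#' @param min_blocks minimum number of permutation blocks.
#' @export
coupling_config <- function(max_lag_h = 12, shuffle_segment_min = 30,
                            n_permutations = 1000L, alpha = 0.05,
                            min_overlap = 100L, min_blocks = 10L) {
  if (max_lag_h <= 0) stop("max_lag_h must be positive")
  if (n_permutations < 100L) stop("n_permutations must be at least 100")
  list(max_lag_h = max_lag_h, shuffle_segment_min = shuffle_segment_min,
       n_permutations = as.integer(n_permutations), alpha = alpha,
       min_overlap = as.integer(min_overlap), min_blocks = as.integer(min_blocks))
}

lag_slices <- function(n, lag) {
  if (lag >= 0L) list(ix = (1L + lag):n, iy = 1L:(n - lag))
  else list(ix = 1L:(n + lag), iy = (1L - lag):n)
}

#' Lag-resolved cross-correlogram
#'
#' Pearson correlation of `x(t + l)` with `y(t)` for every integer-step lag
#' `l` in `[-max_lag, +max_lag]`; masked (`NA`) samples are excluded
#' pairwise, and lags with fewer than `min_overlap` overlapping finite pairs
#' are undefined.
#'
#' @param x,y numeric series on a common uniform grid.
#' @param max_lag maximum lag in grid steps.
#' @param dt_h grid step in hours (optional; adds `lag_h` to the result).
#' @param min_overlap minimum overlap per lag.
#' @return an object of class `cross_correlogram` with `lags` (steps),
#'   `r`, `n` and optionally `lag_h`.
#' @export
cross_correlogram <- function(x, y, max_lag, dt_h = NULL, min_overlap = 100L) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  fx <- is.finite(x); fy <- is.finite(y)
  if (stats::var(x[fx]) == 0 || stats::var(y[fy]) == 0)
    stop("correlation undefined for constant input")
  max_lag <- as.integer(max_lag)
  if (max_lag >= n) stop("max_lag must be smaller than the series length")
  lags <- (-max_lag):max_lag
  r <- rep(NA_real_, length(lags)); nn <- integer(length(lags))
  any_na <- !all(fx) || !all(fy)
  for (k in seq_along(lags)) {
    s <- lag_slices(n, lags[k])
    xs <- x[s$ix]; ys <- y[s$iy]
    if (any_na) {
      ok <- is.finite(xs) & is.finite(ys)
      xs <- xs[ok]; ys <- ys[ok]
    }
    nn[k] <- length(xs)
    if (nn[k] >= min_overlap) r[k] <- pearson_r(xs, ys)
  }
  out <- list(lags = lags, r = r, n = nn)
  if (!is.null(dt_h)) out$lag_h <- lags * dt_h
  structure(out, class = "cross_correlogram")
}

#' Best lag under the rectified criterion
#'
#' The lag maximising `|r|` (the rectified cross-correlation criterion),
#' with ties broken toward smaller `|lag|` (and the negative lag first on an
#' exact +/- tie); the signed Pearson correlation at that lag is returned.
#' A flat correlogram therefore yields lag 0.
#'
#' @param cc a [cross_correlogram()].
#' @return list with `lag` (grid steps), `lag_h` (hours, if available) and
#'   `r` (signed correlation at the best lag).
#' @export
best_lag_correlation <- function(cc) {
  if (all(is.na(cc$r))) stop("no defined lag in the correlogram")
  a <- abs(cc$r)
  mx <- max(a, na.rm = TRUE)
  cand <- which(!is.na(a) & a >= mx - 1e-15)
  best <- cand[order(abs(cc$lags[cand]), cc$lags[cand])][1L]
  list(lag = cc$lags[best],
       lag_h = if (!is.null(cc$lag_h)) cc$lag_h[best] else NULL,
       r = cc$r[best])
}

## contiguous permutation blocks; remainder appended to the last block
make_blocks <- function(n, block_len) {
  nb <- n %/% block_len
  idx <- vector("list", nb)
  for (b in seq_len(nb)) idx[[b]] <- ((b - 1L) * block_len + 1L):(b * block_len)
  if (n %% block_len) idx[[nb]] <- c(idx[[nb]], (nb * block_len + 1L):n)
  idx
}

#' Block-permutation null for the cross-correlogram
#'
#' `y` is partitioned into contiguous blocks of `shuffle_segment_min`
#' minutes, the block order is permuted uniformly (identity permutation
#' excluded), and the correlogram is recomputed per iteration.  The null
#' band is the pointwise 2.5/97.5 percentile envelope; the p-value of the
#' observed best-lag correlation uses the max-|r|-across-lags statistic of
#' each permutation, which corrects for the lag search.
#'
#' @param x,y numeric series on a common grid.
#' @param cfg a [coupling_config()].
#' @param dt_s grid step in seconds.
#' @param seed RNG seed (optional).
#' @return list with `null_band` (data.frame: lag, lo, hi), `null_max`
#'   (per-permutation max |r|), `obs_max`, `p` and `significant`.
#' @export
permutation_null <- function(x, y, cfg = coupling_config(), dt_s = 300,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  block_len <- max(1L, as.integer(round(cfg$shuffle_segment_min * 60 / dt_s)))
  blocks <- make_blocks(n, block_len)
  nb <- length(blocks)
  if (nb < cfg$min_blocks)
    stop("need at least ", cfg$min_blocks, " permutation blocks, have ", nb)
  max_lag <- as.integer(round(cfg$max_lag_h * 3600 / dt_s))
  dt_h <- dt_s / 3600
  obs <- cross_correlogram(x, y, max_lag, dt_h = dt_h,
                           min_overlap = cfg$min_overlap)
  obs_max <- max(abs(obs$r), na.rm = TRUE)
  P <- cfg$n_permutations

  perms <- vapply(seq_len(P), function(i) {
    repeat {
      p <- sample.int(nb)
      if (!all(p == seq_len(nb))) return(p)
    }
  }, integer(nb))
  Y <- vapply(seq_len(P), function(i) y[unlist(blocks[perms[, i]], use.names = FALSE)],
              numeric(n))

  lags <- (-max_lag):max_lag
  R <- matrix(NA_real_, nrow = length(lags), ncol = P)
  if (all(is.finite(x)) && all(is.finite(y))) {
    cx <- cumsum(x); cx2 <- cumsum(x^2)
    cY <- apply(Y, 2L, cumsum); cY2 <- apply(Y^2, 2L, cumsum)
    rsum <- function(cs, a, b) cs[b] - (if (a > 1L) cs[a - 1L] else 0)
    csum <- function(cm, a, b) cm[b, ] - (if (a > 1L) cm[a - 1L, ] else 0)
    for (k in seq_along(lags)) {
      s <- lag_slices(n, lags[k])
      m <- length(s$ix)
      if (m < cfg$min_overlap) next
      sx <- rsum(cx, s$ix[1L], s$ix[m]); sxx <- rsum(cx2, s$ix[1L], s$ix[m])
      sy <- csum(cY, s$iy[1L], s$iy[m]); syy <- csum(cY2, s$iy[1L], s$iy[m])
      sxy <- as.numeric(crossprod(x[s$ix], Y[s$iy, , drop = FALSE]))
      den <- sqrt(pmax(m * sxx - sx^2, 0) * pmax(m * syy - sy^2, 0))
      R[k, ] <- ifelse(den > 0, (m * sxy - sx * sy) / den, NA_real_)
    }
  } else {
    for (i in seq_len(P)) {
      cc <- cross_correlogram(x, Y[, i], max_lag, min_overlap = cfg$min_overlap)
      R[, i] <- cc$r
    }
  }
  null_max <- apply(abs(R), 2L, max, na.rm = TRUE)
  qs <- apply(R, 1L, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE,
              names = FALSE)
  p <- (1 + sum(null_max >= obs_max)) / (P + 1)
  list(null_band = data.frame(lag = lags, lag_h = lags * dt_h,
                              lo = qs[1L, ], hi = qs[2L, ]),
       null_max = null_max, obs_max = obs_max, p = p,
       significant = p <= cfg$alpha)
}

#' State-stratified lag-corrected correlation
#'
#' The neural series is shifted by the supplied best lag and the Pearson
#' correlation is recomputed over the samples where each state mask
#' (evaluated at the glucose timestamp) is true.  States with fewer than
#' `min_n` overlapping samples are reported as `NA` with a warning.
#'
#' @param x,y numeric series on a common grid.
#' @param lag best lag in grid steps (as from [best_lag_correlation()]).
#' @param masks named list of logical vectors on the grid.
#' @param min_n minimum samples per state (default 50).
#' @return named numeric vector of per-state correlations.
#' @export
stratified_correlation <- function(x, y, lag, masks, min_n = 50L) {
  n <- length(x)
  s <- lag_slices(n, as.integer(lag))
  out <- stats::setNames(rep(NA_real_, length(masks)), names(masks))
  for (nm in names(masks)) {
    sel <- masks[[nm]][s$iy]
    xs <- x[s$ix][sel]; ys <- y[s$iy][sel]
    ok <- is.finite(xs) & is.finite(ys)
    if (sum(ok) < min_n) {
      warning("state ", nm, " has fewer than ", min_n, " samples; undefined")
      next
    }
    out[nm] <- pearson_r(xs[ok], ys[ok])
  }
  out
}

#' Full coupling analysis of one feature series against glucose
#'
#' Convenience wrapper: cross-correlogram over `+/- max_lag_h`, rectified
#' best lag, block-permutation null (optional) and state stratification.
#' Applies identically to glucose level and glucose-derivative targets.
#'
#' @param x neural feature series.
#' @param y target series (glucose level or derivative) on the same grid.
#' @param dt_s grid step in seconds.
#' @param cfg a [coupling_config()].
#' @param masks optional named list of state masks.
#' @param n_permutations permutation count (0 skips the null; defaults to
#'   `cfg$n_permutations`).
#' @param seed RNG seed for the permutation null.
#' @param lag optional fixed lag in grid steps: skips the rectified best-lag
#'   search and evaluates the correlation at this lag instead (used when a
#'   lag estimated from the full signals is held fixed for component-wise
#'   analyses).
#' @return an object of class `coupling_result`.
#' @export
couple <- function(x, y, dt_s = 300, cfg = coupling_config(), masks = NULL,
                   n_permutations = cfg$n_permutations, seed = NULL,
                   lag = NULL) {
  max_lag <- as.integer(round(cfg$max_lag_h * 3600 / dt_s))
  cc <- cross_correlogram(x, y, max_lag, dt_h = dt_s / 3600,
                          min_overlap = cfg$min_overlap)
  best <- if (is.null(lag)) best_lag_correlation(cc) else {
    k <- match(as.integer(lag), cc$lags)
    if (is.na(k)) stop("fixed lag outside the correlogram window")
    list(lag = cc$lags[k], lag_h = cc$lag_h[k], r = cc$r[k])
  }
  null <- NULL
  if (n_permutations > 0L) {
    cfg2 <- cfg; cfg2$n_permutations <- as.integer(n_permutations)
    null <- permutation_null(x, y, cfg2, dt_s = dt_s, seed = seed)
  }
  strat <- if (!is.null(masks))
    suppressWarnings(stratified_correlation(x, y, best$lag, masks)) else NULL
  structure(list(correlogram = cc, best_lag = best$lag,
                 best_lag_h = best$lag_h, r_at_best = best$r,
                 null = null, state_r = strat, dt_s = dt_s),
            class = "coupling_result")
}

#' @export
print.coupling_result <- function(x, ...) {
  cat(sprintf("<coupling_result> best lag %.2f h, r = %.3f%s\n",
              x$best_lag_h, x$r_at_best,
              if (!is.null(x$null)) sprintf(" (p = %.4g)", x$null$p) else ""))
  invisible(x)
}

#' Region-level summary of per-channel coupling results
#'
#' Mean and SEM of the lag-corrected correlation per region and state, a
#' paired sleep-vs-wake t-test per region, and a one-way ANOVA of the
#' lag-corrected correlation across regions.  With a single region the
#' ANOVA is skipped with a note.
#'
#' @param tbl data.frame with columns `channel`, `region`, `r_best`,
#'   `r_sleep`, `r_wake`.
#' @return list with `region_table`, `paired_tests`, `anova` (or `NULL`)
#'   and `note`.
#' @export
regional_summary <- function(tbl) {
  stopifnot(all(c("channel", "region", "r_best", "r_sleep", "r_wake") %in% names(tbl)))
  regs <- unique(tbl$region)
  sem <- function(v) if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else 0
  rt <- do.call(rbind, lapply(regs, function(rg) {
    d <- tbl[tbl$region == rg, ]
    data.frame(region = rg,
               state = c("all", "sleep", "wake"),
               mean_r = c(mean(d$r_best), mean(d$r_sleep, na.rm = TRUE),
                          mean(d$r_wake, na.rm = TRUE)),
               sem_r = c(sem(d$r_best), sem(d$r_sleep[is.finite(d$r_sleep)]),
                         sem(d$r_wake[is.finite(d$r_wake)])),
               n = nrow(d))
  }))
  paired <- do.call(rbind, lapply(regs, function(rg) {
    d <- tbl[tbl$region == rg, ]
    ok <- is.finite(d$r_sleep) & is.finite(d$r_wake)
    if (sum(ok) < 2L || stats::sd(d$r_sleep[ok] - d$r_wake[ok]) == 0)
      return(data.frame(region = rg, t = NA_real_, df = NA_real_, p = NA_real_))
    tt <- stats::t.test(d$r_sleep[ok], d$r_wake[ok], paired = TRUE)
    data.frame(region = rg, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value)
  }))
  note <- NULL; an <- NULL
  if (length(regs) < 2L) {
    note <- "single region: across-region ANOVA skipped"
  } else if (stats::sd(tbl$r_best) < 1e-12) {
    ## exactly constant correlations: no between-region effect
    an <- list(F = 0, df1 = length(regs) - 1L, df2 = nrow(tbl) - length(regs),
               p = 1)
  } else {
    fit <- stats::aov(r_best ~ region, data = tbl)
    s <- summary(fit)[[1L]]
    an <- list(F = s[["F value"]][1L], df1 = s[["Df"]][1L],
               df2 = s[["Df"]][2L], p = s[["Pr(>F)"]][1L])
  }
  list(region_table = rt, paired_tests = paired, anova = an, note = note)
}
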