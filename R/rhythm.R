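## rhythm_analysis: Morlet wavelet coherence between neural features and
## glucose, circadian-band coherence and phase lag, circadian/ultradian
## decomposition, and the phase-lag vs temporal-lag relation.
##
## The continuous wavelet transform, the time/scale smoothing that makes
## wavelet coherence non-degenerate, the cone of influence and the inverse
## band reconstruction are implemented here directly (no suitable installed
## package provides them), following the standard Morlet conventions
## (omega0 = 6, Fourier period = 4*pi*s / (omega0 + sqrt(2 + omega0^2))).

#' Rhythm analysis configuration
#'
#' @param period_range_h analysed period span in hours (default 0.5-48).
#' @param voices voices per octave of the log-spaced period grid (>= 12).
#' @param circadian_band_h circadian band for coherence averaging; the
#'   default 16-32 h is 24 h +/- 33%; a narrow 20-28 h variant is common.
#' @param decomp_split_h circadian band for signal decomposition
#'   (default 18-36 h; everything below 18 h is ultradian).
#' @param coi_policy `"exclude"` (default) drops the cone of influence from
#'   time-averaged summaries; `"include"` keeps it.
#' @param coherence `"msq"` (magnitude-squared, default) or `"mag"`.
#' @param omega0 Morlet centre frequency parameter.
#' @param n_permutations block-shuffle iterations for coherence significance.
#' @param alpha significance level.
#' @export
rhythm_config <- function(period_range_h = c(0.5, 48), voices = 12L,
                          circadian_band_h = c(16, 32),
                          decomp_split_h = c(18, 36),
                          coi_policy = c("exclude", "include"),
                          coherence = c("msq", "mag"),
                          omega0 = 6, n_permutations = 1000L, alpha = 0.05) {
  stopifnot(period_range_h[1L] > 0, period_range_h[2L] > period_range_h[1L],
            circadian_band_h[1L] > 0, circadian_band_h[2L] > circadian_band_h[1L])
  list(period_range_h = period_range_h, voices = as.integer(voices),
       circadian_band_h = circadian_band_h, decomp_split_h = decomp_split_h,
       coi_policy = match.arg(coi_policy), coherence = match.arg(coherence),
       omega0 = omega0, n_permutations = as.integer(n_permutations),
       alpha = alpha)
}

period_grid <- function(cfg) {
  n_oct <- log2(cfg$period_range_h[2L] / cfg$period_range_h[1L])
  n <- ceiling(n_oct * cfg$voices) + 1L
  cfg$period_range_h[1L] * 2^(seq(0, n_oct, length.out = n))
}

morlet_fourier_factor <- function(omega0) 4 * pi / (omega0 + sqrt(2 + omega0^2))

#' Morlet continuous wavelet transform
#'
#' @param x numeric series (finite).
#' @param dt_h sample step in hours.
#' @param periods_h Fourier periods to analyse (hours).
#' @param omega0 Morlet parameter (default 6).
#' @return list with `W` (periods x time complex matrix), `periods_h`,
#'   `scales_h` and `coi_h` (per-sample maximum uncontaminated period).
#' @export
cwt_morlet <- function(x, dt_h, periods_h, omega0 = 6) {
  n <- length(x)
  if (any(!is.finite(x))) stop("cwt_morlet requires a finite series")
  nf <- stats::nextn(n, c(2L, 3L, 5L))
  xf <- stats::fft(c(x - mean(x), rep(0, nf - n)))
  omega <- 2 * pi * c(0:(nf %/% 2L), -((nf - nf %/% 2L - 1L):1L)) / (nf * dt_h)
  ff <- morlet_fourier_factor(omega0)
  scales <- periods_h / ff
  W <- matrix(0i, nrow = length(scales), ncol = n)
  pos <- omega > 0
  for (j in seq_along(scales)) {
    s <- scales[j]
    psi <- numeric(nf)
    psi[pos] <- pi^(-0.25) * sqrt(2 * pi * s / dt_h) *
      exp(-(s * omega[pos] - omega0)^2 / 2)
    wj <- stats::fft(xf * psi, inverse = TRUE) / nf
    W[j, ] <- wj[seq_len(n)]
  }
  dist_h <- pmin(seq_len(n) - 1L, n - seq_len(n)) * dt_h
  coi_h <- ff * dist_h / sqrt(2)          # periods above this are edge-affected
  list(W = W, periods_h = periods_h, scales_h = scales, coi_h = coi_h)
}

## Smooth a (scales x time) field: Gaussian in time with sd = scale, then a
## boxcar across ~0.6 octave of scales.  Operates on real or complex fields.
smooth_field <- function(F, scales_h, dt_h, voices) {
  n <- ncol(F)
  nf <- stats::nextn(n, c(2L, 3L, 5L))
  omega <- 2 * pi * c(0:(nf %/% 2L), -((nf - nf %/% 2L - 1L):1L)) / (nf * dt_h)
  out <- F
  for (j in seq_len(nrow(F))) {
    k <- exp(-(scales_h[j] * omega)^2 / 2)
    row <- c(F[j, ], rep(0, nf - n))
    sm <- stats::fft(stats::fft(row) * k, inverse = TRUE) / nf
    out[j, ] <- sm[seq_len(n)]
  }
  win <- max(1L, 2L * floor(0.3 * voices) + 1L)
  if (win > 1L && nrow(F) >= win) {
    half <- win %/% 2L
    cum <- apply(rbind(0, out), 2L, cumsum)
    for (j in seq_len(nrow(F))) {
      lo <- max(1L, j - half); hi <- min(nrow(F), j + half)
      out[j, ] <- (cum[hi + 1L, ] - cum[lo, ]) / (hi - lo + 1L)
    }
  }
  out
}

#' Wavelet coherence between two series
#'
#' Smoothed Morlet wavelet coherence with phase: the cross-spectrum and the
#' two auto-spectra (each scale-normalised) are smoothed in time (Gaussian
#' matched to scale) and across scales (boxcar over ~0.6 octave), and
#' coherence is their normalised ratio, clipped to `[0, 1]`.  The phase of
#' the smoothed cross-spectrum is positive when `x` leads `y`.
#'
#' @param x,y series on a common uniform grid (length at least 3x the
#'   longest analysed period).
#' @param dt_h grid step in hours.
#' @param cfg a [rhythm_config()].
#' @return an object of class `coherence_result`: `periods_h`, `coh`
#'   (periods x time, in `[0,1]`), `phase` (radians), `coi_h`,
#'   `periodogram` (time-averaged coherence per period, COI handled per
#'   `cfg$coi_policy`).
#' @export
wavelet_coherence <- function(x, y, dt_h, cfg = rhythm_config()) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  periods <- period_grid(cfg)
  periods <- periods[periods <= n * dt_h / 3]
  if (length(periods) < 2L)
    stop("series too short for the requested period range (need >= 3 cycles)")
  wx <- cwt_morlet(x, dt_h, periods, cfg$omega0)
  wy <- cwt_morlet(y, dt_h, periods, cfg$omega0)
  inv_s <- 1 / wx$scales_h
  Sxy <- smooth_field(wx$W * Conj(wy$W) * inv_s, wx$scales_h, dt_h, cfg$voices)
  Sxx <- Re(smooth_field(Mod(wx$W)^2 * inv_s, wx$scales_h, dt_h, cfg$voices))
  Syy <- Re(smooth_field(Mod(wy$W)^2 * inv_s, wx$scales_h, dt_h, cfg$voices))
  msq <- Mod(Sxy)^2 / pmax(Sxx * Syy, .Machine$double.eps)
  msq <- pmin(pmax(msq, 0), 1)
  coh <- if (cfg$coherence == "msq") msq else sqrt(msq)
  phase <- Arg(Sxy)
  excl <- outer(periods, wx$coi_h, ">")        # TRUE where inside the COI
  pg_coh <- coh
  if (cfg$coi_policy == "exclude") pg_coh[excl] <- NA_real_
  periodogram <- rowMeans(pg_coh, na.rm = TRUE)
  structure(list(periods_h = periods, coh = coh, phase = phase,
                 coi_h = wx$coi_h, coi_excluded = excl,
                 periodogram = periodogram, dt_h = dt_h, cfg = cfg),
            class = "coherence_result")
}

band_rows <- function(cr, band_h) {
  which(cr$periods_h >= band_h[1L] & cr$periods_h <= band_h[2L])
}

band_mean_coherence <- function(cr, band_h) {
  rows <- band_rows(cr, band_h)
  if (length(rows) == 0L) stop("circadian band outside the period grid")
  v <- cr$coh[rows, , drop = FALSE]
  if (cr$cfg$coi_policy == "exclude")
    v[cr$coi_excluded[rows, , drop = FALSE]] <- NA_real_
  mean(v, na.rm = TRUE)
}

#' Circadian coherence with block-shuffle significance
#'
#' Mean wavelet coherence over the circadian band (default 24 h +/- 33%)
#' and over time (COI excluded by default).  Significance comes from a
#' 30-min block-shuffle null: the glucose series is block-permuted and the
#' band coherence recomputed per iteration.
#'
#' @param x,y series on a common grid (`x` neural, `y` glucose).
#' @param dt_h grid step in hours.
#' @param cfg a [rhythm_config()].
#' @param band_h circadian band (defaults to `cfg$circadian_band_h`).
#' @param n_permutations iterations (0 skips significance).
#' @param block_min shuffle block length in minutes.
#' @param seed RNG seed.
#' @return list with `coherence`, `p`, `significant`, `null`.
#' @export
circadian_coherence <- function(x, y, dt_h, cfg = rhythm_config(),
                                band_h = cfg$circadian_band_h,
                                n_permutations = cfg$n_permutations,
                                block_min = 30, seed = NULL) {
  cr <- wavelet_coherence(x, y, dt_h, cfg)
  obs <- band_mean_coherence(cr, band_h)
  if (n_permutations <= 0L)
    return(list(coherence = obs, p = NA_real_, significant = NA, null = NULL))
  if (!is.null(seed)) set.seed(seed)
  ## permutations only need the band scales: restrict the grid for speed
  cfg_band <- cfg
  cfg_band$period_range_h <- band_h
  blocks <- make_blocks(length(y), max(1L, as.integer(round(block_min * 60 / (dt_h * 3600)))))
  nb <- length(blocks)
  null <- vapply(seq_len(n_permutations), function(i) {
    repeat {
      pm <- sample.int(nb)
      if (!all(pm == seq_len(nb))) break
    }
    yp <- y[unlist(blocks[pm], use.names = FALSE)]
    crp <- wavelet_coherence(x, yp, dt_h, cfg_band)
    band_mean_coherence(crp, band_h)
  }, numeric(1))
  p <- (1 + sum(null >= obs)) / (n_permutations + 1)
  list(coherence = obs, p = p, significant = p <= cfg$alpha, null = null)
}

#' Circadian phase lag in hours
#'
#' Coherence-weighted circular mean of the cross-spectral phase over the
#' circadian band (COI excluded), converted to hours via the band-centre
#' period.  Positive values mean the neural circadian component peaks
#' before the glucose circadian component (neural leads).  Offsets close to
#' half the period are flagged as wraparound-ambiguous.
#'
#' @param cr a [wavelet_coherence()] result.
#' @param band_h circadian band (defaults to the config of `cr`).
#' @param significant optional logical from [circadian_coherence()]; if
#'   `FALSE` the lag is undefined (`NA`) with a warning.
#' @return list with `lag_h`, `phase_rad`, `band_center_h`, `wrap_ambiguous`.
#' @export
circadian_phase_lag <- function(cr, band_h = cr$cfg$circadian_band_h,
                                significant = NULL) {
  if (isFALSE(significant)) {
    warning("circadian coherence not significant; phase lag undefined")
    return(list(lag_h = NA_real_, phase_rad = NA_real_,
                band_center_h = NA_real_, wrap_ambiguous = NA))
  }
  rows <- band_rows(cr, band_h)
  if (length(rows) == 0L) stop("circadian band outside the period grid")
  w <- cr$coh[rows, , drop = FALSE]
  ph <- cr$phase[rows, , drop = FALSE]
  if (cr$cfg$coi_policy == "exclude") {
    drop_ <- cr$coi_excluded[rows, , drop = FALSE]
    w[drop_] <- 0
  }
  z <- sum(w * exp(1i * ph))
  phase <- Arg(z)
  center <- sqrt(band_h[1L] * band_h[2L])
  center <- if (center >= 20 && center <= 28) 24 else center  # report on the 24-h clock
  lag_h <- phase / (2 * pi) * center
  list(lag_h = lag_h, phase_rad = phase, band_center_h = center,
       wrap_ambiguous = abs(phase) > 0.95 * pi)
}

#' Circadian / ultradian band decomposition
#'
#' Splits a series into a circadian component (periods inside
#' `split_h = c(18, 36)` hours by default), an ultradian component (periods
#' below the lower edge) and a residual (slower-than-circadian variation,
#' trend and mean).  The split is a zero-phase spectral partition of unity
#' with raised-cosine crossovers in log-frequency, so the three components
#' sum back to the input at machine precision; the series is linearly
#' detrended first and the trend assigned to the residual.
#'
#' @param x numeric series (finite).
#' @param dt_h grid step in hours.
#' @param split_h circadian band edges in hours.
#' @param transition_oct crossover half-width in octaves.
#' @return list with `circadian`, `ultradian`, `residual` (same length as
#'   `x`; their sum equals `x`).
#' @export
decompose_bands <- function(x, dt_h, split_h = c(18, 36), transition_oct = 0.3) {
  n <- length(x)
  if (any(!is.finite(x))) stop("decompose_bands requires a finite series")
  if (n * dt_h < 3 * split_h[2L])
    stop("series must span at least 3x the upper circadian edge")
  t_idx <- seq_len(n)
  fit <- stats::lm.fit(cbind(1, t_idx), x)
  trend <- as.numeric(cbind(1, t_idx) %*% fit$coefficients)
  xd <- x - trend
  xf <- stats::fft(xd)
  freq <- c(0:(n %/% 2L), -((n - n %/% 2L - 1L):1L)) / (n * dt_h)  # cycles/h
  af <- abs(freq)
  step_up <- function(f, fc) {                 # 0 below fc/2^w, 1 above fc*2^w
    out <- numeric(length(f))
    lo <- fc * 2^(-transition_oct); hi <- fc * 2^(transition_oct)
    out[f >= hi] <- 1
    mid <- f > lo & f < hi
    out[mid] <- 0.5 * (1 - cos(pi * (log2(f[mid] / lo)) / (2 * transition_oct)))
    out
  }
  s_lo <- step_up(af, 1 / split_h[2L])         # rises at the 36-h cutoff
  s_hi <- step_up(af, 1 / split_h[1L])         # rises at the 18-h cutoff
  w_circ <- s_lo * (1 - s_hi)
  w_ultra <- s_hi
  circ <- Re(stats::fft(xf * w_circ, inverse = TRUE)) / n
  ultra <- Re(stats::fft(xf * w_ultra, inverse = TRUE)) / n
  resid <- x - circ - ultra                    # includes trend + slow band
  list(circadian = circ, ultradian = ultra, residual = resid)
}

#' Coupling analysis on ultradian components
#'
#' Removes the circadian band from both series via [decompose_bands()] and
#' runs the full coupling analysis (best-lag search, permutation null,
#' state stratification) on the ultradian components.
#'
#' @param x,y series on a common grid.
#' @param dt_s grid step in seconds.
#' @param rhythm_cfg a [rhythm_config()].
#' @param coupling_cfg a [coupling_config()].
#' @param masks optional state masks.
#' @param n_permutations forwarded to [couple()].
#' @param seed RNG seed.
#' @param lag optional fixed lag in grid steps (e.g. the best lag estimated
#'   from the raw series, where it is most identifiable) to hold fixed for
#'   the ultradian analysis instead of re-searching.
#' @return a `coupling_result` for the ultradian components.
#' @export
ultradian_coupling <- function(x, y, dt_s = 300,
                               rhythm_cfg = rhythm_config(),
                               coupling_cfg = coupling_config(),
                               masks = NULL, n_permutations = 0L, seed = NULL,
                               lag = NULL) {
  dt_h <- dt_s / 3600
  xu <- decompose_bands(x, dt_h, rhythm_cfg$decomp_split_h)$ultradian
  yu <- decompose_bands(y, dt_h, rhythm_cfg$decomp_split_h)$ultradian
  couple(xu, yu, dt_s = dt_s, cfg = coupling_cfg, masks = masks,
         n_permutations = n_permutations, seed = seed, lag = lag)
}

#' Relation between circadian phase lag and correlational temporal lag
#'
#' Across channels with a defined circadian phase lag, correlates the
#' circadian phase lead with the correlational temporal lead
#' (`-best_lag_h`), both in hours with positive = neural leads, so a
#' generator that drives temporal lags from per-channel phase lags yields a
#' strongly positive R.
#'
#' @param phase_lag_h per-channel circadian phase lag (hours, positive =
#'   neural leads).
#' @param best_lag_h per-channel best temporal lag (hours, negative =
#'   neural leads).
#' @param min_channels minimum channels required (default 10).
#' @return list with `r`, `p`, `n` (Pearson), or `NA` entries with a note
#'   when undefined.
#' @export
phase_vs_temporal_lag <- function(phase_lag_h, best_lag_h, min_channels = 10L) {
  ok <- is.finite(phase_lag_h) & is.finite(best_lag_h)
  if (sum(ok) < min_channels)
    return(list(r = NA_real_, p = NA_real_, n = sum(ok),
                note = "too few channels with significant circadian coherence"))
  lead <- -best_lag_h[ok]
  if (stats::sd(phase_lag_h[ok]) == 0 || stats::sd(lead) == 0)
    return(list(r = NA_real_, p = NA_real_, n = sum(ok),
                note = "zero variance in lags"))
  ct <- stats::cor.test(phase_lag_h[ok], lead)
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok), note = NULL)
}
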