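## Small numerical helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Analytic signal via the frequency domain
#'
#' Returns the complex analytic signal of a real series (the signal plus
#' i times its Hilbert transform), so that `Mod(analytic_signal(x))` is the
#' instantaneous amplitude envelope.
#'
#' @param x numeric vector.
#' @return complex vector, same length as `x`.
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2L) return(complex(real = x, imaginary = rep(0, n)))
  ## zero-pad to a 2-3-5 smooth length for fft speed; edge error is confined
  ## to the pad boundary and edge samples are masked downstream anyway
  nf <- stats::nextn(n, c(2L, 3L, 5L))
  xf <- stats::fft(c(x, rep(0, nf - n)))
  h <- numeric(nf)
  h[1L] <- 1
  if (nf %% 2L == 0L) {
    h[nf / 2L + 1L] <- 1
    h[2L:(nf / 2L)] <- 2
  } else {
    h[2L:((nf + 1L) / 2L)] <- 2
  }
  a <- stats::fft(xf * h, inverse = TRUE) / nf
  a[seq_len(n)]
}

#' Fast Pearson correlation without NA handling overhead
#' @keywords internal
pearson_r <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(NA_real_)
  mx <- sum(x) / n; my <- sum(y) / n
  xc <- x - mx; yc <- y - my
  den <- sqrt(sum(xc * xc) * sum(yc * yc))
  if (den <= 0 || !is.finite(den)) return(NA_real_)
  sum(xc * yc) / den
}

#' Pearson correlation over finite pairs only
#' @keywords internal
pearson_r_na <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 2L) return(NA_real_)
  pearson_r(x[ok], y[ok])
}

#' Stationary AR(1) noise
#'
#' @param n length.
#' @param sd marginal standard deviation of the process.
#' @param phi lag-one autocorrelation in `[0, 1)`.
#' @return numeric vector of length `n`.
#' @keywords internal
ar1_noise <- function(n, sd = 1, phi = 0) {
  if (sd <= 0) return(numeric(n))
  if (phi == 0) return(stats::rnorm(n, sd = sd))
  innov_sd <- sd * sqrt(1 - phi^2)
  x <- numeric(n)
  x[1L] <- stats::rnorm(1L, sd = sd)
  e <- stats::rnorm(n - 1L, sd = innov_sd)
  for (i in seq_len(n - 1L)) x[i + 1L] <- phi * x[i] + e[i]
  x
}

#' Log-spaced sequence
#' @keywords internal
logspace <- function(from, to, length.out) {
  exp(seq(log(from), log(to), length.out = length.out))
}

## Derive a reproducible child seed from a master seed and a stage label.
## Kept below 2^31 so it is always a valid R integer seed.
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

## Moving-average smoothing along a vector with edge renormalisation.
box_smooth <- function(x, width) {
  if (width <= 1L) return(x)
  k <- rep(1, width)
  num <- stats::filter(x, k, sides = 2)
  den <- stats::filter(rep(1, length(x)), k, sides = 2)
  out <- as.numeric(num / den)
  ## stats::filter leaves NAs at the very edges when width is even; patch
  ## with partial means
  bad <- which(is.na(out))
  for (i in bad) {
    lo <- max(1L, i - width %/% 2L)
    hi <- min(length(x), i + width %/% 2L)
    out[i] <- mean(x[lo:hi])
  }
  out
}
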