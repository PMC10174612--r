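## Shared fixtures and independent oracles for the test suite.

## Brute-force cross-correlogram oracle: Pearson correlation of explicitly
## shifted copies, r(l) = cor(x(t+l), y(t)).  Kept deliberately naive and
## independent of the package's fast path.
naive_xcf <- function(x, y, max_lag) {
  n <- length(x)
  vapply((-max_lag):max_lag, function(l) {
    if (l >= 0) stats::cor(x[(1 + l):n], y[1:(n - l)])
    else stats::cor(x[1:(n + l)], y[(1 - l):n])
  }, numeric(1))
}

## Small coupled simulation used by several tests.
quick_sim <- function(seed = 1, days = 4, nch = 2, ...) {
  simulate_study(synth_config(duration_days = days, n_channels = nch,
                              coupled_channels = seq_len(nch), seed = seed, ...))
}

## A tiny glucose series on the 5-min grid.
tiny_glucose <- function(values, t0 = as.POSIXct("2021-01-01", tz = "UTC")) {
  glucose_series(t0 + 300 * (seq_along(values) - 1L), values)
}

expect_hours_equal <- function(a, b, tol = 1e-6) {
  expect_lt(abs(a - b), tol)
}
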