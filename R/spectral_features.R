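## spectral_features: raw multichannel voltage -> smoothed powerband
## envelope series.  Filtering is zero-phase (forward-backward) throughout
## so that no filter group delay leaks into the hour-scale lag analyses.

#' Band definition
#'
#' @param name band label.
#' @param low,high band edges in Hz (`0 < low < high < fs/2` at use time).
#' @param filter_order order of the Butterworth bandpass (applied
#'   forward-backward, so the effective order is doubled).
#' @export
band_definition <- function(name, low, high, filter_order = 4L) {
  if (!(low > 0 && high > low)) stop("require 0 < low < high")
  list(name = name, low = low, high = high, filter_order = as.integer(filter_order))
}

#' Canonical powerband set
#'
#' delta 1-4, theta 4-8, alpha 8-12, beta 15-25, gamma 25-70 Hz (4th-order
#' Butterworth) and high-frequency activity (HFA) 70-170 Hz (8th order).
#' @return list of [band_definition()]s.
#' @export
canonical_bands <- function() {
  list(band_definition("delta", 1, 4, 4L),
       band_definition("theta", 4, 8, 4L),
       band_definition("alpha", 8, 12, 4L),
       band_definition("beta", 15, 25, 4L),
       band_definition("gamma", 25, 70, 4L),
       band_definition("hfa", 70, 170, 8L))
}

#' Spectral preprocessing configuration
#'
#' @param notch_freqs power-line frequencies to attenuate (Hz).
#' @param reference `"laplacian"`, `"bipolar"` or `"none"`.
#' @param smoothing_s boxcar smoothing window in seconds; envelopes are
#'   averaged over non-overlapping windows of this length, so each output
#'   sample represents a one-minute mean at the default.
#' @param bands list of [band_definition()]s.
#' @export
spectral_config <- function(notch_freqs = c(60, 120, 180),
                            reference = c("laplacian", "bipolar", "none"),
                            smoothing_s = 60,
                            bands = canonical_bands()) {
  if (smoothing_s <= 0) stop("smoothing_s must be positive")
  list(notch_freqs = notch_freqs, reference = match.arg(reference),
       smoothing_s = smoothing_s, bands = bands)
}

#' Powerband envelope container
#'
#' @param time `POSIXct` grid (centres of the smoothing windows).
#' @param values channels x bands x time array (uV, non-negative; `NA`
#'   marks masked edge samples).
#' @param bands band names (length = second array dimension).
#' @param channels channel metadata ([channel_meta()]).
#' @export
powerband_envelope <- function(time, values, bands, channels) {
  if (length(dim(values)) != 3L) stop("values must be a 3-d array")
  if (dim(values)[2L] != length(bands)) stop("band dimension mismatch")
  if (dim(values)[3L] != length(time)) stop("time dimension mismatch")
  structure(list(time = as.POSIXct(time, tz = "UTC"), values = values,
                 bands = as.character(bands), channels = channels),
            class = "powerband_envelope")
}

#' @export
print.powerband_envelope <- function(x, ...) {
  cat(sprintf("<powerband_envelope> %d channels x %d bands x %d samples\n",
              dim(x$values)[1L], dim(x$values)[2L], dim(x$values)[3L]))
  invisible(x)
}

#' Notch-filter a recording
#'
#' Zero-phase 2nd-order Butterworth band-stop (4 Hz wide) at each requested
#' frequency; applied forward-backward so attenuation at the notch exceeds
#' 20 dB while the passband away from the notch stays within 1 dB.
#'
#' @param rec a [neural_recording()].
#' @param freqs notch frequencies (Hz), all below Nyquist.
#' @param width_hz full stop-band width (Hz).
#' @return the filtered [neural_recording()].
#' @export
notch_filter <- function(rec, freqs = c(60, 120, 180), width_hz = 4) {
  nyq <- rec$fs / 2
  freqs <- freqs[freqs < nyq]                 # silently skip inapplicable
  if (length(freqs) == 0L) return(rec)
  if (any(freqs + width_hz / 2 >= nyq)) stop("notch frequency too close to Nyquist")
  x <- rec$samples
  for (f in freqs) {
    flt <- signal::butter(2, c(f - width_hz / 2, f + width_hz / 2) / nyq,
                          type = "stop")
    for (ch in seq_len(nrow(x))) x[ch, ] <- signal::filtfilt(flt, x[ch, ])
  }
  rec$samples <- x
  rec
}

#' Laplacian re-referencing
#'
#' Each interior contact is referenced against the mean of its two shaft
#' neighbours (`v_i - (v_{i-1} + v_{i+1}) / 2`), suppressing far-field
#' volume conduction; shaft-end contacts fall back to a bipolar reference
#' against their single neighbour; single-contact electrodes are passed
#' through with a warning.
#'
#' @param rec a [neural_recording()].
#' @return the re-referenced [neural_recording()].
#' @export
rereference_laplacian <- function(rec) {
  x <- rec$samples
  out <- x
  for (el in unique(rec$channels$electrode)) {
    rows <- which(rec$channels$electrode == el)
    rows <- rows[order(rec$channels$contact_index[rows])]
    k <- length(rows)
    if (k == 1L) {
      warning("single-contact electrode ", el, " passed through unreferenced")
      next
    }
    out[rows[1L], ] <- x[rows[1L], ] - x[rows[2L], ]
    out[rows[k], ] <- x[rows[k], ] - x[rows[k - 1L], ]
    if (k > 2L) for (i in 2L:(k - 1L))
      out[rows[i], ] <- x[rows[i], ] - (x[rows[i - 1L], ] + x[rows[i + 1L], ]) / 2
  }
  rec$samples <- out
  rec
}

#' Bipolar re-referencing (adjacent-contact differences)
#' @param rec a [neural_recording()].
#' @return a [neural_recording()] with one fewer channel per electrode.
#' @export
rereference_bipolar <- function(rec) {
  keep <- c(); vals <- list(); names_ <- c()
  for (el in unique(rec$channels$electrode)) {
    rows <- which(rec$channels$electrode == el)
    rows <- rows[order(rec$channels$contact_index[rows])]
    if (length(rows) < 2L) next
    for (i in seq_len(length(rows) - 1L)) {
      vals[[length(vals) + 1L]] <- rec$samples[rows[i], ] - rec$samples[rows[i + 1L], ]
      keep <- c(keep, rows[i])
      names_ <- c(names_, paste0(rec$channels$name[rows[i]], "-",
                                 rec$channels$name[rows[i + 1L]]))
    }
  }
  ch <- rec$channels[keep, , drop = FALSE]
  ch$name <- names_
  neural_recording(do.call(rbind, vals), fs = rec$fs,
                   start_time = rec$start_time, channels = channel_meta(
                     ch$name, ch$electrode, seq_len(nrow(ch)), ch$region,
                     ch$tissue, ch$laterality))
}

#' Single-band smoothed Hilbert envelope
#'
#' Zero-phase Butterworth bandpass of the stated order, magnitude of the
#' analytic (Hilbert) signal, then a mean over non-overlapping windows of
#' `smoothing_s` seconds, so each output sample is the average envelope of
#' one window.  Windows are centred on multiples of `smoothing_s` from the
#' recording start; the first and last window (which contain the filter
#' edge transients) are masked `NA`.
#'
#' @param rec a [neural_recording()] (already notched / re-referenced).
#' @param band a [band_definition()].
#' @param smoothing_s window length in seconds (default 60).
#' @return a [powerband_envelope()] with a single band.
#' @export
band_envelope <- function(rec, band, smoothing_s = 60) {
  nyq <- rec$fs / 2
  if (band$high >= nyq) stop("band upper edge at or above Nyquist")
  flt <- signal::butter(band$filter_order / 2L, c(band$low, band$high) / nyq,
                        type = "pass")
  w <- as.integer(round(smoothing_s * rec$fs))
  n <- ncol(rec$samples)
  centers <- seq(0L, n - 1L, by = w)                   # samples, window centres
  keep <- centers - w %/% 2L >= 0L & centers + w %/% 2L <= n
  centers <- centers[keep]
  out <- matrix(NA_real_, nrow = nrow(rec$samples), ncol = length(centers))
  for (ch in seq_len(nrow(rec$samples))) {
    bp <- signal::filtfilt(flt, rec$samples[ch, ])
    envl <- Mod(analytic_signal(bp))
    for (k in seq_along(centers)) {
      lo <- centers[k] - w %/% 2L + 1L
      hi <- centers[k] + w %/% 2L
      out[ch, k] <- mean(envl[lo:hi])
    }
  }
  if (ncol(out) > 2L) out[, c(1L, ncol(out))] <- NA_real_   # edge transients
  powerband_envelope(time = rec$start_time + centers / rec$fs,
                     values = array(out, dim = c(nrow(out), 1L, ncol(out))),
                     bands = band$name, channels = rec$channels)
}

#' Full preprocessing chain: voltage to powerband envelopes
#'
#' Notch filtering, re-referencing, exclusion of non-gray-matter contacts,
#' then one smoothed Hilbert envelope per configured band.
#'
#' @param rec a [neural_recording()].
#' @param cfg a [spectral_config()].
#' @return a [powerband_envelope()] with all configured bands.
#' @export
compute_envelopes <- function(rec, cfg = spectral_config()) {
  rec <- notch_filter(rec, cfg$notch_freqs)
  rec <- switch(cfg$reference,
                laplacian = rereference_laplacian(rec),
                bipolar = rereference_bipolar(rec),
                none = rec)
  gray <- rec$channels$tissue == "gray"
  if (!any(gray)) stop("no gray-matter channels to analyse")
  rec$samples <- rec$samples[gray, , drop = FALSE]
  rec$channels <- rec$channels[gray, , drop = FALSE]
  envs <- lapply(cfg$bands, function(b) band_envelope(rec, b, cfg$smoothing_s))
  vals <- array(NA_real_, dim = c(nrow(rec$channels), length(cfg$bands),
                                  length(envs[[1L]]$time)))
  for (b in seq_along(envs)) vals[, b, ] <- envs[[b]]$values[, 1L, ]
  powerband_envelope(envs[[1L]]$time, vals,
                     vapply(cfg$bands, `[[`, "", "name"), rec$channels)
}
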