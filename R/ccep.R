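## ccep_analysis: stimulation-evoked potential epoching, baseline
## correction, magnitude quantification, and the comparison between
## glucose-coupled and uncoupled channels.

#' Epoch a recording around stimulation pulses with baseline correction
#'
#' Cuts 2-s windows centred on each pulse, blanks the immediate
#' stimulation artifact (0-10 ms, replaced by a linear bridge), and
#' subtracts the per-epoch mean over the baseline window.  Pulses too close
#' to a recording edge are dropped and counted.
#'
#' @param rec a [neural_recording()].
#' @param pulse_times_s pulse times in seconds from recording start.
#' @param epoch_s epoch length (default 2 s, centred on the pulse).
#' @param baseline_s baseline window relative to the pulse (default
#'   `c(-0.150, 0.050)` s).
#' @param blank_s artifact-blanking window (default `c(0, 0.010)` s);
#'   `NULL` disables blanking.
#' @param stim_site label for the stimulated site.
#' @return an object of class `ccep_epochs` with `epochs`
#'   (channels x pulses x time), `rel_time`, `n_dropped` and
#'   `baseline_corrected = TRUE`.
#' @export
epoch_ccep <- function(rec, pulse_times_s, epoch_s = 2,
                       baseline_s = c(-0.150, 0.050), blank_s = c(0, 0.010),
                       stim_site = "unknown") {
  fs <- rec$fs
  half <- as.integer(round(epoch_s / 2 * fs))
  rel_time <- (seq_len(2L * half) - half - 1L) / fs
  n <- ncol(rec$samples)
  centers <- as.integer(round(pulse_times_s * fs)) + 1L
  ok <- centers - half >= 1L & centers + half - 1L <= n
  n_dropped <- sum(!ok)
  centers <- centers[ok]
  if (length(centers) == 0L) stop("no pulse fits inside the recording")
  ep <- array(0, dim = c(nrow(rec$samples), length(centers), 2L * half))
  for (p in seq_along(centers))
    ep[, p, ] <- rec$samples[, (centers[p] - half):(centers[p] + half - 1L),
                             drop = FALSE]
  obj <- structure(list(epochs = ep, rel_time = rel_time, fs = fs,
                        pulse_times = pulse_times_s[ok], stim_site = stim_site,
                        baseline_corrected = FALSE, n_dropped = n_dropped),
                   class = "ccep_epochs")
  if (!is.null(blank_s)) obj <- ccep_blank(obj, blank_s)
  ccep_baseline(obj, baseline_s)
}

## replace the blanking window by a linear bridge between its endpoints
ccep_blank <- function(ep, blank_s = c(0, 0.010)) {
  idx <- which(ep$rel_time >= blank_s[1L] & ep$rel_time <= blank_s[2L])
  if (length(idx) < 2L) return(ep)
  i0 <- max(min(idx) - 1L, 1L); i1 <- min(max(idx) + 1L, length(ep$rel_time))
  w <- (idx - i0) / (i1 - i0)
  for (ch in seq_len(dim(ep$epochs)[1L]))
    for (p in seq_len(dim(ep$epochs)[2L]))
      ep$epochs[ch, p, idx] <- ep$epochs[ch, p, i0] +
        w * (ep$epochs[ch, p, i1] - ep$epochs[ch, p, i0])
  ep
}

#' Baseline-correct CCEP epochs
#'
#' Subtracts each epoch's mean over the baseline window, so the corrected
#' baseline-window mean is exactly zero.
#'
#' @param ep a `ccep_epochs` object.
#' @param baseline_s baseline window relative to the pulse (seconds).
#' @return the corrected `ccep_epochs`.
#' @export
ccep_baseline <- function(ep, baseline_s = c(-0.150, 0.050)) {
  sel <- ep$rel_time >= baseline_s[1L] & ep$rel_time <= baseline_s[2L]
  if (!any(sel)) stop("baseline window outside the epoch")
  d <- dim(ep$epochs)
  for (ch in seq_len(d[1L])) {
    m <- matrix(ep$epochs[ch, , ], nrow = d[2L])      # pulses x time
    b <- rowMeans(m[, sel, drop = FALSE])
    ep$epochs[ch, , ] <- m - b
  }
  ep$baseline_corrected <- TRUE
  ep$baseline_s <- baseline_s
  ep
}

#' Mean evoked waveform per channel
#' @param ep a `ccep_epochs` object.
#' @return channels x time matrix (mean over pulses).
#' @export
ccep_mean_waveform <- function(ep) {
  apply(ep$epochs, c(1L, 3L), mean)
}

#' CCEP magnitude
#'
#' Mean of the pulse-averaged waveform over the response window, signed by
#' default (a rectified option is available).  The default window is
#' 10-150 ms post-pulse, starting after the artifact roll-off.
#'
#' @param ep a baseline-corrected `ccep_epochs`.
#' @param window_s response window in seconds (default `c(0.010, 0.150)`).
#' @param rectified take the mean absolute value instead of the signed mean.
#' @return named numeric vector, one magnitude per channel (uV).
#' @export
ccep_magnitude <- function(ep, window_s = c(0.010, 0.150), rectified = FALSE) {
  if (!isTRUE(ep$baseline_corrected))
    stop("epochs must be baseline-corrected first (see ccep_baseline)")
  sel <- ep$rel_time >= window_s[1L] & ep$rel_time <= window_s[2L]
  wf <- ccep_mean_waveform(ep)
  v <- if (rectified) rowMeans(abs(wf[, sel, drop = FALSE]))
       else rowMeans(wf[, sel, drop = FALSE])
  stats::setNames(v, rownames(wf))
}

#' Compare CCEP magnitudes between coupled and uncoupled channels
#'
#' Two-sample t-test of the per-channel magnitudes split by the coupling
#' partition, plus (optionally) the Pearson correlation between magnitude
#' and the per-channel lag-corrected glucose correlation.
#'
#' @param magnitudes per-channel CCEP magnitudes.
#' @param coupled_mask logical: channel significantly glucose-coupled.
#' @param coupling_r optional per-channel lag-corrected correlation.
#' @param min_per_group minimum channels per group for the t-test.
#' @return list with `t`, `df`, `p`, `mean_coupled`, `mean_uncoupled` and,
#'   when `coupling_r` is given, `cor_r`, `cor_p`.
#' @export
compare_by_coupling <- function(magnitudes, coupled_mask, coupling_r = NULL,
                                min_per_group = 5L) {
  a <- magnitudes[coupled_mask]; b <- magnitudes[!coupled_mask]
  out <- list(t = NA_real_, df = NA_real_, p = NA_real_,
              mean_coupled = mean(a), mean_uncoupled = mean(b))
  if (length(a) >= min_per_group && length(b) >= min_per_group &&
      (stats::sd(a) > 0 || stats::sd(b) > 0)) {
    tt <- stats::t.test(a, b, var.equal = TRUE)
    out$t <- unname(tt$statistic); out$df <- unname(tt$parameter)
    out$p <- tt$p.value
  }
  if (!is.null(coupling_r)) {
    ok <- is.finite(coupling_r) & is.finite(magnitudes)
    if (sum(ok) >= 3L && stats::sd(coupling_r[ok]) > 0) {
      ct <- stats::cor.test(magnitudes[ok], coupling_r[ok])
      out$cor_r <- unname(ct$estimate); out$cor_p <- ct$p.value
    }
  }
  out
}
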