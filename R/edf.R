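## Minimal European Data Format (EDF) reader/writer.  EDF stores a fixed
## ASCII header (256 bytes + 256 per signal) followed by data records of
## 16-bit little-endian integers, scaled per channel between declared
## physical and digital ranges.  Only continuous, equal-rate recordings are
## handled, which is all this package needs.

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1L, width)
  sprintf(paste0("%-", width, "s"), s)
}

#' Write a neural recording to EDF
#'
#' One-second data records; the sampling rate must therefore be a positive
#' integer.  Physical scaling is chosen per channel from the data range, so
#' round-trip error is bounded by the 16-bit quantisation step
#' (range / 65535).  A trailing partial second is truncated.
#'
#' @param rec a [neural_recording()].
#' @param path output path.
#' @export
write_edf <- function(rec, path) {
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  ns <- nrow(rec$samples)
  n_rec <- ncol(rec$samples) %/% fs
  if (n_rec < 1L) stop("recording shorter than one EDF record (1 s)")
  x <- rec$samples[, seq_len(n_rec * fs), drop = FALSE]
  pmin_ <- apply(x, 1L, min); pmax_ <- apply(x, 1L, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1; pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(pad_field("0", 8L),
                pad_field("X X X X", 80L),
                pad_field("Startdate X X X X", 80L),
                format(rec$start_time, "%d.%m.%y"),
                format(rec$start_time, "%H.%M.%S"),
                pad_field(256L * (ns + 1L), 8L),
                pad_field("", 44L),
                pad_field(n_rec, 8L),
                pad_field(1L, 8L),
                pad_field(ns, 4L))
  writeChar(hdr, con, eos = NULL)
  fields <- list(pad = c(16L, 80L, 8L, 8L, 8L, 8L, 8L, 80L, 8L, 32L),
                 val = list(rec$channels$name, "sEEG", "uV",
                            sprintf("%.6g", pmin_), sprintf("%.6g", pmax_),
                            dmin, dmax, "", fs, ""))
  for (f in seq_along(fields$pad)) {
    v <- rep_len(fields$val[[f]], ns)
    writeChar(paste0(vapply(v, pad_field, "", width = fields$pad[f]),
                     collapse = ""), con, eos = NULL)
  }
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  dig <- round((x - pmin_) / gain + dmin)
  dig <- pmin(pmax(dig, dmin), dmax)
  ## interleave: per record, all samples of signal 1, then signal 2, ...
  out <- integer(n_rec * ns * fs)
  pos <- 0L
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    blk <- t(dig[, cols, drop = FALSE])
    out[pos + seq_len(ns * fs)] <- as.integer(blk)
    pos <- pos + ns * fs
  }
  writeBin(out, con, size = 2L, endian = "little")
  invisible(path)
}

#' Read an EDF file into a neural recording
#'
#' All signals must share one sampling rate; mixed per-channel rates raise
#' an error.  Channel metadata beyond the label is not stored in EDF; use a
#' JSON sidecar via [read_neural()] to attach regions.
#'
#' @param path EDF path.
#' @return a [neural_recording()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8L)                                   # version
  rd(80L); rd(80L)                         # patient / recording id
  d <- rd(8L); tm <- rd(8L)
  rd(8L)                                   # header bytes
  rd(44L)
  n_rec <- as.integer(rd(8L))
  rec_dur <- as.numeric(rd(8L))
  ns <- as.integer(rd(4L))
  if (is.na(ns) || ns < 1L) stop("unreadable EDF header")
  grab <- function(w) vapply(seq_len(ns), function(i) trimws(rd(w)), "")
  labels <- grab(16L)
  grab(80L); grab(8L)
  pmin_ <- as.numeric(grab(8L)); pmax_ <- as.numeric(grab(8L))
  dmin <- as.numeric(grab(8L)); dmax <- as.numeric(grab(8L))
  grab(80L)
  spr <- as.integer(grab(8L))
  grab(32L)
  if (any(is.na(spr)) || any(spr <= 0)) stop("EDF header missing sampling rate")
  if (length(unique(spr)) != 1L)
    stop("EDF with mismatched per-channel sampling rates is not supported")
  fs <- spr[1L] / rec_dur
  raw <- readBin(con, "integer", n = n_rec * sum(spr), size = 2L,
                 endian = "little", signed = TRUE)
  if (length(raw) < n_rec * sum(spr)) stop("truncated EDF data section")
  samples <- matrix(0, nrow = ns, ncol = n_rec * spr[1L])
  pos <- 0L
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      seg <- raw[(pos + 1L):(pos + spr[s])]
      samples[s, ((r - 1L) * spr[s] + 1L):(r * spr[s])] <- seg
      pos <- pos + spr[s]
    }
  }
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  samples <- sweep(sweep(samples, 1L, dmin, "-"), 1L, gain, "*")
  samples <- sweep(samples, 1L, pmin_, "+")
  start <- as.POSIXct(paste(d, tm), format = "%d.%m.%y %H.%M.%S", tz = "UTC")
  if (is.na(start)) start <- as.POSIXct("2021-01-01", tz = "UTC")
  neural_recording(samples, fs = fs, start_time = start,
                   channels = channel_meta(labels))
}
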