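## io_and_timebase: containers for neural recordings, CGM glucose series and
## behavioural state annotations, plus alignment onto a shared 5-min grid.

REGION_VOCAB <- c("hypothalamus", "insula", "cingulate", "ahc", "frontal",
                  "temporal", "subcortical", "orbitofrontal", "unassigned")
STATE_VOCAB <- c("sleep", "wake", "pre_prandial", "prandial")

#' Channel metadata table
#'
#' Builds and validates the per-contact metadata used throughout the package:
#' electrode shaft, contact position along the shaft (needed for Laplacian
#' re-referencing), anatomical region label and tissue class.
#'
#' @param name channel labels (unique).
#' @param electrode shaft identifier (contacts on the same shaft share it).
#' @param contact_index integer position along the shaft, unique per shaft.
#' @param region anatomical label drawn from the declared vocabulary
#'   (`"hypothalamus"`, `"insula"`, `"cingulate"`, `"ahc"`, `"frontal"`,
#'   `"temporal"`, `"subcortical"`, `"orbitofrontal"`, `"unassigned"`).
#' @param tissue one of `"gray"`, `"white"`, `"excluded"` per contact.
#' @param laterality one of `"left"`, `"right"`, `"midline"` per contact.
#' @return a `data.frame` with one row per channel.
#' @export
channel_meta <- function(name,
                         electrode = name,
                         contact_index = seq_along(name),
                         region = "unassigned",
                         tissue = "gray",
                         laterality = "midline") {
  df <- data.frame(name = as.character(name),
                   electrode = as.character(electrode),
                   contact_index = as.integer(contact_index),
                   region = rep_len(as.character(region), length(name)),
                   tissue = rep_len(as.character(tissue), length(name)),
                   laterality = rep_len(as.character(laterality), length(name)),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$name)) stop("channel names must be unique")
  df$region[!(df$region %in% REGION_VOCAB)] <- "unassigned"
  for (el in unique(df$electrode)) {
    idx <- df$contact_index[df$electrode == el]
    if (anyDuplicated(idx)) stop("contact_index must be unique within electrode ", el)
  }
  if (!all(df$tissue %in% c("gray", "white", "excluded")))
    stop("tissue must be gray, white or excluded")
  df
}

#' Multichannel neural recording
#'
#' @param samples channels x time numeric matrix of voltages (microvolts).
#' @param fs sampling rate in Hz (positive scalar).
#' @param start_time absolute start timestamp (`POSIXct`, UTC).
#' @param channels channel metadata as built by [channel_meta()]; defaults to
#'   generic gray-matter contacts.
#' @return an object of class `neural_recording`.
#' @export
neural_recording <- function(samples, fs, start_time = as.POSIXct("2021-01-01", tz = "UTC"),
                             channels = NULL) {
  samples <- as.matrix(samples)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be a positive scalar")
  if (is.null(channels))
    channels <- channel_meta(paste0("ch", seq_len(nrow(samples))))
  if (nrow(channels) != nrow(samples))
    stop("channel metadata rows must match the number of sample rows")
  rownames(samples) <- channels$name
  structure(list(samples = samples, fs = fs,
                 start_time = as.POSIXct(start_time, tz = "UTC"),
                 channels = channels),
            class = "neural_recording")
}

#' @export
print.neural_recording <- function(x, ...) {
  cat(sprintf("<neural_recording> %d channels x %d samples @ %g Hz, start %s\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              format(x$start_time, "%Y-%m-%d %H:%M:%S")))
  invisible(x)
}

#' Read a neural recording
#'
#' Two on-disk layouts are supported: European Data Format (`"edf"`, see
#' [read_edf()]) and a plain numeric matrix (`"matrix"`): a TSV with one
#' column per channel plus a JSON sidecar (`<path>.json`) carrying `fs`,
#' `start_time` and the channel metadata.  Channels with no region in the
#' sidecar are labelled `"unassigned"`.
#'
#' @param path file path.
#' @param format `"edf"` or `"matrix"`.
#' @param sidecar optional explicit path to the JSON sidecar.
#' @return a [neural_recording()].
#' @export
read_neural <- function(path, format = c("edf", "matrix"), sidecar = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "edf") {
    rec <- read_edf(path)
    sidecar <- sidecar %||% paste0(path, ".json")
    if (file.exists(sidecar)) rec$channels <- sidecar_channels(sidecar, rec$channels$name)
    return(rec)
  }
  sidecar <- sidecar %||% paste0(path, ".json")
  if (!file.exists(sidecar)) stop("matrix format requires a JSON sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$fs)) stop("sidecar missing fs")
  vals <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  samples <- t(as.matrix(vals))
  ch <- sidecar_channels(sidecar, colnames(vals))
  neural_recording(samples, fs = meta$fs,
                   start_time = as.POSIXct(meta$start_time %||% "2021-01-01",
                                           tz = "UTC"),
                   channels = ch)
}

sidecar_channels <- function(sidecar, names_found) {
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  ch <- meta$channels
  if (is.null(ch)) return(channel_meta(names_found))
  ch <- as.data.frame(ch, stringsAsFactors = FALSE)
  channel_meta(name = ch$name %||% names_found,
               electrode = ch$electrode %||% (ch$name %||% names_found),
               contact_index = ch$contact_index %||% seq_along(names_found),
               region = ch$region %||% "unassigned",
               tissue = ch$tissue %||% "gray",
               laterality = ch$laterality %||% "midline")
}

#' Write a neural recording
#'
#' Counterpart of [read_neural()]; always writes the JSON metadata sidecar.
#'
#' @inheritParams read_neural
#' @param rec a [neural_recording()].
#' @export
write_neural <- function(rec, path, format = c("edf", "matrix")) {
  format <- match.arg(format)
  meta <- list(fs = rec$fs,
               start_time = format(rec$start_time, "%Y-%m-%dT%H:%M:%SZ"),
               channels = rec$channels)
  if (format == "edf") {
    write_edf(rec, path)
  } else {
    df <- as.data.frame(t(rec$samples))
    colnames(df) <- rec$channels$name
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path)
}

## ---------------------------------------------------------------------------
## Glucose series

#' Continuous glucose series
#'
#' A glucose series lives on a nominal uniform grid (5-minute cadence for the
#' CGM device emulated here).  Missing grid points are retained as `NA` with
#' `source == "missing"`; [interpolate_gaps()] fills short runs.
#'
#' @param time `POSIXct` timestamps on a uniform cadence.
#' @param value glucose in mg/dL (`NA` for missing points).
#' @param source per-point provenance: `"measured"`, `"interpolated"` or
#'   `"missing"`.
#' @param cadence_s nominal cadence in seconds (default 300).
#' @param check_positive require strictly positive non-missing values
#'   (disabled for derivative series).
#' @return an object of class `glucose_series`.
#' @export
glucose_series <- function(time, value, source = NULL, cadence_s = 300,
                           check_positive = TRUE) {
  time <- as.POSIXct(time, tz = "UTC")
  n <- length(time)
  if (length(value) != n) stop("time and value lengths differ")
  if (n > 1L) {
    d <- diff(as.numeric(time))
    if (any(d <= 0)) stop("timestamps must be strictly increasing")
    if (any(abs(d - cadence_s) > 0.02 * cadence_s))
      stop("cadence deviates from the nominal ", cadence_s, " s grid")
  }
  if (is.null(source)) source <- ifelse(is.na(value), "missing", "measured")
  if (check_positive && any(value[!is.na(value)] <= 0))
    stop("glucose values must be positive")
  structure(list(time = time, value = as.numeric(value),
                 source = as.character(source), cadence_s = cadence_s),
            class = "glucose_series")
}

#' @export
print.glucose_series <- function(x, ...) {
  cat(sprintf("<glucose_series> %d points @ %gs cadence (%d measured, %d interpolated, %d missing)\n",
              length(x$time), x$cadence_s, sum(x$source == "measured"),
              sum(x$source == "interpolated"), sum(x$source == "missing")))
  invisible(x)
}

#' Read a CGM glucose export
#'
#' Minimal two-column dialect: an ISO-8601 `timestamp` column and a
#' `glucose_mg_dl` column; any additional device columns are ignored.  The
#' series is validated (monotone timestamps, positive values), snapped onto
#' its nominal cadence grid, and gaps are recorded as `NA` rows (not yet
#' filled; see [interpolate_gaps()]).
#'
#' @param path CSV path.
#' @param cadence_s nominal cadence in seconds (default 300).
#' @return a [glucose_series()].
#' @export
read_glucose <- function(path, cadence_s = 300) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tcol <- if ("timestamp" %in% names(df)) "timestamp" else names(df)[1L]
  gcol <- if ("glucose_mg_dl" %in% names(df)) "glucose_mg_dl" else names(df)[2L]
  tm <- as.POSIXct(df[[tcol]], tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  if (any(is.na(tm))) stop("unparseable timestamps in ", path)
  val <- as.numeric(df[[gcol]])
  if (any(diff(as.numeric(tm)) <= 0)) stop("timestamps must be strictly increasing")
  if (any(val <= 0, na.rm = TRUE)) stop("negative or zero glucose values")
  ## snap onto the nominal grid, inserting NA rows for skipped points
  steps <- round(as.numeric(tm - tm[1L], units = "secs") / cadence_s)
  if (anyDuplicated(steps)) stop("duplicate grid points after cadence snapping")
  grid <- seq(0L, max(steps))
  full <- rep(NA_real_, length(grid))
  full[match(steps, grid)] <- val
  glucose_series(tm[1L] + grid * cadence_s, full, cadence_s = cadence_s)
}

#' Write a glucose series as CSV
#' @param g a [glucose_series()].
#' @param path output CSV path.
#' @export
write_glucose <- function(g, path) {
  keep <- !is.na(g$value) & g$source != "interpolated"
  df <- data.frame(timestamp = format(g$time[keep], "%Y-%m-%dT%H:%M:%S"),
                   glucose_mg_dl = g$value[keep])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fill short gaps in a glucose series
#'
#' Runs of at most `max_run` consecutive missing points flanked by measured
#' values are filled linearly between the flanking values and flagged
#' `"interpolated"`.  Longer runs are left missing and are excluded pairwise
#' from all downstream correlations.  Measured points are never modified, so
#' the operation is idempotent.
#'
#' @param g a [glucose_series()].
#' @param max_run longest fillable run (default 3 points).
#' @return a [glucose_series()] with short gaps filled.
#' @export
interpolate_gaps <- function(g, max_run = 3L) {
  v <- g$value
  src <- g$source
  miss <- is.na(v)
  if (!any(miss)) return(g)
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$lengths)) {
    if (!r$values[k]) next
    i0 <- starts[k]; i1 <- ends[k]
    if (r$lengths[k] > max_run) next
    if (i0 == 1L || i1 == length(v)) next            # no flanking value
    lo <- v[i0 - 1L]; hi <- v[i1 + 1L]
    if (is.na(lo) || is.na(hi)) next
    w <- seq_len(r$lengths[k]) / (r$lengths[k] + 1L)
    v[i0:i1] <- lo + w * (hi - lo)
    src[i0:i1] <- "interpolated"
  }
  glucose_series(g$time, v, src, cadence_s = g$cadence_s)
}

#' Discretised glucose derivative
#'
#' Backward first difference divided by the step, in mg/dL per minute,
#' assigned to the later timestamp (causal convention).  Requires a uniform
#' cadence; pairs with a missing neighbour yield `NA`.
#'
#' @param g a [glucose_series()].
#' @return a `glucose_series` of length `n - 1` whose values are rates
#'   (mg/dL/min, may be negative).
#' @export
glucose_derivative <- function(g) {
  d <- diff(as.numeric(g$time))
  if (length(d) && any(abs(d - d[1L]) > 1e-6)) stop("non-uniform cadence")
  step_min <- g$cadence_s / 60
  val <- diff(g$value) / step_min
  glucose_series(g$time[-1L], val, cadence_s = g$cadence_s,
                 check_positive = FALSE)
}

## ---------------------------------------------------------------------------
## State annotations

#' Behavioural state annotations
#'
#' Labelled time intervals: `sleep` (sustained sleep of at least 2 h),
#' `wake`, `pre_prandial` (-3 to 0 h relative to meal start) and `prandial`
#' (0 to +3 h).
#'
#' @param start,end interval bounds (`POSIXct`).
#' @param label state label per interval.
#' @param provenance free-text note on how the intervals were obtained.
#' @return an object of class `state_annotations`.
#' @export
state_annotations <- function(start, end, label, provenance = "unspecified") {
  start <- as.POSIXct(start, tz = "UTC"); end <- as.POSIXct(end, tz = "UTC")
  if (length(start) != length(end) || length(start) != length(label))
    stop("start, end and label lengths differ")
  if (any(end <= start)) stop("intervals must satisfy start < end")
  label <- as.character(label)
  if (!all(label %in% STATE_VOCAB))
    stop("labels must be one of: ", paste(STATE_VOCAB, collapse = ", "))
  dur_h <- as.numeric(end - start, units = "hours")
  if (any(label == "sleep" & dur_h < 2))
    stop("sleep intervals must last at least 2 h")
  structure(list(intervals = data.frame(start = start, end = end, label = label,
                                        stringsAsFactors = FALSE),
                 provenance = provenance),
            class = "state_annotations")
}

#' Read a state-annotation interval table (CSV: start,end,label)
#' @param path CSV path.
#' @export
read_states <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  fmt <- c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S")
  state_annotations(as.POSIXct(df$start, tz = "UTC", tryFormats = fmt),
                    as.POSIXct(df$end, tz = "UTC", tryFormats = fmt),
                    df$label, provenance = path)
}

#' Write state annotations to CSV
#' @param states a [state_annotations()].
#' @param path output path.
#' @export
write_states <- function(states, path) {
  df <- states$intervals
  df$start <- format(df$start, "%Y-%m-%dT%H:%M:%S")
  df$end <- format(df$end, "%Y-%m-%dT%H:%M:%S")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Rasterise state annotations onto a time grid
#'
#' @param states a [state_annotations()] (or `NULL`).
#' @param times `POSIXct` grid.
#' @return named list of logical vectors, one per state; `wake` is the
#'   complement of `sleep` unless wake intervals are given explicitly.
#' @export
state_masks <- function(states, times) {
  masks <- stats::setNames(rep(list(rep(FALSE, length(times))), length(STATE_VOCAB)),
                           STATE_VOCAB)
  if (is.null(states)) return(masks)
  for (k in seq_len(nrow(states$intervals))) {
    iv <- states$intervals[k, ]
    hit <- times >= iv$start & times < iv$end
    masks[[iv$label]] <- masks[[iv$label]] | hit
  }
  if (!any(states$intervals$label == "wake")) masks$wake <- !masks$sleep
  masks
}

## ---------------------------------------------------------------------------
## Alignment

#' Align powerband envelopes with a glucose series
#'
#' For every glucose timestamp the envelope sample whose centre time is
#' nearest and within `tolerance_s` is taken; glucose points with no match
#' are dropped together with their (absent) neural values so the two series
#' stay paired.  State masks are rasterised onto the retained grid.
#'
#' @param env a [powerband_envelope()].
#' @param g a [glucose_series()].
#' @param states optional [state_annotations()].
#' @param tolerance_s matching tolerance in seconds (default 1).
#' @return an object of class `aligned_pair` with elements `time`,
#'   `features` (channels x bands x time array), `glucose`, `masks`,
#'   `channels`, `bands` and `dt_s`.
#' @export
align_series <- function(env, g, states = NULL, tolerance_s = 1) {
  te <- as.numeric(env$time)
  tg <- as.numeric(g$time)
  dt_e <- if (length(te) > 1L) stats::median(diff(te)) else 1
  idx <- round((tg - te[1L]) / dt_e) + 1L
  ok <- idx >= 1L & idx <= length(te)
  miss <- abs(te[pmin(pmax(idx, 1L), length(te))] - tg) > tolerance_s
  matched <- ok & !miss
  if (mean(matched) < 0.5)
    stop("fewer than 50% of glucose points matched a neural sample within ",
         tolerance_s, " s; check clock alignment")
  keep <- which(matched)
  feats <- env$values[, , idx[keep], drop = FALSE]
  gl <- g$value[keep]
  times <- g$time[keep]
  masks <- state_masks(states, times)
  structure(list(time = times,
                 features = feats,
                 glucose = gl,
                 masks = masks,
                 channels = env$channels,
                 bands = env$bands,
                 dt_s = g$cadence_s),
            class = "aligned_pair")
}

#' @export
print.aligned_pair <- function(x, ...) {
  cat(sprintf("<aligned_pair> %d channels x %d bands x %d grid points @ %gs\n",
              dim(x$features)[1L], dim(x$features)[2L], dim(x$features)[3L],
              x$dt_s))
  invisible(x)
}
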