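## synthetic_data: neural powerband envelopes, glucose series, state
## annotations and evoked-potential epochs with fully known circadian and
## ultradian structure, coupling lags and noise.  Every analysis stage in
## the package has a parameter-recovery test against this generator.

#' Configuration for the coupled synthetic study
#'
#' The generator emits a glucose series on a 5-min grid and per-channel
#' powerband envelopes on a 1-min grid.  Both share a circadian sinusoid and
#' a set of ultradian sinusoids; coupled channels carry the shared terms
#' shifted by a per-channel temporal lag (negative = neural leads) and,
#' optionally, an additional circadian phase lead.  Uncoupled channels carry
#' private components of matched amplitude.  Glucose noise is AR(1) (CGM
#' noise is autocorrelated, which exercises the block-permutation null);
#' channel noise is white.
#'
#' Default amplitudes and periods follow the ultradian/circadian peak
#' structure the analyses are designed to detect (ultradian periods 0.7,
#' 1.8 and 7.8 h alongside a 24-h circadian component) over a 6-day
#' recording, comparable to a multi-day inpatient stay.
#'
#' @param duration_days recording length in days (must be at least 3
#'   circadian periods).
#' @param seed master seed; the same seed reproduces byte-identical output.
#' @param start_time absolute start (`POSIXct`, midnight recommended so the
#'   sleep schedule lines up with clock time).
#' @param n_channels number of envelope channels.
#' @param coupled_channels indices of channels sharing the glucose rhythm.
#' @param n_bands number of powerbands emitted per channel (band b is a
#'   scaled copy with independent noise).
#' @param lag_h per-channel temporal lag in hours (negative = neural leads;
#'   recycled across coupled channels).
#' @param phase_lead_h additional per-channel circadian phase lead in hours
#'   (positive = the channel's circadian component peaks earlier than the
#'   glucose circadian component, on top of any lead implied by `lag_h`).
#' @param circadian_period_h circadian period (default 24).
#' @param glucose_phase_h clock hour of the glucose circadian peak.
#' @param glucose_baseline,glucose_circ_amp baseline and circadian amplitude
#'   of glucose (mg/dL).
#' @param ultradian_periods_h shared ultradian periods (hours).
#' @param glucose_ultra_amp,channel_ultra_amp ultradian amplitudes for the
#'   glucose series (mg/dL) and channel envelopes (uV), one per period.
#' @param channel_base,channel_circ_amp envelope baseline and circadian
#'   amplitude (uV); `channel_circ_amp` may be a per-channel vector (0
#'   removes the circadian term from that channel).
#' @param noise_sd_glucose,glucose_noise_ar glucose noise marginal sd and
#'   AR(1) coefficient.
#' @param noise_sd_channel white-noise sd on each envelope.
#' @param wake_gated_ultradian if `TRUE`, the shared ultradian terms enter
#'   the neural channels only during wake, so ultradian coupling exists only
#'   in the wake state.
#' @param hyper_count,hyper_magnitude number and height (mg/dL) of smooth
#'   hyperglycaemia bumps added to glucose (exercises the decoder's
#'   saturation rule at 160 mg/dL).
#' @param sleep_onset_h,sleep_duration_h daily sleep schedule (clock hours).
#' @param meal_times_h daily meal start times (clock hours).
#' @param cadence_glucose_s,cadence_env_s output cadences in seconds.
#' @return a `synth_config` list.
#' @export
synth_config <- function(duration_days = 6,
                         seed = 1L,
                         start_time = as.POSIXct("2021-01-01", tz = "UTC"),
                         n_channels = 12L,
                         coupled_channels = 1:8,
                         n_bands = 1L,
                         lag_h = -2.8,
                         phase_lead_h = 0,
                         circadian_period_h = 24,
                         glucose_phase_h = 4,
                         glucose_baseline = 110,
                         glucose_circ_amp = 12,
                         ultradian_periods_h = c(0.7, 1.8, 7.8),
                         glucose_ultra_amp = c(2, 3, 5),
                         channel_base = 10,
                         channel_circ_amp = 2,
                         channel_ultra_amp = c(0.5, 0.8, 1.2),
                         noise_sd_glucose = 4,
                         glucose_noise_ar = 0.8,
                         noise_sd_channel = 0.5,
                         wake_gated_ultradian = FALSE,
                         hyper_count = 2L,
                         hyper_magnitude = 70,
                         sleep_onset_h = 23,
                         sleep_duration_h = 8,
                         meal_times_h = c(8, 13, 19),
                         cadence_glucose_s = 300,
                         cadence_env_s = 60) {
  cfg <- as.list(environment())
  if (duration_days * 24 < 3 * circadian_period_h)
    stop("duration must cover at least 3 circadian periods")
  if (any(ultradian_periods_h <= 0) || circadian_period_h <= 0)
    stop("periods must be positive")
  if (length(glucose_ultra_amp) != length(ultradian_periods_h) ||
      length(channel_ultra_amp) != length(ultradian_periods_h))
    stop("one ultradian amplitude per period is required")
  class(cfg) <- "synth_config"
  cfg
}

## wake indicator (1 = awake) at time t hours after a midnight start
wake_indicator <- function(t_h, onset_h, dur_h) {
  tod <- t_h %% 24
  asleep <- if (onset_h + dur_h <= 24) {
    tod >= onset_h & tod < onset_h + dur_h
  } else {
    tod >= onset_h | tod < (onset_h + dur_h - 24)
  }
  as.numeric(!asleep)
}

#' Simulate a coupled neural-glucose study
#'
#' @param cfg a [synth_config()].
#' @return a list with elements `envelopes` ([powerband_envelope()]),
#'   `glucose` ([glucose_series()]), `states` ([state_annotations()]) and
#'   `truth`: the realised component series per signal (their sum
#'   reconstructs each emitted series to machine precision), the true lags,
#'   circadian phase leads and the coupled-channel set.
#' @export
simulate_study <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  T_c <- cfg$circadian_period_h
  dur_h <- cfg$duration_days * 24
  n_g <- as.integer(dur_h * 3600 / cfg$cadence_glucose_s)
  n_e <- as.integer(dur_h * 3600 / cfg$cadence_env_s)
  t_g <- (seq_len(n_g) - 1L) * cfg$cadence_glucose_s / 3600   # hours
  t_e <- (seq_len(n_e) - 1L) * cfg$cadence_env_s / 3600

  circ_shape <- function(t) cos(2 * pi * (t - cfg$glucose_phase_h) / T_c)
  theta <- stats::runif(length(cfg$ultradian_periods_h), 0, cfg$ultradian_periods_h)
  ultra_shape <- function(t, amps) {
    out <- numeric(length(t))
    for (j in seq_along(amps))
      out <- out + amps[j] * cos(2 * pi * (t - theta[j]) / cfg$ultradian_periods_h[j])
    out
  }

  ## glucose components
  g_circ <- cfg$glucose_circ_amp * circ_shape(t_g)
  g_ultra <- ultra_shape(t_g, cfg$glucose_ultra_amp)
  g_epis <- numeric(n_g)
  ep_times <- numeric(0)
  if (cfg$hyper_count > 0) {
    ep_times <- sort(stats::runif(cfg$hyper_count, 12, dur_h - 12))
    for (te in ep_times)
      g_epis <- g_epis + cfg$hyper_magnitude * exp(-(t_g - te)^2 / (2 * 0.4^2))
  }
  g_noise <- ar1_noise(n_g, sd = cfg$noise_sd_glucose, phi = cfg$glucose_noise_ar)
  g_val <- cfg$glucose_baseline + g_circ + g_ultra + g_epis + g_noise
  glucose <- glucose_series(cfg$start_time + (t_g * 3600), g_val,
                            cadence_s = cfg$cadence_glucose_s)

  ## channels
  coupled <- seq_len(cfg$n_channels) %in% cfg$coupled_channels
  lag_ch <- rep_len(cfg$lag_h, cfg$n_channels)
  lead_ch <- rep_len(cfg$phase_lead_h, cfg$n_channels)
  circ_amp_ch <- rep_len(cfg$channel_circ_amp, cfg$n_channels)
  wk <- wake_indicator(t_e, cfg$sleep_onset_h, cfg$sleep_duration_h)

  bands <- if (cfg$n_bands == 1L) "hfa" else
    c("delta", "theta", "alpha", "beta", "gamma", "hfa")[seq_len(cfg$n_bands)]
  band_gain <- seq(1, 0.6, length.out = cfg$n_bands)
  vals <- array(0, dim = c(cfg$n_channels, cfg$n_bands, n_e))
  truth_ch <- vector("list", cfg$n_channels)
  for (ch in seq_len(cfg$n_channels)) {
    if (coupled[ch]) {
      tt <- t_e - lag_ch[ch]                     # negative lag -> leads
      circ <- circ_amp_ch[ch] * circ_shape(tt + lead_ch[ch])
      ultra <- ultra_shape(tt, cfg$channel_ultra_amp)
      if (cfg$wake_gated_ultradian) ultra <- ultra * wk
    } else {
      ph_c <- stats::runif(1, 0, T_c)
      th_p <- stats::runif(length(cfg$ultradian_periods_h), 0,
                           cfg$ultradian_periods_h)
      circ <- circ_amp_ch[ch] * cos(2 * pi * (t_e - ph_c) / T_c)
      ultra <- numeric(n_e)
      for (j in seq_along(cfg$channel_ultra_amp))
        ultra <- ultra + cfg$channel_ultra_amp[j] *
          cos(2 * pi * (t_e - th_p[j]) / cfg$ultradian_periods_h[j])
    }
    noise_b <- matrix(stats::rnorm(cfg$n_bands * n_e, sd = cfg$noise_sd_channel),
                      nrow = cfg$n_bands)
    for (b in seq_len(cfg$n_bands))
      vals[ch, b, ] <- cfg$channel_base +
        band_gain[b] * (circ + ultra) + noise_b[b, ]
    truth_ch[[ch]] <- list(base = cfg$channel_base, circadian = circ,
                           ultradian = ultra, noise = noise_b,
                           band_gain = band_gain)
  }

  chans <- channel_meta(name = sprintf("ch%02d", seq_len(cfg$n_channels)),
                        electrode = sprintf("E%d", (seq_len(cfg$n_channels) - 1L) %/% 4L + 1L),
                        contact_index = (seq_len(cfg$n_channels) - 1L) %% 4L + 1L,
                        region = rep_len(c("hypothalamus", "insula", "cingulate",
                                           "ahc", "frontal", "temporal"),
                                         cfg$n_channels))
  env <- powerband_envelope(time = cfg$start_time + t_e * 3600,
                            values = vals, bands = bands, channels = chans)

  states <- schedule_states(cfg)

  truth <- list(glucose = list(baseline = cfg$glucose_baseline,
                               circadian = g_circ, ultradian = g_ultra,
                               episodes = g_epis, noise = g_noise,
                               episode_times_h = ep_times),
                channels = truth_ch,
                lag_h = lag_ch,
                phase_lead_h = -lag_ch + lead_ch,
                coupled = coupled,
                ultradian_theta_h = theta,
                t_glucose_h = t_g, t_env_h = t_e)
  list(envelopes = env, glucose = glucose, states = states, truth = truth)
}

## sleep + pre/prandial interval table from the schedule in a synth_config
schedule_states <- function(cfg) {
  t0 <- cfg$start_time
  end <- t0 + cfg$duration_days * 86400
  starts <- c(); ends <- c(); labels <- c()
  for (d in 0:(cfg$duration_days)) {
    s0 <- t0 + d * 86400 + cfg$sleep_onset_h * 3600
    s1 <- s0 + cfg$sleep_duration_h * 3600
    s0 <- max(s0, t0); s1 <- min(s1, end)
    if (as.numeric(s1 - s0, units = "hours") >= 2) {
      starts <- c(starts, s0); ends <- c(ends, s1); labels <- c(labels, "sleep")
    }
    for (m in cfg$meal_times_h) {
      m0 <- t0 + d * 86400 + m * 3600
      if (m0 >= end) next
      p0 <- max(m0 - 3 * 3600, t0); p1 <- m0
      q0 <- m0; q1 <- min(m0 + 3 * 3600, end)
      if (p1 > p0) {
        starts <- c(starts, p0); ends <- c(ends, p1); labels <- c(labels, "pre_prandial")
      }
      if (q1 > q0) {
        starts <- c(starts, q0); ends <- c(ends, q1); labels <- c(labels, "prandial")
      }
    }
  }
  o <- order(starts)
  state_annotations(.POSIXct(starts[o], tz = "UTC"),
                    .POSIXct(ends[o], tz = "UTC"), labels[o],
                    provenance = "synthetic schedule")
}

#' Simulate stimulation-evoked potential epochs
#'
#' Per-channel 2-s epochs centred on each stimulation pulse.  Coupled
#' channels carry a damped-oscillation evoked response whose peak amplitude
#' within 10-150 ms is `amp_coupled` (times a per-channel log-normal-ish
#' jitter); uncoupled channels use `amp_uncoupled`.  Roughly 50 pulses is
#' the convention for single-pulse mapping.
#'
#' @param n_channels number of channels.
#' @param coupled indices of coupled channels.
#' @param amp_coupled,amp_uncoupled evoked peak amplitudes (uV);
#'   `amp_coupled > amp_uncoupled >= 0`.
#' @param n_pulses number of stimulation pulses (default 50).
#' @param noise_sd white noise sd per sample (uV).
#' @param amp_jitter relative sd of the per-channel amplitude jitter.
#' @param offset_sd sd of per-channel DC offsets (exercises baseline
#'   correction).
#' @param fs epoch sampling rate (Hz).
#' @param seed RNG seed.
#' @return a `ccep_epochs` object (uncorrected) whose `truth` element holds
#'   the per-channel true amplitudes, the unit template and the analytic
#'   mean of the template over the 10-150 ms window.
#' @export
simulate_ccep <- function(n_channels = 20L, coupled = 1:10,
                          amp_coupled = 30, amp_uncoupled = 10,
                          n_pulses = 50L, noise_sd = 5, amp_jitter = 0.2,
                          offset_sd = 0, fs = 512, seed = 1L) {
  if (!(amp_coupled > amp_uncoupled && amp_uncoupled >= 0))
    stop("require amp_coupled > amp_uncoupled >= 0")
  set.seed(seed)
  rel_time <- seq(-1, 1 - 1 / fs, by = 1 / fs)
  u <- rel_time - 0.010
  tmpl <- ifelse(u >= 0, sin(2 * pi * 8 * u) * exp(-u / 0.05), 0)
  win <- rel_time >= 0.010 & rel_time <= 0.150
  tmpl <- tmpl / max(tmpl[win])                     # unit peak in the window
  is_coupled <- seq_len(n_channels) %in% coupled
  amp <- ifelse(is_coupled, amp_coupled, amp_uncoupled)
  amp <- amp * pmax(0.1, 1 + amp_jitter * stats::rnorm(n_channels))
  offs <- stats::rnorm(n_channels, sd = offset_sd)
  ep <- array(0, dim = c(n_channels, n_pulses, length(rel_time)))
  for (ch in seq_len(n_channels)) {
    base <- amp[ch] * tmpl + offs[ch]
    for (p in seq_len(n_pulses))
      ep[ch, p, ] <- base + stats::rnorm(length(rel_time), sd = noise_sd)
  }
  structure(list(epochs = ep, rel_time = rel_time, fs = fs,
                 pulse_times = seq_len(n_pulses), stim_site = "synthetic",
                 baseline_corrected = FALSE, n_dropped = 0L,
                 truth = list(amp = amp, coupled = is_coupled, template = tmpl,
                              window_mean = mean(tmpl[win]))),
            class = "ccep_epochs")
}

#' Simulate a sparse linear decoding problem
#'
#' A feature table with `n_channels * n_bands` columns of AR(1) series in
#' which exactly `n_active` columns drive the target through a sparse linear
#' map plus Gaussian noise at a configurable amplitude signal-to-noise
#' ratio.  Ground truth (active set and coefficients) is attached for
#' support-recovery tests.
#'
#' @param n_rows time points.
#' @param n_channels,n_bands feature grid (columns = `n_channels * n_bands`).
#' @param n_active number of truly contributing columns.
#' @param snr amplitude SNR: `sd(signal) / sd(noise)` of the target.
#' @param ar feature column AR(1) coefficient.
#' @param seed RNG seed.
#' @return a `feature_table` with a `truth` element (`active`, `beta`).
#' @export
simulate_sparse_features <- function(n_rows = 1500L, n_channels = 10L,
                                     n_bands = 6L, n_active = 3L, snr = 20,
                                     ar = 0.5, seed = 1L) {
  set.seed(seed)
  p <- n_channels * n_bands
  X <- vapply(seq_len(p), function(j) ar1_noise(n_rows, sd = 1, phi = ar),
              numeric(n_rows))
  active <- sort(sample.int(p, n_active))
  beta <- numeric(p)
  beta[active] <- sample(c(-1, 1), n_active, replace = TRUE) *
    stats::runif(n_active, 0.8, 1.2)
  signal <- as.numeric(X %*% beta)
  noise <- stats::rnorm(n_rows, sd = stats::sd(signal) / snr)
  y <- 120 + signal + noise
  bands <- c("delta", "theta", "alpha", "beta", "gamma", "hfa")[seq_len(n_bands)]
  meta <- expand.grid(band = bands, channel = sprintf("ch%02d", seq_len(n_channels)),
                      stringsAsFactors = FALSE)[, c("channel", "band")]
  ft <- feature_table(X = X, y = y,
                      time = as.POSIXct("2021-01-01", tz = "UTC") + 300 * (seq_len(n_rows) - 1L),
                      col_meta = meta)
  ft$truth <- list(active = active, beta = beta)
  ft
}

#' Simulate a raw-voltage recording with a programmed envelope
#'
#' Thin raw-voltage mode for testing the spectral chain: an in-band carrier
#' amplitude-modulated by a slow programmed envelope, plus white noise.  The
#' full preprocessing chain should recover the programmed envelope (up to
#' scale) on the 1-min grid.
#'
#' @param duration_s recording length (seconds).
#' @param fs sampling rate (Hz).
#' @param carrier_hz carrier frequency (place it inside the band under test).
#' @param env_period_s period of the programmed sinusoidal envelope.
#' @param env_base,env_amp envelope offset and modulation depth (uV);
#'   `env_base > env_amp` keeps the envelope positive.
#' @param noise_sd additive white noise sd (uV).
#' @param seed RNG seed.
#' @return list with `rec` (a [neural_recording()]) and `true_env`, the
#'   programmed envelope averaged over the 1-min analysis windows.
#' @export
simulate_raw_voltage <- function(duration_s = 1800, fs = 512, carrier_hz = 100,
                                 env_period_s = 450, env_base = 2, env_amp = 1,
                                 noise_sd = 0.05, seed = 1L) {
  set.seed(seed)
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  E <- env_base + env_amp * sin(2 * pi * t / env_period_s)
  x <- E * sin(2 * pi * carrier_hz * t) + stats::rnorm(length(t), sd = noise_sd)
  rec <- neural_recording(matrix(x, nrow = 1L), fs = fs,
                          channels = channel_meta("sim1"))
  centers <- seq(60, duration_s - 60, by = 60)
  true_env <- vapply(centers, function(ct) mean(E[t >= ct - 30 & t < ct + 30]),
                     numeric(1))
  list(rec = rec, true_env = true_env, center_s = centers)
}
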