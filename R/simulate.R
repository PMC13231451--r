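#' Configuration for the synthetic sleep/IED recording generator
#'
#' Builds the parameter set that drives the seeded simulator: a semi-Markov
#' hypnogram, multichannel 1/f background with stage-dependent slow-wave
#' oscillation, embedded spike-wave IED kernels with stage-dependent rate
#' and amplitude, unit spike trains with stage-dependent baseline firing
#' and PDS-like modulation time-locked to each IED (a transient gain during
#' the spike, suppression during the following slow wave), and artefact
#' intervals.
#'
#' Defaults encode the orderings the analysis is designed to detect:
#' IED rate and amplitude increase with NREM depth (S3 > S2 > S1 >
#' REM = Wake), background firing decreases into slow-wave sleep, and the
#' spike peak is 150 uV on the deepest contact over 20 uV r.m.s. noise
#' (signal-to-noise ratio 7.5).
#'
#' @param duration_s total recording duration (seconds).
#' @param sample_rate_hz sampling rate (Hz); 1000 by default, 4000 mirrors
#'   clinical acquisition.
#' @param n_channels number of depth contacts (channel 1 = deepest).
#' @param pre_s,post_s durations of the pre-sleep and post-sleep blocks.
#' @param stage_dwell_s named mean dwell times (seconds) of the semi-Markov
#'   sleep stages (Wake, S1, S2, S3, REM).
#' @param stage_transition row-stochastic transition matrix between those
#'   stages (no self-transitions; dwell times carry the holding).
#' @param ied_base_rate_per_min IED rate in Wake/Pre (events per minute).
#' @param ied_rate_mult,ied_amp_mult named per-stage multipliers of IED rate
#'   and amplitude.
#' @param ied_amplitude_uv spike-peak amplitude on the deepest contact (uV).
#' @param ied_amp_jitter_sdlog lognormal jitter of per-event amplitude.
#' @param ied_min_separation_s hard-core minimum separation between
#'   injected IEDs (keeps the +-50 ms scoring tolerance unambiguous).
#' @param n_templates number of distinct IED morphologies to mix.
#' @param depth_gradient amplitude decay from deepest to most superficial
#'   contact (recycled/interpolated to `n_channels`).
#' @param noise_exponent spectral exponent of the 1/f background.
#' @param noise_rms_uv r.m.s. amplitude of the background noise (uV).
#' @param swa_freq_hz centre frequency of the slow oscillation.
#' @param swa_amp_uv named per-stage amplitude of the slow oscillation (uV).
#' @param n_units number of simulated units.
#' @param unit_baseline_hz baseline firing rate (Hz) per unit (recycled).
#' @param unit_stage_mult named per-stage multipliers of baseline firing.
#' @param burst_prob probability that a spike spawns a doublet (ISI < 5 ms).
#' @param g_spike multiplicative firing gain during the IED spike window.
#' @param g_wave multiplicative gain (< 1 = suppression) during the slow
#'   wave window; must be >= 0.
#' @param spike_gain_window_s,wave_gain_window_s modulation windows relative
#'   to the IED peak (seconds).
#' @param unit_amp_mult named per-stage multipliers of the spike amplitude
#'   mark.
#' @param artefact_rate_per_hour,artefact_duration_s artefact interval rate
#'   and mean duration.
#' @param seed integer seed; together with the config it fully determines
#'   every generated object.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(duration_s = 3600,
                       sample_rate_hz = 1000,
                       n_channels = 5,
                       pre_s = 300,
                       post_s = 300,
                       stage_dwell_s = c(Wake = 90, S1 = 120, S2 = 300, S3 = 300, REM = 180),
                       stage_transition = NULL,
                       ied_base_rate_per_min = 6,
                       ied_rate_mult = c(Pre = 1, Wake = 1, S1 = 2, S2 = 3, S3 = 4, REM = 1, Post = 1),
                       ied_amp_mult = c(Pre = 1, Wake = 1, S1 = 1.15, S2 = 1.3, S3 = 1.5, REM = 1, Post = 1),
                       ied_amplitude_uv = 150,
                       ied_amp_jitter_sdlog = 0.1,
                       ied_min_separation_s = 0.3,
                       n_templates = 2,
                       depth_gradient = c(1, 0.75, 0.55, 0.4, 0.3),
                       noise_exponent = 1,
                       noise_rms_uv = 20,
                       swa_freq_hz = 0.8,
                       swa_amp_uv = c(Pre = 5, Wake = 5, S1 = 10, S2 = 20, S3 = 40, REM = 5, Post = 5),
                       n_units = 3,
                       unit_baseline_hz = 5,
                       unit_stage_mult = c(Pre = 1, Wake = 1, S1 = 0.85, S2 = 0.7, S3 = 0.5, REM = 0.9, Post = 1),
                       burst_prob = 0.1,
                       g_spike = 3,
                       g_wave = 0.3,
                       spike_gain_window_s = c(-0.025, 0.075),
                       wave_gain_window_s = c(0.1, 0.5),
                       unit_amp_mult = c(Pre = 1, Wake = 1, S1 = 1.05, S2 = 1.1, S3 = 1.2, REM = 1, Post = 1),
                       artefact_rate_per_hour = 2,
                       artefact_duration_s = 2,
                       seed = 1) {
  if (is.null(stage_transition)) {
    stage_transition <- rbind(
      Wake = c(Wake = 0,   S1 = 0.8, S2 = 0.2, S3 = 0,   REM = 0),
      S1   = c(Wake = 0.2, S1 = 0,   S2 = 0.6, S3 = 0,   REM = 0.2),
      S2   = c(Wake = 0.1, S1 = 0.2, S2 = 0,   S3 = 0.5, REM = 0.2),
      S3   = c(Wake = 0.1, S1 = 0.1, S2 = 0.6, S3 = 0,   REM = 0.2),
      REM  = c(Wake = 0.3, S1 = 0.3, S2 = 0.4, S3 = 0,   REM = 0))
  }
  cfg <- list(
    duration_s = duration_s, sample_rate_hz = sample_rate_hz,
    n_channels = as.integer(n_channels), pre_s = pre_s, post_s = post_s,
    stage_dwell_s = stage_dwell_s, stage_transition = stage_transition,
    ied_base_rate_per_min = ied_base_rate_per_min,
    ied_rate_mult = ied_rate_mult, ied_amp_mult = ied_amp_mult,
    ied_amplitude_uv = ied_amplitude_uv,
    ied_amp_jitter_sdlog = ied_amp_jitter_sdlog,
    ied_min_separation_s = ied_min_separation_s,
    n_templates = as.integer(n_templates),
    depth_gradient = depth_gradient,
    noise_exponent = noise_exponent, noise_rms_uv = noise_rms_uv,
    swa_freq_hz = swa_freq_hz, swa_amp_uv = swa_amp_uv,
    n_units = as.integer(n_units),
    unit_baseline_hz = rep_len(unit_baseline_hz, n_units),
    unit_stage_mult = unit_stage_mult,
    burst_prob = burst_prob, g_spike = g_spike, g_wave = g_wave,
    spike_gain_window_s = spike_gain_window_s,
    wave_gain_window_s = wave_gain_window_s,
    unit_amp_mult = unit_amp_mult,
    artefact_rate_per_hour = artefact_rate_per_hour,
    artefact_duration_s = artefact_duration_s,
    seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot_scalar(cfg$duration_s, "duration_s")
  stopifnot_scalar(cfg$sample_rate_hz, "sample_rate_hz")
  if (cfg$n_channels < 1) stop("n_channels must be >= 1")
  if (cfg$ied_base_rate_per_min < 0) stop("rates must be >= 0")
  if (any(cfg$ied_rate_mult <= 0) || any(cfg$ied_amp_mult <= 0))
    stop("stage multipliers must be > 0")
  if (any(cfg$stage_dwell_s <= 0)) stop("stage dwell times must be positive")
  if (any(abs(rowSums(cfg$stage_transition) - 1) > 1e-9))
    stop("stage_transition rows must sum to 1")
  if (cfg$g_wave < 0) stop("g_wave must be >= 0")
  if (cfg$duration_s < cfg$pre_s + cfg$post_s)
    stop("duration shorter than the pre- plus post-sleep blocks")
  invisible(cfg)
}

#' Simulate a hypnogram
#'
#' Generates ordered, gap-free stage intervals: a pre-sleep block, then a
#' semi-Markov chain over \{Wake, S1, S2, S3, REM\} with exponential dwell
#' times, then a post-sleep block. With `pre_s` equal to the full duration
#' the hypnogram degenerates to a single Pre interval.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `onset_s`, `offset_s`, `stage` covering
#'   `[0, duration_s)` without gaps or overlaps.
#' @export
generate_hypnogram <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed + 1L, {
    dur <- config$duration_s
    sleep_end <- dur - config$post_s
    rows <- list()
    if (config$pre_s > 0)
      rows[[1]] <- data.frame(onset_s = 0, offset_s = min(config$pre_s, dur),
                              stage = "Pre")
    t <- config$pre_s
    state <- "Wake"
    states <- rownames(config$stage_transition)
    while (t < sleep_end - 1e-9) {
      dwell <- rexp(1, 1 / config$stage_dwell_s[[state]])
      off <- min(t + dwell, sleep_end)
      rows[[length(rows) + 1]] <- data.frame(onset_s = t, offset_s = off, stage = state)
      t <- off
      state <- sample(states, 1, prob = config$stage_transition[state, ])
    }
    if (config$post_s > 0)
      rows[[length(rows) + 1]] <- data.frame(onset_s = sleep_end, offset_s = dur,
                                             stage = "Post")
    hyp <- do.call(rbind, rows)
    rownames(hyp) <- NULL
    validate_intervals(hyp)
    hyp
  })
}

#' Spike-wave IED kernel
#'
#' Channel x time template of one interictal discharge morphology: a sharp
#' positive transient (< 200 ms wide) peaking at kernel time 0, followed by
#' a slower negative wave, with amplitude decaying monotonically from the
#' deepest contact (channel 1) to the most superficial. Clinical polarity
#' is stored (spike positive, wave negative); display inversion is a
#' plotting concern only. Peak amplitude is 1 on the deepest channel;
#' scaling happens at injection time.
#'
#' @param template_id integer >= 1 selecting the morphology (1 = narrow
#'   monophasic spike, 2 = broader polyspike-like transient with an earlier
#'   deeper wave; further ids vary the spike width parametrically).
#' @param config a [sim_config()].
#' @return List with `waveform` (channels x time), `times_s` (kernel time
#'   axis, `[-0.3, 0.7)` s), `peak_index` (sample of kernel time 0) and
#'   `sample_rate_hz`.
#' @export
make_ied_kernel <- function(template_id, config) {
  fs <- config$sample_rate_hz
  tk <- seq(-0.3, 0.7 - 1 / fs, by = 1 / fs)
  id <- as.integer(template_id)
  if (id == 1L) {
    spike <- exp(-0.5 * (tk / 0.022)^2)
    wave <- -0.45 * sinpulse(tk, 0.05, 0.50)
  } else if (id == 2L) {
    ## polyspike-like: dominant sharp peak plus a trailing secondary peak,
    ## with a shorter, deeper slow wave than morphology 1
    spike <- exp(-0.5 * (tk / 0.012)^2) + 0.75 * exp(-0.5 * ((tk - 0.06) / 0.012)^2)
    wave <- -0.8 * sinpulse(tk, 0.12, 0.35)
  } else {
    sg <- 0.015 + 0.006 * (id - 2L)
    spike <- exp(-0.5 * (tk / sg)^2)
    wave <- -(0.4 + 0.05 * (id %% 3)) * sinpulse(tk, 0.05 + 0.02 * (id %% 4), 0.45)
  }
  shape <- spike + wave
  shape <- shape / max(shape)
  g <- depth_profile(config)
  list(waveform = outer(g, shape), times_s = tk,
       peak_index = which.min(abs(tk)), sample_rate_hz = fs)
}

## Half-sine pulse supported on [t0, t1], zero elsewhere.
sinpulse <- function(t, t0, t1) {
  y <- numeric(length(t))
  inside <- t >= t0 & t <= t1
  y[inside] <- sin(pi * (t[inside] - t0) / (t1 - t0))
  y
}

depth_profile <- function(config) {
  g <- config$depth_gradient
  nc <- config$n_channels
  if (length(g) == nc) return(g)
  stats::approx(seq_along(g), g, xout = seq(1, length(g), length.out = nc))$y
}

## 1/f^a noise of length n with unit standard deviation.
colored_noise <- function(n, exponent) {
  m <- nextn(n, c(2, 3, 5))
  white <- rnorm(m)
  x <- fft(white)
  f <- c(1, seq_len(m - 1))  # avoid 0; DC handled below
  f <- pmin(f, m - f + 1)    # symmetric frequency index
  scale <- f^(-exponent / 2)
  scale[1] <- 0
  x <- x * scale
  y <- Re(fft(x, inverse = TRUE)) / m
  y <- y[seq_len(n)]
  (y - mean(y)) / sd(y)
}

#' Simulate a multichannel LFP recording with embedded IEDs
#'
#' Background = 1/f noise plus a stage-dependent slow oscillation; IEDs are
#' injected at inhomogeneous-Poisson times whose intensity and amplitude
#' follow the per-stage multipliers, with a hard-core minimum separation
#' enforced by thinning. Artefact intervals receive broadband
#' high-amplitude noise. Every injection is listed in the ground truth.
#'
#' @param config a [sim_config()].
#' @param hypnogram optional hypnogram; generated from `config` when absent.
#' @return List with `recording` (an [recording()] object), `ground_truth`
#'   (data.frame `time_s`, `template_id`, `stage`, `amplitude_uv`),
#'   `artefacts` (interval data.frame) and `hypnogram`.
#' @export
generate_recording <- function(config, hypnogram = NULL) {
  validate_sim_config(config)
  if (is.null(hypnogram)) hypnogram <- generate_hypnogram(config)
  fs <- config$sample_rate_hz
  n <- round(config$duration_s * fs)
  nc <- config$n_channels
  lambda_max <- config$ied_base_rate_per_min / 60 * max(config$ied_rate_mult)
  if (lambda_max > 0 && lambda_max >= 1 / config$ied_min_separation_s)
    stop("IED rate too high for the configured minimum separation")
  g <- depth_profile(config)

  events <- with_seed(config$seed + 2L, draw_ied_times(config, hypnogram))

  samples <- with_seed(config$seed + 3L, {
    s <- matrix(0, nc, n)
    for (c in seq_len(nc))
      s[c, ] <- config$noise_rms_uv * colored_noise(n, config$noise_exponent)
    ## stage-dependent slow oscillation, coherent across depth
    tt <- (seq_len(n) - 1) / fs
    swa <- numeric(n)
    for (i in seq_len(nrow(hypnogram))) {
      i0 <- floor(hypnogram$onset_s[i] * fs) + 1
      i1 <- min(floor(hypnogram$offset_s[i] * fs), n)
      if (i1 < i0) next
      amp <- config$swa_amp_uv[[hypnogram$stage[i]]]
      swa[i0:i1] <- amp * sin(2 * pi * config$swa_freq_hz * tt[i0:i1] + runif(1, 0, 2 * pi))
    }
    s + outer(g, swa)
  })

  ## inject kernels at ground-truth times (peak-aligned)
  kernels <- lapply(seq_len(config$n_templates), make_ied_kernel, config = config)
  if (nrow(events)) {
    for (e in seq_len(nrow(events))) {
      k <- kernels[[events$template_id[e]]]
      ipk <- round(events$time_s[e] * fs) + 1
      idx <- (ipk - k$peak_index + 1):(ipk - k$peak_index + length(k$times_s))
      ok <- idx >= 1 & idx <= n
      samples[, idx[ok]] <- samples[, idx[ok]] +
        events$amplitude_uv[e] * k$waveform[, ok, drop = FALSE]
    }
  }

  artefacts <- with_seed(config$seed + 4L, {
    na <- rpois(1, config$artefact_rate_per_hour * config$duration_s / 3600)
    if (na == 0) {
      data.frame(onset_s = numeric(0), offset_s = numeric(0), label = character(0))
    } else {
      on <- sort(runif(na, 0, config$duration_s - 3 * config$artefact_duration_s))
      len <- rexp(na, 1 / config$artefact_duration_s) + 0.2
      data.frame(onset_s = on, offset_s = pmin(on + len, config$duration_s),
                 label = "artefact")
    }
  })
  if (nrow(artefacts)) {
    with_seed(config$seed + 5L, {
      for (i in seq_len(nrow(artefacts))) {
        i0 <- floor(artefacts$onset_s[i] * fs) + 1
        i1 <- min(floor(artefacts$offset_s[i] * fs), n)
        samples[, i0:i1] <- samples[, i0:i1] +
          matrix(rnorm(nc * (i1 - i0 + 1), sd = 300), nc)
      }
    })
  }

  rec <- recording(samples, fs)
  list(recording = rec, ground_truth = events, artefacts = artefacts,
       hypnogram = hypnogram)
}

## Stage-modulated Poisson IED times with hard-core thinning and an edge
## margin wide enough for epoch extraction.
draw_ied_times <- function(config, hypnogram) {
  base <- config$ied_base_rate_per_min / 60
  times <- numeric(0)
  if (base > 0) {
    for (i in seq_len(nrow(hypnogram))) {
      lambda <- base * config$ied_rate_mult[[hypnogram$stage[i]]]
      len <- hypnogram$offset_s[i] - hypnogram$onset_s[i]
      k <- rpois(1, lambda * len)
      if (k > 0) times <- c(times, runif(k, hypnogram$onset_s[i], hypnogram$offset_s[i]))
    }
  }
  times <- sort(times)
  margin <- 1.0
  times <- times[times > margin & times < config$duration_s - margin]
  keep <- logical(length(times))
  last <- -Inf
  for (j in seq_along(times)) {
    if (times[j] - last >= config$ied_min_separation_s) {
      keep[j] <- TRUE
      last <- times[j]
    }
  }
  times <- round(times[keep] * config$sample_rate_hz) / config$sample_rate_hz
  if (!length(times)) {
    return(data.frame(time_s = numeric(0), template_id = integer(0),
                      stage = character(0), amplitude_uv = numeric(0)))
  }
  stg <- stage_of_time(hypnogram, times)
  tid <- sample.int(config$n_templates, length(times), replace = TRUE)
  amp <- config$ied_amplitude_uv *
    unlist(config$ied_amp_mult[stg], use.names = FALSE) *
    exp(rnorm(length(times), 0, config$ied_amp_jitter_sdlog))
  data.frame(time_s = times, template_id = tid, stage = stg, amplitude_uv = amp)
}

#' Simulate unit spike trains coupled to IEDs
#'
#' Each unit is an inhomogeneous Poisson process whose intensity is the
#' stage-dependent baseline multiplied by a PDS-like gain around every IED:
#' `g_spike` inside the spike window and `g_wave` inside the slow-wave
#' window. Doublet injection (probability `burst_prob` per spike) creates
#' inter-spike intervals below 5 ms; a per-spike amplitude mark is drawn
#' with a stage-dependent mean.
#'
#' @param config a [sim_config()].
#' @param ground_truth IED ground truth from [generate_recording()].
#' @param hypnogram stage intervals the trains should follow.
#' @return Named list of spike trains (`unit_id`, `quality`,
#'   `spike_times_s`, `amplitude`).
#' @export
generate_spike_trains <- function(config, ground_truth, hypnogram) {
  validate_sim_config(config)
  ied <- ground_truth$time_s
  with_seed(config$seed + 6L, {
    trains <- vector("list", config$n_units)
    for (u in seq_len(config$n_units)) {
      base <- config$unit_baseline_hz[u]
      lam_max <- base * max(config$unit_stage_mult) * max(config$g_spike, 1)
      ncand <- rpois(1, lam_max * config$duration_s)
      cand <- sort(runif(ncand, 0, config$duration_s))
      lam <- base * unlist(config$unit_stage_mult[stage_of_time(hypnogram, cand)],
                           use.names = FALSE)
      lam[is.na(lam)] <- base
      lam <- lam * ied_gain_at(cand, ied, config)
      acc <- cand[runif(ncand) < lam / lam_max]
      ## doublets: a second spike 2-4 ms after the parent
      parents <- acc[runif(length(acc)) < config$burst_prob]
      extra <- parents + runif(length(parents), 0.002, 0.004)
      t <- sort(c(acc, extra))
      t <- t[t < config$duration_s]
      t <- t[c(TRUE, diff(t) > 1e-5)]
      stg <- stage_of_time(hypnogram, t)
      ampm <- unlist(config$unit_amp_mult[stg], use.names = FALSE)
      ampm[is.na(ampm)] <- 1
      trains[[u]] <- list(
        unit_id = sprintf("unit%02d", u),
        quality = if (u %% 3 == 0) "MUA" else "SUA",
        spike_times_s = t,
        amplitude = 50 * ampm * exp(rnorm(length(t), 0, 0.05)))
    }
    names(trains) <- vapply(trains, `[[`, "", "unit_id")
    trains
  })
}

## Multiplicative PDS gain at times t given sorted IED peak times.
ied_gain_at <- function(t, ied, config) {
  gain <- rep(1, length(t))
  if (!length(ied)) return(gain)
  idx <- findInterval(t, ied)
  sw <- config$spike_gain_window_s
  ww <- config$wave_gain_window_s
  for (shift in 0:1) {
    ## relative to the previous IED (shift 0) and the next one (shift 1),
    ## enough reach since windows span < min separation
    ref <- ifelse(idx + shift >= 1 & idx + shift <= length(ied),
                  ied[pmax(pmin(idx + shift, length(ied)), 1)], NA)
    rel <- t - ref
    gain[!is.na(rel) & rel >= sw[1] & rel < sw[2]] <- config$g_spike
    gain[!is.na(rel) & rel >= ww[1] & rel < ww[2]] <- config$g_wave
  }
  gain
}

#' Simulate a full recording session
#'
#' Convenience wrapper producing the hypnogram, LFP recording with ground
#' truth, artefacts, and unit spike trains for one seeded configuration.
#'
#' @param config a [sim_config()].
#' @return List with `config`, `hypnogram`, `recording`, `ground_truth`,
#'   `artefacts`, `spike_trains`.
#' @export
simulate_session <- function(config) {
  hyp <- generate_hypnogram(config)
  rec <- generate_recording(config, hyp)
  trains <- generate_spike_trains(config, rec$ground_truth, hyp)
  list(config = config, hypnogram = hyp, recording = rec$recording,
       ground_truth = rec$ground_truth, artefacts = rec$artefacts,
       spike_trains = trains)
}
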