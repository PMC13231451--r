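#' Segment a recording into non-overlapping 10 s windows
#'
#' Windows are labelled with a sleep stage under the strict majority
#' (>50\%) rule, and flagged excluded when they overlap an artefact by any
#' amount; in `"baseline"` mode windows containing an IED are excluded as
#' well, so the surviving windows measure background activity free of
#' interictal events.
#'
#' @param duration_s recording duration in seconds (or an
#'   [recording()] object).
#' @param hypnogram stage intervals.
#' @param artefacts artefact intervals (`NULL` for none).
#' @param ied_times IED event times (used in `"baseline"` mode).
#' @param window_s window length (seconds, default 10).
#' @param mode `"all"` or `"baseline"`.
#' @return data.frame `onset_s`, `offset_s`, `stage`, `excluded`,
#'   `reason`, with attribute `n_excluded` per reason.
#' @export
segment_windows <- function(duration_s, hypnogram, artefacts = NULL,
                            ied_times = NULL, window_s = 10,
                            mode = c("all", "baseline")) {
  mode <- match.arg(mode)
  if (inherits(duration_s, "ied_recording"))
    duration_s <- recording_duration(duration_s)
  onsets <- seq(0, duration_s - window_s, by = window_s)
  w <- data.frame(onset_s = onsets, offset_s = onsets + window_s)
  w$stage <- stage_at(hypnogram, w$onset_s, w$offset_s)
  w$excluded <- FALSE
  w$reason <- NA_character_
  if (!is.null(artefacts) && nrow(artefacts)) {
    for (i in seq_len(nrow(artefacts))) {
      hit <- overlap_length(w$onset_s, w$offset_s,
                            artefacts$onset_s[i], artefacts$offset_s[i]) > 0
      w$excluded <- w$excluded | hit
      w$reason[hit & is.na(w$reason)] <- "artefact"
    }
  }
  if (mode == "baseline" && length(ied_times)) {
    idx <- floor(ied_times / window_s) + 1
    idx <- idx[idx >= 1 & idx <= nrow(w)]
    hit <- seq_len(nrow(w)) %in% idx
    w$reason[hit & is.na(w$reason)] <- "ied"
    w$excluded <- w$excluded | hit
  }
  attr(w, "n_excluded") <- table(w$reason, useNA = "no")
  w
}

#' Hann-tapered FFT power spectrum of one window
#'
#' Removes the mean, applies a periodic Hann taper, and returns the
#' one-sided power spectrum on the natural frequency grid (0.1 Hz spacing
#' for a 10 s window at any sample rate). Powers are normalized by the
#' window energy so that the sum over all bins equals the variance of the
#' tapered signal (Parseval), in uV^2.
#'
#' @param x numeric samples of one window (no NaNs).
#' @param fs sample rate (Hz).
#' @return List with `freq_hz` and `power`.
#' @export
window_power <- function(x, fs) {
  if (anyNA(x)) stop("window contains NaN samples")
  n <- length(x)
  w <- hann_window(n)
  xw <- w * (x - mean(x))
  X <- fft(xw)
  p <- Mod(X)^2 / (n * sum(w^2))
  half <- floor(n / 2) + 1
  one <- p[seq_len(half)]
  if (n %% 2 == 0) {
    one[2:(half - 1)] <- 2 * one[2:(half - 1)]
  } else {
    one[2:half] <- 2 * one[2:half]
  }
  list(freq_hz = (seq_len(half) - 1) * fs / n, power = one)
}

#' Mean band power of a spectrum
#'
#' Mean of the power bins with `lo <= f <= hi` (inclusive edges). The
#' slow-wave activity band (0.1--2.5 Hz) starts above 0 Hz, so the DC bin
#' never contributes.
#'
#' @param spectrum result of [window_power()].
#' @param lo,hi band edges (Hz).
#' @return Mean power in the band (uV^2).
#' @export
band_power <- function(spectrum, lo, hi) {
  sel <- spectrum$freq_hz >= lo - 1e-9 & spectrum$freq_hz <= hi + 1e-9
  if (!any(sel)) stop("no frequency bins inside the band")
  mean(spectrum$power[sel])
}

#' Band powers of every window and channel
#'
#' @param rec an [recording()] object.
#' @param windows window table from [segment_windows()]; excluded windows
#'   are skipped.
#' @param bands named list of `c(lo, hi)` band edges (defaults: SWA
#'   0.1--2.5 Hz, delta 2.5--4 Hz).
#' @param channels channel indices (default all).
#' @return data.frame, one row per window x channel, with `onset_s`,
#'   `stage`, `channel` and one column per band.
#' @export
window_power_table <- function(rec, windows,
                               bands = list(swa = c(0.1, 2.5), delta = c(2.5, 4)),
                               channels = NULL) {
  fs <- rec$sample_rate_hz
  channels <- channels %||% seq_len(nrow(rec$samples))
  keep <- which(!windows$excluded)
  rows <- vector("list", length(keep) * length(channels))
  k <- 0L
  for (i in keep) {
    i0 <- floor(windows$onset_s[i] * fs) + 1
    i1 <- i0 + round((windows$offset_s[i] - windows$onset_s[i]) * fs) - 1
    for (ch in channels) {
      sp <- window_power(rec$samples[ch, i0:i1], fs)
      bp <- lapply(bands, function(b) band_power(sp, b[1], b[2]))
      k <- k + 1L
      rows[[k]] <- cbind(data.frame(onset_s = windows$onset_s[i],
                                    stage = windows$stage[i], channel = ch),
                         as.data.frame(bp))
    }
  }
  out <- do.call(rbind, rows[seq_len(k)])
  rownames(out) <- NULL
  out
}

#' Power relative to the pre-sleep period
#'
#' Divides each value column by the mean over the pre-sleep windows of the
#' same channel, the normalization that makes stages comparable across
#' patients and contacts.
#'
#' @param tbl window table (e.g. from [window_power_table()]) with a
#'   `stage` column and a `channel` column.
#' @param cols value columns to normalize.
#' @param ref reference stage (default `"Pre"`).
#' @return `tbl` with the columns replaced by relative values.
#' @export
relative_power <- function(tbl, cols, ref = "Pre") {
  if (!any(tbl$stage == ref, na.rm = TRUE))
    stop(sprintf("no '%s' windows to normalize against", ref))
  for (ch in unique(tbl$channel)) {
    in_ch <- tbl$channel == ch
    for (cl in cols) {
      m <- mean(tbl[[cl]][in_ch & tbl$stage == ref], na.rm = TRUE)
      if (!is.finite(m) || m == 0) stop("reference mean is zero or undefined")
      tbl[[cl]][in_ch] <- tbl[[cl]][in_ch] / m
    }
  }
  tbl
}

#' CV2: local variability of inter-spike intervals
#'
#' Mean over consecutive interval pairs of
#' `2 * |ISI[i+1] - ISI[i]| / (ISI[i+1] + ISI[i])`. A perfectly periodic
#' train gives exactly 0, a Poisson train 1 in expectation, and bursty
#' firing pushes values above 1. The statistic is invariant to rescaling
#' all intervals by a common factor. At least two intervals are required;
#' otherwise the value is undefined (`NA`).
#'
#' @param isi numeric vector of inter-spike intervals (seconds, all > 0).
#' @return Numeric scalar in `[0, 2]`, or `NA` with fewer than 2
#'   intervals.
#' @export
cv2 <- function(isi) {
  if (any(isi <= 0)) stop("non-positive inter-spike interval (duplicate spike times?)")
  n <- length(isi)
  if (n < 2) return(NA_real_)
  a <- isi[-n]
  b <- isi[-1]
  mean(2 * abs(b - a) / (b + a))
}

#' Burst detection by inter-spike interval cutoff
#'
#' A burst is a maximal run of spikes whose consecutive inter-spike
#' intervals are all strictly below `cutoff_s` (default 5 ms), involving
#' at least two spikes. An interval of exactly 5 ms does not start a
#' burst.
#'
#' @param spike_times_s sorted spike times (seconds).
#' @param cutoff_s ISI cutoff (seconds).
#' @return data.frame with one row per burst: `start_index`, `n_spikes`,
#'   `onset_s`, `offset_s`.
#' @export
detect_bursts <- function(spike_times_s, cutoff_s = 0.005) {
  n <- length(spike_times_s)
  empty <- data.frame(start_index = integer(0), n_spikes = integer(0),
                      onset_s = numeric(0), offset_s = numeric(0))
  if (n < 2) return(empty)
  inburst <- diff(spike_times_s) < cutoff_s
  if (!any(inburst)) return(empty)
  r <- rle(inburst)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  idx <- which(r$values)
  data.frame(start_index = starts[idx],
             n_spikes = r$lengths[idx] + 1L,
             onset_s = spike_times_s[starts[idx]],
             offset_s = spike_times_s[ends[idx] + 1L])
}

#' Burst-corrected spike train
#'
#' Keeps only the first spike of every burst, removing the bursting
#' action potentials beyond it; inter-spike intervals and firing rates on
#' the corrected train are "burst-corrected".
#'
#' @param spike_times_s sorted spike times (seconds).
#' @param cutoff_s ISI cutoff (seconds, default 5 ms).
#' @return The corrected spike time vector.
#' @export
correct_bursts <- function(spike_times_s, cutoff_s = 0.005) {
  if (length(spike_times_s) < 2) return(spike_times_s)
  spike_times_s[c(TRUE, diff(spike_times_s) >= cutoff_s)]
}

#' Firing metrics of one unit in one window
#'
#' Firing rate (spikes / window length), CV2 over the intervals fully
#' inside the window (undefined below 3 spikes), burst rate (bursts per
#' second), burst-corrected rate, and the mean spike amplitude when marks
#' are present. An empty window yields rate 0 with CV2 absent.
#'
#' @param spike_times_s the unit's spike times (seconds).
#' @param onset_s,offset_s window bounds (half-open).
#' @param amplitudes optional per-spike amplitude marks aligned with
#'   `spike_times_s`.
#' @param burst_cutoff_s burst ISI cutoff.
#' @return One-row data.frame: `n_spikes`, `firing_rate`, `cv2`,
#'   `burst_rate`, `corrected_rate`, `mean_amplitude`.
#' @export
unit_window_metrics <- function(spike_times_s, onset_s, offset_s,
                                amplitudes = NULL, burst_cutoff_s = 0.005) {
  len <- offset_s - onset_s
  if (len <= 0) stop("malformed window")
  sel <- spike_times_s >= onset_s & spike_times_s < offset_s
  t <- spike_times_s[sel]
  isi <- diff(t)
  data.frame(
    n_spikes = length(t),
    firing_rate = length(t) / len,
    cv2 = if (length(t) >= 3) cv2(isi) else NA_real_,
    burst_rate = nrow(detect_bursts(t, burst_cutoff_s)) / len,
    corrected_rate = length(correct_bursts(t, burst_cutoff_s)) / len,
    mean_amplitude = if (!is.null(amplitudes) && any(sel))
      mean(amplitudes[sel]) else NA_real_)
}

#' Window metrics table for a set of units
#'
#' @param trains named list of spike trains (as from
#'   [generate_spike_trains()] or [read_spike_trains()]).
#' @param windows window table from [segment_windows()]; excluded windows
#'   are skipped.
#' @return data.frame, one row per window x unit, with the window stage
#'   and all [unit_window_metrics()] columns.
#' @export
unit_window_table <- function(trains, windows) {
  keep <- which(!windows$excluded)
  rows <- list()
  for (u in names(trains)) {
    tr <- trains[[u]]
    for (i in keep) {
      m <- unit_window_metrics(tr$spike_times_s, windows$onset_s[i],
                               windows$offset_s[i], tr$amplitude)
      rows[[length(rows) + 1]] <- cbind(
        data.frame(onset_s = windows$onset_s[i], stage = windows$stage[i],
                   unit = u, quality = tr$quality %||% NA_character_), m)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
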