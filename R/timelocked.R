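#' Baseline-corrected average LFP around IEDs
#'
#' Subtracts each epoch's per-channel baseline mean (over
#' `[-0.15, -0.05]` s by default) and averages over epochs. Stage-split
#' averages can be requested with per-epoch stage labels; component
#' intervals are meant to be measured on the all-stage average only, so
#' that latency choices are independent of any sleep-stage analysis.
#'
#' @param epochs an `ied_epochs` object (n >= 2).
#' @param baseline baseline window (seconds, relative to the event).
#' @param by_stage split averages by stage as well.
#' @param stages character vector of per-epoch stage labels (required when
#'   `by_stage`).
#' @return Object of class `lfp_average`: `mean` (channels x time),
#'   `times_s`, `n_epochs`, `sample_rate_hz`, and `by_stage` (named list
#'   of per-stage `mean`/`n`) when requested.
#' @export
average_lfp <- function(epochs, baseline = c(-0.15, -0.05), by_stage = FALSE,
                        stages = NULL) {
  n <- dim(epochs$trials)[1]
  if (n < 2) stop("averaging needs at least 2 epochs")
  times <- epoch_times(epochs)
  bl <- times >= baseline[1] & times < baseline[2]
  if (!any(bl)) stop("baseline window lies outside the epoch")
  corrected <- epochs$trials
  for (i in seq_len(n)) {
    tr <- matrix(corrected[i, , ], nrow = dim(corrected)[2])
    corrected[i, , ] <- tr - rowMeans(tr[, bl, drop = FALSE])
  }
  out <- list(mean = apply(corrected, c(2, 3), mean), times_s = times,
              n_epochs = n, sample_rate_hz = epochs$sample_rate_hz,
              baseline = baseline)
  if (by_stage) {
    if (is.null(stages)) stop("stage-split averages need per-epoch stage labels")
    if (length(stages) != n) stop("one stage label per epoch required")
    out$by_stage <- lapply(split(seq_len(n), stages), function(idx) {
      list(mean = apply(corrected[idx, , , drop = FALSE], c(2, 3), mean),
           n = length(idx))
    })
  }
  structure(out, class = "lfp_average")
}

epoch_times <- function(epochs) {
  epochs$window[1] + (seq_len(dim(epochs$trials)[3]) - 1) / epochs$sample_rate_hz
}

#' Spike and slow-wave component intervals of the average IED
#'
#' On the reference (deepest) channel of the all-stage average, the spike
#' interval is the contiguous span containing the global maximum within
#' the spike search window where the trace is at or above half the
#' maximum; the slow-wave interval is the contiguous span containing the
#' global minimum within the wave search window where the trace is at or
#' below half the minimum. `V_peak` and `V_SW` are the mean amplitudes
#' over those intervals; the deflection is their difference. Intervals
#' are invariant to positive amplitude scaling.
#'
#' @param avg an `lfp_average`.
#' @param channel reference channel (default 1, the deepest contact).
#' @param spike_window search window for the spike (seconds).
#' @param wave_window search window for the slow wave; the default
#'   `[0.05, 0.5]` s places it after the spike.
#' @return List with `spike_interval`, `wave_interval` (each `c(t_on,
#'   t_off)` seconds, `NA` when undefined), `V_peak`, `V_SW`,
#'   `deflection`, `channel` and `flags`.
#' @export
find_component_intervals <- function(avg, channel = 1,
                                     spike_window = c(-0.15, 0.15),
                                     wave_window = c(0.05, 0.5)) {
  stopifnot(inherits(avg, "lfp_average"))
  v <- avg$mean[channel, ]
  t <- avg$times_s
  flags <- character(0)

  half_span <- function(window, sign) {
    idx <- which(t >= window[1] & t <= window[2])
    vv <- sign * v[idx]
    ext <- max(vv)
    if (ext <= 0) return(NULL)
    ## relative epsilon so samples lying exactly at half-extremum (up to
    ## float rounding) are included
    above <- vv >= ext / 2 - 1e-9 * ext
    i_ext <- which.max(vv)
    lo <- i_ext
    while (lo > 1 && above[lo - 1]) lo <- lo - 1
    hi <- i_ext
    while (hi < length(vv) && above[hi + 1]) hi <- hi + 1
    list(interval = c(t[idx[lo]], t[idx[hi]]), mean = sign * mean(vv[lo:hi]))
  }

  spike <- half_span(spike_window, +1)
  wave <- half_span(wave_window, -1)
  if (is.null(spike)) flags <- c(flags, "spike interval undefined (max <= 0)")
  if (is.null(wave)) flags <- c(flags, "wave interval undefined (min >= 0)")
  list(spike_interval = if (!is.null(spike)) spike$interval else c(NA_real_, NA_real_),
       wave_interval = if (!is.null(wave)) wave$interval else c(NA_real_, NA_real_),
       V_peak = if (!is.null(spike)) spike$mean else NA_real_,
       V_SW = if (!is.null(wave)) wave$mean else NA_real_,
       deflection = if (!is.null(spike) && !is.null(wave)) spike$mean - wave$mean else NA_real_,
       channel = channel, flags = flags)
}

#' Per-event LFP component measures for stage-wise statistics
#'
#' Applies the spike/wave intervals (measured once on the all-stage
#' average) to every baseline-corrected epoch, yielding one row per event
#' with `V_peak`, `V_SW` and `deflection` on the reference channel, plus
#' the stage label and any identifier columns, ready for the
#' mixed-effects stage contrasts. Events without a stage label are
#' dropped and counted.
#'
#' @param epochs an `ied_epochs` object.
#' @param stages per-epoch stage labels.
#' @param intervals result of [find_component_intervals()].
#' @param ids optional data.frame of per-epoch identifiers (patient,
#'   night, template, ...), recycled row-wise.
#' @param channel reference channel.
#' @param baseline baseline window used for the correction.
#' @return data.frame, one row per labelled event, with attribute
#'   `n_dropped`.
#' @export
stage_component_measures <- function(epochs, stages, intervals, ids = NULL,
                                     channel = 1, baseline = c(-0.15, -0.05)) {
  n <- dim(epochs$trials)[1]
  if (length(stages) != n) stop("one stage label per epoch required")
  t <- epoch_times(epochs)
  bl <- t >= baseline[1] & t < baseline[2]
  si <- intervals$spike_interval
  wi <- intervals$wave_interval
  spike_idx <- which(t >= si[1] & t <= si[2])
  wave_idx <- which(t >= wi[1] & t <= wi[2])
  v <- epochs$trials[, channel, , drop = FALSE][, 1, ]
  if (n == 1) v <- matrix(v, nrow = 1)
  v <- v - rowMeans(v[, bl, drop = FALSE])
  out <- data.frame(
    event_time_s = epochs$times_s, stage = stages,
    V_peak = rowMeans(v[, spike_idx, drop = FALSE]),
    V_SW = rowMeans(v[, wave_idx, drop = FALSE]))
  out$deflection <- out$V_peak - out$V_SW
  if (!is.null(ids)) out <- cbind(out, ids[rep_len(seq_len(nrow(ids)), n), , drop = FALSE])
  keep <- !is.na(out$stage)
  res <- out[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_dropped") <- sum(!keep)
  res
}

#' Pearson correlation between the average LFP and a PSTH
#'
#' The LFP (reference channel of the average) is downsampled to the PSTH
#' time axis by averaging the samples falling in each 10 ms bin, then the
#' Pearson correlation over common bins is returned.
#'
#' @param avg an `lfp_average`.
#' @param psth an `ied_psth` (see [compute_psth()]).
#' @param channel reference LFP channel.
#' @return Pearson correlation coefficient.
#' @export
lfp_psth_correlation <- function(avg, psth, channel = 1) {
  v <- avg$mean[channel, ]
  t <- avg$times_s
  edges <- psth$bin_edges
  nb <- length(edges) - 1
  binned <- rep(NA_real_, nb)
  for (b in seq_len(nb)) {
    idx <- t >= edges[b] & t < edges[b + 1]
    if (any(idx)) binned[b] <- mean(v[idx])
  }
  common <- which(!is.na(binned))
  if (length(common) < 3) stop("fewer than 3 common bins")
  cor(binned[common], psth$mean_rate[common])
}
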