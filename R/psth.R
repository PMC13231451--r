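#' Peri-stimulus time histogram of a spike train around events
#'
#' Bins spike times relative to each event into half-open 10 ms bins
#' (counts divided by the bin width give rates in Hz), and derives the
#' mean PSTH and the normalized PSTH (mean rate divided by the mean
#' baseline rate). A spike exactly at the event time lands in the
#' `[0, 10)` ms bin.
#'
#' @param spike_times_s sorted spike times (seconds).
#' @param event_times_s sorted event times (seconds).
#' @param window PSTH window relative to the event (seconds); the bin
#'   width must divide it.
#' @param bin_s bin width (seconds, default 0.010).
#' @param baseline baseline window (seconds); only bins fully inside it
#'   count.
#' @return Object of class `ied_psth`: `rates` (events x bins, Hz),
#'   `bin_edges`, `bin_centers`, `mean_rate`, `baseline_per_event`,
#'   `baseline_mean`, `norm_rate` (`NA` with a flag when the baseline
#'   rate is 0), `n_events`.
#' @export
compute_psth <- function(spike_times_s, event_times_s, window = c(-0.5, 1.0),
                         bin_s = 0.010, baseline = c(-0.3, -0.1)) {
  nb <- (window[2] - window[1]) / bin_s
  if (abs(nb - round(nb)) > 1e-9) stop("bin width must divide the window")
  nb <- round(nb)
  edges <- window[1] + bin_s * (0:nb)
  n <- length(event_times_s)
  if (n < 1) stop("no events")
  counts <- matrix(0, n, nb)
  spikes <- sort(spike_times_s)
  for (i in seq_len(n)) {
    lo <- findInterval(event_times_s[i] + window[1], spikes) + 1
    hi <- findInterval(event_times_s[i] + window[2] - 1e-12, spikes)
    if (hi >= lo) {
      rel <- spikes[lo:hi] - event_times_s[i]
      b <- floor((rel - window[1]) / bin_s) + 1
      b <- b[b >= 1 & b <= nb]
      tb <- tabulate(b, nbins = nb)
      counts[i, ] <- tb
    }
  }
  rates <- counts / bin_s
  bl_bins <- which(edges[-length(edges)] >= baseline[1] - 1e-9 &
                   edges[-1] <= baseline[2] + 1e-9)
  baseline_per_event <- rowMeans(rates[, bl_bins, drop = FALSE])
  baseline_mean <- mean(baseline_per_event)
  mean_rate <- colMeans(rates)
  norm_rate <- if (baseline_mean > 0) mean_rate / baseline_mean else rep(NA_real_, nb)
  structure(list(rates = rates, bin_edges = edges,
                 bin_centers = edges[-length(edges)] + bin_s / 2,
                 bin_s = bin_s, window = window, baseline_window = baseline,
                 baseline_bins = bl_bins, baseline_per_event = baseline_per_event,
                 baseline_mean = baseline_mean, mean_rate = mean_rate,
                 norm_rate = norm_rate,
                 flag = if (baseline_mean > 0) NULL else "zero baseline rate",
                 n_events = n),
            class = "ied_psth")
}

#' Cluster-based permutation test of IED responsiveness
#'
#' Tests where the firing rate deviates from the event's own baseline:
#' per bin, a one-sample t statistic of the baseline-subtracted responses
#' across events; contiguous bins exceeding the first-level threshold
#' (two-sided p < `alpha_cluster`) form clusters scored by their summed t
#' values; cluster masses are referred to a seeded permutation null. By
#' default every cluster is compared against the permutation distribution
#' of the maximum absolute cluster mass over both polarities, which keeps
#' the family-wise error at `alpha`; `null = "per-tail"` compares
#' positive and negative clusters against their own one-sided maxima
#' instead. A unit is responsive when any cluster's p-value is below
#' `alpha`.
#'
#' Spike counts in 10 ms bins are sparse, which makes naive choices
#' anticonservative (a bin with accidentally few spikes has a small mean
#' *and* a small standard deviation -- the "spurious significance from
#' lack of data" problem). Three defaults keep the type-I error at its
#' nominal level on null units: a square-root variance-stabilizing
#' transform of the rates (`transform = "sqrt"`), a pooled standard
#' deviation over all bins (`variance = "pooled"`; under the null of
#' stationary firing all bins share one variance), and a rotation null
#' (`null_method = "rotation"`): each permutation circularly shifts every
#' event's binned response by an independent random offset and re-anchors
#' it to its shifted baseline window -- the classical shift-predictor
#' construction, exact under the null of no time-locking. Sign flipping
#' of the baseline-subtracted responses (`null_method = "sign-flip"`) is
#' available but anticonservative on skewed sparse counts. Degenerate
#' input (no variance anywhere) skips the test and returns
#' non-responsive.
#'
#' @param psth an `ied_psth` with at least 10 events.
#' @param alpha_cluster first-level (per-bin) two-sided threshold.
#' @param alpha cluster-level threshold.
#' @param n_perm number of permutations.
#' @param seed seed for the permutation draw.
#' @param null `"common"` (max |mass| over both polarities) or
#'   `"per-tail"`.
#' @param null_method `"rotation"` (default) or `"sign-flip"`.
#' @param transform `"sqrt"` (variance-stabilizing, default) or `"none"`.
#' @param variance `"pooled"` (one sd across all bins, default) or
#'   `"per-bin"`.
#' @return Object of class `cluster_test`: `clusters` (data.frame with
#'   bin range, times, mass, sign, p), `responsive`, `n_perm`, `skipped`.
#' @export
cluster_permutation_test <- function(psth, alpha_cluster = 0.01, alpha = 0.05,
                                     n_perm = 10000, seed = 1,
                                     null = c("common", "per-tail"),
                                     null_method = c("rotation", "sign-flip"),
                                     transform = c("sqrt", "none"),
                                     variance = c("pooled", "per-bin")) {
  null <- match.arg(null)
  null_method <- match.arg(null_method)
  transform <- match.arg(transform)
  variance <- match.arg(variance)
  stopifnot(inherits(psth, "ied_psth"))
  n <- psth$n_events
  if (n < 10) stop("cluster permutation test needs >= 10 events")
  x <- if (transform == "sqrt") sqrt(psth$rates) else psth$rates
  x <- x - rowMeans(x[, psth$baseline_bins, drop = FALSE])
  nb <- ncol(x)
  sd_pool <- sd(x)
  sdb <- if (variance == "pooled") rep(sd_pool, nb) else apply(x, 2, sd)
  if (all(sdb == 0)) {
    return(structure(list(clusters = data.frame(), responsive = FALSE,
                          n_perm = n_perm, skipped = TRUE),
                     class = "cluster_test"))
  }
  tobs <- ifelse(sdb > 0, colMeans(x) / (sdb / sqrt(n)), 0)
  tcrit <- qt(1 - alpha_cluster / 2, n - 1)

  cl <- find_clusters(tobs, tcrit)
  if (!nrow(cl)) {
    return(structure(list(clusters = cl, responsive = FALSE,
                          n_perm = n_perm, skipped = FALSE),
                     class = "cluster_test"))
  }

  maxima <- with_seed(seed, {
    if (null_method == "rotation") {
      rotation_null_maxima(x, psth$baseline_bins, n_perm, tcrit, variance)
    } else {
      sign_flip_null_maxima(x, n_perm, tcrit, variance, sd_pool)
    }
  })
  if (null == "common") {
    null_mass <- pmax(maxima$pos, maxima$neg)
    cl$p <- vapply(abs(cl$mass),
                   function(m) (sum(null_mass >= m) + 1) / (n_perm + 1), 0)
  } else {
    cl$p <- vapply(seq_len(nrow(cl)), function(i) {
      nm <- if (cl$sign[i] > 0) maxima$pos else maxima$neg
      (sum(nm >= abs(cl$mass[i])) + 1) / (n_perm + 1)
    }, 0)
  }
  responsive <- any(cl$p < alpha)
  structure(list(clusters = cl,
                 responsive = responsive,
                 direction = if (responsive)
                   paste(unique(ifelse(cl$sign[cl$p < alpha] > 0,
                                       "increase", "decrease")), collapse = "+")
                   else NA_character_,
                 n_perm = n_perm, skipped = FALSE, tcrit = tcrit, t = tobs),
            class = "cluster_test")
}

## Shift-predictor null: every permutation rotates each event's binned
## response by an independent circular offset and re-anchors it to the
## mean over its (rotated) baseline bins; exact under stationarity.
rotation_null_maxima <- function(x, bl_bins, n_perm, tcrit, variance) {
  n <- nrow(x)
  nb <- ncol(x)
  msum <- matrix(0, n_perm, nb)     # sum over events of anchored rotations
  ssq <- numeric(n_perm)            # running sum of squared entries
  stot <- numeric(n_perm)           # running sum of entries
  col_off <- 0:(nb - 1)
  for (i in seq_len(n)) {
    k <- sample.int(nb, n_perm, replace = TRUE) - 1L
    x2 <- c(x[i, ], x[i, ])
    xr <- matrix(x2[outer(k, col_off, "+") + 1L], n_perm, nb)
    anchor <- rowMeans(xr[, bl_bins, drop = FALSE])
    xr <- xr - anchor
    msum <- msum + xr
    if (variance == "pooled") {
      ssq <- ssq + rowSums(xr^2)
      stot <- stot + rowSums(xr)
    }
  }
  m <- msum / n
  if (variance == "pooled") {
    nn <- n * nb
    v <- (ssq - stot^2 / nn) / (nn - 1)
    tm <- m / sqrt(pmax(v, .Machine$double.eps) / n)
  } else {
    ## per-bin variances are not tracked under rotation; fall back to the
    ## observed per-bin sd as a fixed scale
    sdb <- apply(x, 2, sd)
    sdb[sdb == 0] <- Inf
    tm <- sweep(m, 2, sdb / sqrt(n), "/")
  }
  max_cluster_mass(tm, tcrit)
}

## Sign-flip null on the baseline-subtracted responses.
sign_flip_null_maxima <- function(x, n_perm, tcrit, variance, sd_pool) {
  n <- nrow(x)
  nb <- ncol(x)
  signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  m <- signs %*% x / n
  tm <- if (variance == "pooled") {
    ## the pooled sd is invariant under sign flips (squares unchanged)
    m / (sd_pool / sqrt(n))
  } else {
    ss <- colSums(x^2)
    v <- (matrix(ss, n_perm, nb, byrow = TRUE) - n * m^2) / (n - 1)
    m / sqrt(pmax(v, .Machine$double.eps) / n)
  }
  max_cluster_mass(tm, tcrit)
}

## Contiguous supra-threshold runs of a t trace, both polarities.
find_clusters <- function(t_trace, tcrit) {
  out <- list()
  for (sign in c(1, -1)) {
    above <- sign * t_trace > tcrit
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      out[[length(out) + 1]] <- data.frame(
        bin_lo = starts[k], bin_hi = ends[k],
        mass = sum(t_trace[starts[k]:ends[k]]), sign = sign)
    }
  }
  if (!length(out)) {
    return(data.frame(bin_lo = integer(0), bin_hi = integer(0),
                      mass = numeric(0), sign = numeric(0)))
  }
  do.call(rbind, out)
}

## Row-wise maximum positive and negative cluster masses of a permutation
## t matrix (n_perm x bins), via a running sum that resets outside
## supra-threshold runs.
max_cluster_mass <- function(tm, tcrit) {
  n_perm <- nrow(tm)
  run_p <- maxp <- numeric(n_perm)
  run_n <- maxn <- numeric(n_perm)
  for (j in seq_len(ncol(tm))) {
    tj <- tm[, j]
    run_p <- (run_p + tj) * (tj > tcrit)
    run_n <- (run_n - tj) * (-tj > tcrit)
    maxp <- pmax(maxp, run_p)
    maxn <- pmax(maxn, run_n)
  }
  list(pos = maxp, neg = maxn)
}

#' Half-prominence intervals of the mean PSTH
#'
#' Determines the comparison latencies for stage-wise firing statistics
#' independently of sleep stage: the peak interval is the contiguous run
#' of bins around the PSTH maximum that stay within half the peak's
#' prominence (measured against the baseline rate); the trough interval
#' is the analogous run around the minimum. A flat PSTH is flagged as
#' undefined.
#'
#' @param psth an `ied_psth`, or a numeric mean-rate vector (then
#'   `baseline_level` is required).
#' @param baseline_level reference rate used as the prominence baseline;
#'   defaults to the PSTH's baseline mean.
#' @return List with `peak_interval` and `trough_interval` (each `bins`
#'   plus `t_on`/`t_off` when a PSTH was supplied; `NULL` when
#'   undefined) and `flags`.
#' @export
half_prominence_intervals <- function(psth, baseline_level = NULL) {
  if (inherits(psth, "ied_psth")) {
    rate <- psth$mean_rate
    baseline_level <- baseline_level %||% psth$baseline_mean
    centers <- psth$bin_centers
  } else {
    rate <- psth
    if (is.null(baseline_level)) stop("baseline_level required for a bare rate vector")
    centers <- NULL
  }
  flags <- character(0)
  if (max(rate) == min(rate)) {
    return(list(peak_interval = NULL, trough_interval = NULL,
                flags = "flat PSTH: intervals undefined"))
  }
  span <- function(sign) {
    vv <- sign * (rate - baseline_level)
    prom <- max(vv)
    if (prom <= 0) return(NULL)
    i_ext <- which.max(vv)
    above <- vv >= prom / 2
    lo <- i_ext
    while (lo > 1 && above[lo - 1]) lo <- lo - 1
    hi <- i_ext
    while (hi < length(vv) && above[hi + 1]) hi <- hi + 1
    out <- list(bins = lo:hi)
    if (!is.null(centers)) {
      out$t_on <- centers[lo]
      out$t_off <- centers[hi]
    }
    out
  }
  peak <- span(+1)
  trough <- span(-1)
  if (is.null(peak)) flags <- c(flags, "no peak above baseline")
  if (is.null(trough)) flags <- c(flags, "no trough below baseline")
  list(peak_interval = peak, trough_interval = trough, flags = flags)
}

#' Per-stage PSTH measures for stage-wise statistics
#'
#' For one unit, splits events by sleep stage, computes the per-stage
#' PSTH, and extracts the mean firing rate inside the peak and trough
#' intervals (determined once, stage-blind), the stage baseline rate, and
#' the baseline-normalized peak-trough difference. One row per stage with
#' at least `min_events` events.
#'
#' @param spike_times_s the unit's spike times.
#' @param event_times_s IED times.
#' @param stages stage label per event.
#' @param intervals result of [half_prominence_intervals()] on the
#'   all-stage PSTH.
#' @param window,bin_s,baseline as in [compute_psth()].
#' @param min_events minimum events per stage (default 10).
#' @param ids optional one-row data.frame of identifiers to attach.
#' @return data.frame with columns `stage`, `n_events`, `rate_spike`,
#'   `rate_wave`, `rate_baseline`, `norm_difference`.
#' @export
psth_stage_measures <- function(spike_times_s, event_times_s, stages,
                                intervals, window = c(-0.5, 1.0),
                                bin_s = 0.010, baseline = c(-0.3, -0.1),
                                min_events = 10, ids = NULL) {
  stopifnot(length(stages) == length(event_times_s))
  if (is.null(intervals$peak_interval) || is.null(intervals$trough_interval))
    stop("peak/trough intervals undefined")
  rows <- list()
  for (stg in unique(stages[!is.na(stages)])) {
    ev <- event_times_s[!is.na(stages) & stages == stg]
    if (length(ev) < min_events) next
    p <- compute_psth(spike_times_s, ev, window, bin_s, baseline)
    rs <- mean(p$mean_rate[intervals$peak_interval$bins])
    rw <- mean(p$mean_rate[intervals$trough_interval$bins])
    rows[[length(rows) + 1]] <- data.frame(
      stage = stg, n_events = length(ev), rate_spike = rs, rate_wave = rw,
      rate_baseline = p$baseline_mean,
      norm_difference = if (p$baseline_mean > 0) (rs - rw) / p$baseline_mean
                        else NA_real_)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(stage = character(0), n_events = integer(0),
               rate_spike = numeric(0), rate_wave = numeric(0),
               rate_baseline = numeric(0), norm_difference = numeric(0))
  if (!is.null(ids) && nrow(out)) out <- cbind(out, ids)
  rownames(out) <- NULL
  out
}
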