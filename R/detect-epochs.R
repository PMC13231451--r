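#' Extract peri-event epochs from a recording
#'
#' Cuts `[-0.5, +1.0)` s windows (by default) around annotated event times
#' at the recording's sample rate, on the configured subset of deepest
#' contacts. Events too close to the recording edges are dropped with a
#' warning. Sample indexing is 0-based floor(t * fs), so an event at 10 s
#' at 1 kHz occupies samples `[9500, 11000)`.
#'
#' @param rec an [recording()] object.
#' @param event_times numeric event times (seconds, spike-peak convention).
#' @param window epoch window relative to the event (seconds).
#' @param channels channel indices to keep; defaults to the first (deepest)
#'   five contacts, or all channels if fewer.
#' @return Object of class `ied_epochs`: `trials` (n x channels x time
#'   array), `times_s` (event times kept), `lags_s` (alignment shifts, 0
#'   here), `window`, `sample_rate_hz`.
#' @export
extract_epochs <- function(rec, event_times, window = c(-0.5, 1.0),
                           channels = NULL) {
  stopifnot(inherits(rec, "ied_recording"))
  fs <- rec$sample_rate_hz
  channels <- channels %||% seq_len(min(5L, nrow(rec$samples)))
  nt <- round((window[2] - window[1]) * fs)
  n_samp <- ncol(rec$samples)
  i0 <- floor((event_times + window[1]) * fs) + 1
  ok <- i0 >= 1 & (i0 + nt - 1) <= n_samp
  if (!all(ok))
    warning(sprintf("%d event(s) too close to the recording edges dropped", sum(!ok)))
  event_times <- event_times[ok]
  i0 <- i0[ok]
  if (!length(event_times)) stop("no events far enough from the recording edges")
  trials <- array(0, c(length(event_times), length(channels), nt))
  for (j in seq_along(event_times))
    trials[j, , ] <- rec$samples[channels, i0[j]:(i0[j] + nt - 1)]
  structure(list(trials = trials, times_s = event_times,
                 lags_s = numeric(length(event_times)),
                 window = window, sample_rate_hz = fs, channels = channels),
            class = "ied_epochs")
}

subset_epochs <- function(epochs, idx) {
  structure(list(trials = epochs$trials[idx, , , drop = FALSE],
                 times_s = epochs$times_s[idx], lags_s = epochs$lags_s[idx],
                 window = epochs$window, sample_rate_hz = epochs$sample_rate_hz,
                 channels = epochs$channels),
            class = "ied_epochs")
}

## Flatten one trial (channels x time) by concatenating channels over time.
flatten_trial <- function(trial) as.vector(t(trial))

epochs_matrix <- function(epochs) {
  n <- dim(epochs$trials)[1]
  t(vapply(seq_len(n), function(i) flatten_trial(epochs$trials[i, , ]),
           numeric(dim(epochs$trials)[2] * dim(epochs$trials)[3])))
}

#' Iteratively align epochs to their average
#'
#' Each trial is shifted to the lag of its peak cross-correlation with the
#' current all-trial average, computed on the channel-concatenated signals;
#' the average is then recomputed and the procedure repeats until the mean
#' trial-to-average correlation stops improving or `max_iter` iterations
#' are reached. Shifted-out samples are filled by edge replication and the
#' cumulative per-trial shift is bounded to `max_lag_s`.
#'
#' @param epochs an `ied_epochs` object with at least 2 trials.
#' @param max_iter maximum alignment iterations (default 10).
#' @param max_lag_s bound on the cumulative per-trial shift (seconds).
#' @return The aligned `ied_epochs`, with `lags_s` holding the applied
#'   shift of each trial (a trial delayed by +20 ms gets lag -20 ms) and
#'   attributes `iterations` and `mean_correlation`.
#' @export
align_epochs <- function(epochs, max_iter = 10, max_lag_s = 0.15) {
  n <- dim(epochs$trials)[1]
  if (n < 2) stop("alignment needs at least 2 trials")
  fs <- epochs$sample_rate_hz
  maxlag <- round(max_lag_s * fs)
  mat <- epochs_matrix(epochs)
  if (all(mat == 0)) stop("all-zero trials cannot be aligned")
  nchan <- dim(epochs$trials)[2]
  nt <- dim(epochs$trials)[3]
  cum <- integer(n)  # applied shift per trial, samples
  best_mean_r <- -Inf
  iters <- 0L
  for (iter in seq_len(max_iter)) {
    avg <- colMeans(mat)
    lag_hat <- integer(n)
    for (i in seq_len(n)) {
      cc <- cross_correlation_lags(avg, mat[i, ], maxlag)
      lags <- attr(cc, "lags")
      ## keep the cumulative shift within the guard
      feasible <- abs(cum[i] - lags) <= maxlag
      cc[!feasible] <- -Inf
      lag_hat[i] <- lags[which.max(cc)]
    }
    if (all(lag_hat == 0)) {
      ## fixed point: the set is already aligned to its average
      iters <- iter
      avg_new <- colMeans(mat)
      best_mean_r <- mean(apply(mat, 1, function(x) {
        if (sd(x) == 0 || sd(avg_new) == 0) 0 else cor(x, avg_new)
      }))
      break
    }
    ## shift trials left by lag_hat (undo their delay)
    for (i in seq_len(n)) {
      if (lag_hat[i] == 0) next
      tr <- matrix(mat[i, ], nrow = nt)     # time x channels
      tr <- t(shift_columns(t(tr), -lag_hat[i]))
      mat[i, ] <- as.vector(tr)
      cum[i] <- cum[i] - lag_hat[i]
    }
    avg_new <- colMeans(mat)
    mean_r <- mean(apply(mat, 1, function(x) {
      if (sd(x) == 0 || sd(avg_new) == 0) 0 else cor(x, avg_new)
    }))
    iters <- iter
    if (mean_r <= best_mean_r + 1e-12) break
    best_mean_r <- mean_r
  }
  ## anchor the solution: alignment-to-average is only determined up to a
  ## global shift, so re-centre on the median lag (the majority of trials
  ## stays put)
  g <- round(median(cum))
  if (g != 0) {
    for (i in seq_len(n)) {
      tr <- matrix(mat[i, ], nrow = nt)
      mat[i, ] <- as.vector(t(shift_columns(t(tr), -g)))
      cum[i] <- cum[i] - g
    }
  }
  out <- epochs
  for (i in seq_len(n))
    out$trials[i, , ] <- matrix(mat[i, ], nrow = nt)[, seq_len(nchan)] |> t()
  out$lags_s <- cum / fs
  attr(out, "iterations") <- iters
  attr(out, "mean_correlation") <- best_mean_r
  out
}

#' Cluster epochs into k medoid waveform classes
#'
#' k-medoids (PAM, Euclidean distance on the flattened channels x time
#' trials) with automatic pruning: clusters holding less than `min_frac` of
#' the patient's total trial count are removed and the clustering repeats
#' on the remainder (same `k` while enough trials remain), up to
#' `max_rounds` prune-and-recluster rounds.
#'
#' @param epochs an `ied_epochs` object (n >= 2).
#' @param k number of clusters (default 6).
#' @param min_frac minimum cluster size as a fraction of the total trial
#'   count (default 0.025).
#' @param max_rounds cap on prune-and-recluster rounds.
#' @return List with `labels` (cluster id per original trial, `NA` for
#'   pruned trials), `epochs` (the retained trials), `removed` (indices of
#'   pruned trials) and `medoids` (row indices into the retained trials).
#' @export
cluster_epochs <- function(epochs, k = 6, min_frac = 0.025, max_rounds = 10) {
  n_total <- dim(epochs$trials)[1]
  if (n_total < 2) stop("clustering needs at least 2 trials")
  mat <- epochs_matrix(epochs)
  keep <- seq_len(n_total)
  labels <- rep(NA_integer_, n_total)
  med <- NULL
  for (round in seq_len(max_rounds)) {
    kk <- min(k, length(keep))
    if (kk >= length(keep)) {
      cl <- seq_along(keep)   # one trial per medoid
      med <- seq_along(keep)
    } else {
      fit <- cluster::pam(stats::dist(mat[keep, , drop = FALSE]), kk,
                          pamonce = 5, cluster.only = FALSE)
      cl <- fit$clustering
      med <- fit$id.med
    }
    counts <- tabulate(cl, nbins = max(cl))
    small <- which(counts > 0 & counts < min_frac * n_total)
    if (!length(small) || round == max_rounds) {
      labels[] <- NA_integer_
      labels[keep] <- cl
      break
    }
    keep <- keep[!cl %in% small]
    if (length(keep) < 2) stop("pruning removed too many trials")
  }
  list(labels = labels, epochs = subset_epochs(epochs, !is.na(labels)),
       removed = which(is.na(labels)), medoids = med)
}

#' Build per-cluster IED templates
#'
#' Each cluster is re-aligned to its own average (same procedure as
#' [align_epochs()]) and then averaged over trials, giving one
#' channels x time template per surviving cluster. Clusters with fewer
#' than 2 members are skipped with a warning.
#'
#' @param epochs the retained `ied_epochs`.
#' @param labels cluster label per retained trial.
#' @param align re-align each cluster before averaging (default TRUE).
#' @return Object of class `ied_templates`: `templates` (list of
#'   channels x time matrices), `member_counts`, `peak_offset_s` (time
#'   from template start to the spike peak on the deepest channel),
#'   `window`, `sample_rate_hz`.
#' @export
build_templates <- function(epochs, labels, align = TRUE) {
  labels <- labels[!is.na(labels)]
  if (length(labels) != dim(epochs$trials)[1])
    stop("one label per retained trial required")
  ids <- sort(unique(labels))
  templates <- list()
  counts <- integer(0)
  for (id in ids) {
    idx <- which(labels == id)
    if (length(idx) < 2) {
      warning(sprintf("cluster %d has < 2 members; skipped", id))
      next
    }
    sub <- subset_epochs(epochs, idx)
    if (align && length(idx) >= 2) sub <- align_epochs(sub)
    templates[[length(templates) + 1]] <- apply(sub$trials, c(2, 3), mean)
    counts <- c(counts, length(idx))
  }
  if (!length(templates)) stop("no cluster with >= 2 members")
  fs <- epochs$sample_rate_hz
  peak_off <- vapply(templates, function(tpl) (which.max(tpl[1, ]) - 1) / fs, 0)
  structure(list(templates = templates, member_counts = counts,
                 peak_offset_s = peak_off, window = epochs$window,
                 sample_rate_hz = fs),
            class = "ied_templates")
}

#' @export
print.ied_templates <- function(x, ...) {
  cat(sprintf("<ied_templates> %d template(s), %d x %d (channels x samples), members: %s\n",
              length(x$templates), nrow(x$templates[[1]]), ncol(x$templates[[1]]),
              paste(x$member_counts, collapse = ", ")))
  invisible(x)
}
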