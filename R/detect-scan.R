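#' Scan a recording with IED templates by normalized cross-correlation
#'
#' At every time lag the Pearson correlation is computed between the full
#' channels x time template (all channels, flattened) and the equally
#' shaped signal segment starting at that lag; the template slides along
#' time only, with channels fully overlapped. Detections are local maxima
#' of the correlation trace exceeding the threshold, with a minimum peak
#' separation of 50 ms per template; the reported detection time is the
#' correlation-peak lag plus the template's spike-peak offset, i.e. the
#' IED spike peak. Zero-variance segments get correlation 0.
#'
#' The trace is computed exactly (FFT-accelerated sliding sums), matching
#' the naive per-lag Pearson correlation to numerical precision, and is
#' invariant to scaling/offsetting of the signal (`a * x + b`, `a > 0`).
#'
#' @param rec an [recording()] object.
#' @param templates an `ied_templates` object.
#' @param threshold correlation threshold: a number (shared by all
#'   templates), a vector (one per template), or `NULL` to choose it
#'   automatically (see `threshold_method`).
#' @param threshold_method automated surrogate for the visually determined
#'   patient-specific threshold. `"valley"` (default) collects candidate
#'   correlation peaks above a per-template robust floor
#'   (median + `threshold_z` MAD) and places one shared threshold at the
#'   Otsu split of the pooled peak-height distribution, i.e. in the
#'   valley between the background/sidelobe mode and the true-match mode;
#'   `"mad"` uses the per-template robust floor directly.
#' @param threshold_z robust z of the floor (default 6).
#' @param min_peak_sep_s minimum separation between correlation peaks of
#'   one template (seconds).
#' @param channels channels of the recording to scan (must match the
#'   template's channel count); defaults to the first `nrow(template)`.
#' @param keep_traces return the full correlation traces (memory-heavy on
#'   long recordings).
#' @return Object of class `ied_scan`: `detections` (data.frame `time_s`,
#'   `template_id`, `r`, sorted by time), `thresholds`, `threshold_method`,
#'   and, when requested, `traces` (list of numeric vectors) with
#'   `trace_times_s` giving the lag axis (segment start times).
#' @export
scan_templates <- function(rec, templates, threshold = NULL,
                           threshold_method = c("valley", "mad"),
                           threshold_z = 6, min_peak_sep_s = 0.05,
                           channels = NULL, keep_traces = FALSE) {
  threshold_method <- match.arg(threshold_method)
  stopifnot(inherits(rec, "ied_recording"), inherits(templates, "ied_templates"))
  fs <- rec$sample_rate_hz
  nchan <- nrow(templates$templates[[1]])
  channels <- channels %||% seq_len(nchan)
  if (length(channels) != nchan) stop("channel subset must match template channels")
  x <- rec$samples[channels, , drop = FALSE]
  nsig <- ncol(x)
  ntpl <- ncol(templates$templates[[1]])
  if (ntpl >= nsig) stop("template must be shorter than the recording")
  nlag <- nsig - ntpl + 1
  m <- nextn(nsig, c(2, 3, 5))

  ## shared per-channel FFTs and sliding sums of the signal
  fx <- vector("list", nchan)
  s1 <- numeric(nlag)
  s2 <- numeric(nlag)
  for (c in seq_len(nchan)) {
    fx[[c]] <- fft(c(x[c, ], numeric(m - nsig)))
    cs <- cumsum(c(0, x[c, ]))
    cs2 <- cumsum(c(0, x[c, ]^2))
    s1 <- s1 + (cs[(ntpl + 1):(nsig + 1)] - cs[1:nlag])
    s2 <- s2 + (cs2[(ntpl + 1):(nsig + 1)] - cs2[1:nlag])
  }
  npts <- nchan * ntpl
  var_x <- pmax(s2 - s1^2 / npts, 0)

  detections <- list()
  traces <- if (keep_traces) vector("list", length(templates$templates))
  auto <- is.null(threshold)
  floors <- numeric(length(templates$templates))
  thresholds <- if (auto) floors else rep_len(threshold, length(templates$templates))
  for (mdx in seq_along(templates$templates)) {
    tpl <- templates$templates[[mdx]]
    tplc <- tpl - mean(tpl)
    ss_k <- sum(tplc^2)
    num <- numeric(nlag)
    for (c in seq_len(nchan)) {
      k <- c(tplc[c, ], numeric(m - ntpl))
      cc <- Re(fft(Conj(fft(k)) * fx[[c]], inverse = TRUE)) / m
      num <- num + cc[1:nlag]
    }
    denom <- sqrt(ss_k * var_x)
    r <- ifelse(denom > 0, num / denom, 0)
    r <- pmin(pmax(r, -1), 1)
    if (auto) {
      floors[mdx] <- choose_threshold(r, z = threshold_z)
      thresholds[mdx] <- floors[mdx]
    }
    pk <- find_peaks(r, thresholds[mdx], round(min_peak_sep_s * fs))
    if (length(pk)) {
      detections[[length(detections) + 1]] <- data.frame(
        time_s = (pk - 1) / fs + templates$peak_offset_s[mdx],
        template_id = mdx, r = r[pk])
    }
    if (keep_traces) traces[[mdx]] <- r
  }
  det <- if (length(detections)) do.call(rbind, detections) else
    data.frame(time_s = numeric(0), template_id = integer(0), r = numeric(0))
  method <- "fixed"
  if (auto) {
    if (threshold_method == "valley" && nrow(det) >= 10) {
      valley <- choose_threshold(det$r, method = "valley")
      thresholds <- pmax(thresholds, valley)
      det <- det[det$r > valley, , drop = FALSE]
      method <- sprintf("valley (Otsu on peaks above median + %g * MAD)", threshold_z)
    } else {
      method <- sprintf("median + %g * MAD", threshold_z)
    }
  }
  det <- det[order(det$time_s), , drop = FALSE]
  rownames(det) <- NULL
  out <- list(detections = det, thresholds = thresholds, floors = floors,
              threshold_method = method)
  if (keep_traces) {
    out$traces <- traces
    out$trace_times_s <- (seq_len(nlag) - 1) / fs
  }
  structure(out, class = "ied_scan")
}

## Local maxima above `threshold`, thinned to a minimum separation (in
## samples) keeping the highest peaks first.
find_peaks <- function(r, threshold, min_sep) {
  n <- length(r)
  if (n < 3) return(integer(0))
  cand <- which(r[2:(n - 1)] > r[1:(n - 2)] & r[2:(n - 1)] >= r[3:n]) + 1L
  cand <- cand[r[cand] > threshold]
  if (!length(cand) || min_sep <= 1) return(sort(cand))
  cand <- cand[order(r[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in cand) {
    if (!length(kept) || all(abs(kept - i) >= min_sep)) kept <- c(kept, i)
  }
  sort(kept)
}

#' Automated correlation threshold
#'
#' Surrogates for a visually chosen patient-specific threshold, all blind
#' to sleep stage. `"mad"`: the median of the correlation trace plus `z`
#' robust standard deviations (normal-consistent MAD). `"quantile"`: a
#' fixed quantile of the trace. `"valley"`: given the heights of candidate
#' correlation peaks, the Otsu split that separates the low
#' (background and self-similarity sidelobe) mode from the high
#' (true template match) mode -- the automated analogue of eyeballing the
#' bimodal distribution of correlation values. `"fixed"` returns the
#' supplied value unchanged. The chosen method and parameters are recorded
#' as attributes.
#'
#' @param trace numeric correlation trace, or candidate peak heights for
#'   `"valley"` (nonempty; non-constant unless `method = "fixed"`).
#' @param method `"mad"`, `"quantile"`, `"valley"` or `"fixed"`.
#' @param z robust z for `"mad"` (default 6).
#' @param q probability for `"quantile"`.
#' @param value threshold for `"fixed"` (returned unchanged).
#' @return Numeric threshold with attributes `method` and `params`.
#' @export
choose_threshold <- function(trace, method = c("mad", "quantile", "valley", "fixed"),
                             z = 6, q = 0.999, value = NULL) {
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(value)) stop("method 'fixed' needs a value")
    return(structure(value, method = "fixed", params = list(value = value)))
  }
  if (!length(trace)) stop("empty correlation trace")
  if (method == "mad") {
    m <- mad(trace)
    if (m == 0) stop("constant correlation trace: threshold undefined")
    structure(median(trace) + z * m, method = "mad", params = list(z = z))
  } else if (method == "quantile") {
    structure(unname(quantile(trace, q)), method = "quantile", params = list(q = q))
  } else {
    structure(otsu_split(trace), method = "valley", params = list())
  }
}

## Otsu's threshold: the split of a 1-D sample maximizing the
## between-class variance of the two resulting groups.
otsu_split <- function(h) {
  h <- sort(h)
  n <- length(h)
  if (n < 2 || h[1] == h[n]) stop("cannot split a constant sample")
  cs <- cumsum(h)
  i <- seq_len(n - 1)
  w0 <- i / n
  m0 <- cs[i] / i
  m1 <- (cs[n] - cs[i]) / (n - i)
  v <- w0 * (1 - w0) * (m1 - m0)^2
  k <- which.max(v)
  (h[k] + h[k + 1]) / 2
}

#' Deduplicate detections across templates
#'
#' Detections closer than `tol_s` (grouped by transitive closure over the
#' time axis) are collapsed to the one with the highest normalized
#' cross-correlation; ties are broken by the lower template id, then the
#' earlier time. The operation is idempotent.
#'
#' @param detections data.frame `time_s`, `template_id`, `r` (sorted or
#'   not; sorted output).
#' @param tol_s grouping tolerance (seconds, default 0.050).
#' @return Filtered detections with attribute `n_removed`.
#' @export
deduplicate_detections <- function(detections, tol_s = 0.05) {
  if (nrow(detections) < 2) {
    attr(detections, "n_removed") <- 0L
    return(detections)
  }
  d <- detections[order(detections$time_s), , drop = FALSE]
  grp <- cumsum(c(1, diff(d$time_s) > tol_s))
  pick <- vapply(split(seq_len(nrow(d)), grp), function(idx) {
    o <- order(-d$r[idx], d$template_id[idx], d$time_s[idx])
    idx[o[1]]
  }, 0L)
  out <- d[sort(pick), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- nrow(d) - nrow(out)
  out
}

#' Score detections against reference annotations
#'
#' Greedy one-to-one matching in order of increasing time difference,
#' within a tolerance of +-`tol_s`. The hit rate is matched references /
#' total references; the false-alarm rate is unmatched detections / total
#' detections (1 - precision).
#'
#' @param det_times detection times (seconds) or a detections data.frame.
#' @param ref_times reference event times (seconds).
#' @param tol_s matching tolerance (default 0.050 s).
#' @return Object of class `detection_score`: `n_ref`, `n_det`, `hits`,
#'   `misses`, `false_alarms`, `hit_rate`, `false_alarm_rate`, `matches`
#'   (data.frame of matched pairs), `flag` (set when `n_det` is 0).
#' @export
evaluate_detections <- function(det_times, ref_times, tol_s = 0.05) {
  if (is.data.frame(det_times)) det_times <- det_times$time_s
  det_times <- sort(det_times)
  ref_times <- sort(ref_times)
  n_det <- length(det_times)
  n_ref <- length(ref_times)
  if (n_det == 0) {
    return(structure(list(n_ref = n_ref, n_det = 0L, hits = 0L, misses = n_ref,
                          false_alarms = 0L, hit_rate = 0, false_alarm_rate = 0,
                          matches = data.frame(), flag = "no detections"),
                     class = "detection_score"))
  }
  ## candidate pairs within tolerance
  pairs <- list()
  lo <- findInterval(ref_times - tol_s, det_times) + 1
  hi <- findInterval(ref_times + tol_s, det_times)
  for (i in seq_len(n_ref)) {
    if (hi[i] >= lo[i]) {
      j <- lo[i]:hi[i]
      pairs[[length(pairs) + 1]] <- data.frame(
        ref = i, det = j, d = abs(det_times[j] - ref_times[i]))
    }
  }
  hits <- 0L
  matches <- data.frame(ref_time_s = numeric(0), det_time_s = numeric(0))
  if (length(pairs)) {
    p <- do.call(rbind, pairs)
    p <- p[p$d <= tol_s + 1e-12, , drop = FALSE]
    p <- p[order(p$d), , drop = FALSE]
    ref_used <- logical(n_ref)
    det_used <- logical(n_det)
    keep <- logical(nrow(p))
    for (k in seq_len(nrow(p))) {
      if (!ref_used[p$ref[k]] && !det_used[p$det[k]]) {
        ref_used[p$ref[k]] <- det_used[p$det[k]] <- TRUE
        keep[k] <- TRUE
      }
    }
    hits <- sum(keep)
    matches <- data.frame(ref_time_s = ref_times[p$ref[keep]],
                          det_time_s = det_times[p$det[keep]])
  }
  structure(list(n_ref = n_ref, n_det = n_det, hits = hits,
                 misses = n_ref - hits, false_alarms = n_det - hits,
                 hit_rate = if (n_ref > 0) hits / n_ref else NA_real_,
                 false_alarm_rate = (n_det - hits) / n_det,
                 matches = matches, flag = NULL),
            class = "detection_score")
}

#' @export
print.detection_score <- function(x, ...) {
  cat(sprintf("<detection_score> refs %d, detections %d: hit rate %.1f%%, false-alarm rate %.1f%%\n",
              x$n_ref, x$n_det, 100 * x$hit_rate, 100 * x$false_alarm_rate))
  invisible(x)
}

#' Full template-matching IED detector
#'
#' Runs the complete patient-specific detection chain on one recording:
#' zero-phase high-pass preprocessing (detection keys on the sharp spike
#' transient), epoch extraction at the annotated times, iterative
#' alignment, k-medoids clustering with small-cluster pruning, per-cluster
#' template building, normalized cross-correlation scanning with an
#' automated stage-blind threshold, and +-50 ms deduplication across
#' templates.
#'
#' @param rec an [recording()] object.
#' @param annotation_times manually annotated IED times (seconds).
#' @param k,min_frac clustering parameters (see [cluster_epochs()]).
#' @param highpass_hz detection passband floor (Hz); `NULL` disables the
#'   filter. The default (4 Hz) suppresses the slow-wave band so that
#'   background slow oscillations neither widen the correlation
#'   distribution nor mimic the template's wave component.
#' @param threshold_method,threshold_z see [scan_templates()].
#' @param dedup_tol_s deduplication tolerance (seconds).
#' @param window epoch window (seconds).
#' @param channels contacts to use (defaults to the 5 deepest).
#' @return List with `detections`, `templates`, `thresholds`,
#'   `threshold_method`, and counts of the intermediate stages.
#' @export
detect_ieds <- function(rec, annotation_times, k = 6, min_frac = 0.025,
                        highpass_hz = 4, threshold_method = "valley",
                        threshold_z = 6, dedup_tol_s = 0.05,
                        window = c(-0.5, 1.0), channels = NULL) {
  rec_f <- if (is.null(highpass_hz)) rec else highpass_recording(rec, highpass_hz)
  epochs <- extract_epochs(rec_f, annotation_times, window, channels)
  aligned <- align_epochs(epochs)
  cl <- cluster_epochs(aligned, k = k, min_frac = min_frac)
  tpl <- build_templates(cl$epochs, cl$labels[!is.na(cl$labels)])
  scan <- scan_templates(rec_f, tpl, threshold_method = threshold_method,
                         threshold_z = threshold_z,
                         channels = channels %||% epochs$channels)
  det <- deduplicate_detections(scan$detections, dedup_tol_s)
  list(detections = det, templates = tpl, thresholds = scan$thresholds,
       threshold_method = scan$threshold_method,
       n_annotations = length(annotation_times),
       n_epochs = dim(epochs$trials)[1],
       n_pruned = length(cl$removed),
       n_raw_detections = nrow(scan$detections))
}
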