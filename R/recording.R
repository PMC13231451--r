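#' Multichannel continuous recording
#'
#' Container for a continuous local field potential recording: a channels x
#' time matrix of samples in microvolts, a common sample rate, channel
#' labels, and the wall-clock start time (needed for circadian phase
#' mapping). Channel 1 is by convention the deepest contact.
#'
#' @param samples numeric matrix, channels x time (microvolts). `NaN`s are
#'   rejected.
#' @param sample_rate_hz sampling rate in Hz (> 0).
#' @param channel_labels character vector, one label per channel.
#' @param start_time `POSIXct` wall-clock time of the first sample.
#' @return An object of class `ied_recording`.
#' @export
recording <- function(samples, sample_rate_hz, channel_labels = NULL,
                      start_time = as.POSIXct("2024-01-01 20:00:00", tz = "UTC")) {
  if (!is.matrix(samples) || nrow(samples) < 1)
    stop("samples must be a channels x time matrix with >= 1 channel")
  if (anyNA(samples)) stop("recording contains NaN/NA samples")
  stopifnot_scalar(sample_rate_hz, "sample_rate_hz")
  if (is.null(channel_labels))
    channel_labels <- sprintf("ch%02d", seq_len(nrow(samples)))
  if (length(channel_labels) != nrow(samples))
    stop("one channel label per channel required")
  structure(
    list(samples = samples, sample_rate_hz = sample_rate_hz,
         channel_labels = channel_labels, start_time = start_time),
    class = "ied_recording")
}

#' @export
print.ied_recording <- function(x, ...) {
  cat(sprintf("<ied_recording> %d channels x %d samples @ %g Hz (%.1f s), start %s\n",
              nrow(x$samples), ncol(x$samples), x$sample_rate_hz,
              recording_duration(x), format(x$start_time)))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an `ied_recording`.
#' @return Numeric scalar, seconds.
#' @export
recording_duration <- function(rec) ncol(rec$samples) / rec$sample_rate_hz

#' Read and write recordings in the raw-binary + JSON-header dialect
#'
#' Signals are stored as little-endian float32 samples, interleaved by
#' frame (all channels of sample 1, then all channels of sample 2, ...),
#' in `<path>.bin`, with a JSON sidecar `<path>.json` holding
#' `n_channels`, `n_samples`, `sample_rate_hz`, `channel_labels`,
#' `start_time` (ISO-8601) and `dtype` (`"float32le"`). A header carrying
#' per-channel sample rates that differ is rejected as unsupported; a
#' `.bin` file shorter than the header promises is an I/O error.
#'
#' @param rec an `ied_recording`.
#' @param path path prefix (without extension).
#' @return `read_recording` returns an `ied_recording`; `write_recording`
#'   returns `path` invisibly. Round-tripping reproduces samples to
#'   float32 precision.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "ied_recording"))
  header <- list(
    dtype = "float32le",
    n_channels = nrow(rec$samples),
    n_samples = ncol(rec$samples),
    sample_rate_hz = rec$sample_rate_hz,
    channel_labels = rec$channel_labels,
    start_time = format(rec$start_time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  ## column-major write of a channels x time matrix = frame-interleaved
  writeBin(as.vector(rec$samples), con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  fs <- hdr$sample_rate_hz
  if (length(unique(fs)) > 1)
    stop("unsupported: channels with different sample rates")
  fs <- fs[1]
  nc <- as.integer(hdr$n_channels)
  ns <- as.integer(hdr$n_samples)
  bin <- paste0(path, ".bin")
  if (file.info(bin)$size < 4 * nc * ns)
    stop("truncated recording: fewer samples on disk than header declares")
  con <- file(bin, "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = nc * ns, size = 4L, endian = "little")
  samples <- matrix(x, nrow = nc, ncol = ns)
  if (anyNA(samples)) stop("recording contains NaN samples")
  recording(samples, fs, hdr$channel_labels,
            as.POSIXct(hdr$start_time, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
}

#' Read and write per-unit spike trains as JSON
#'
#' Each unit carries `unit_id`, a quality flag (`"SUA"` or `"MUA"`),
#' strictly increasing `spike_times_s`, and optionally per-spike
#' `amplitude` marks.
#'
#' @param trains list of spike-train lists.
#' @param path file path.
#' @return `read_spike_trains` returns the validated list of trains;
#'   `write_spike_trains` returns `path` invisibly.
#' @export
write_spike_trains <- function(trains, path) {
  for (tr in trains) validate_spike_train(tr)
  jsonlite::write_json(trains, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spike_trains
#' @export
read_spike_trains <- function(path) {
  trains <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(trains)) trains <- split(trains, seq_len(nrow(trains)))
  trains <- lapply(trains, function(tr) {
    tr <- as.list(tr)
    tr$spike_times_s <- as.numeric(unlist(tr$spike_times_s))
    if (!is.null(tr$amplitude)) tr$amplitude <- as.numeric(unlist(tr$amplitude))
    validate_spike_train(tr)
    tr
  })
  names(trains) <- vapply(trains, function(tr) as.character(tr$unit_id), "")
  trains
}

validate_spike_train <- function(tr) {
  if (is.null(tr$unit_id)) stop("spike train needs a unit_id")
  t <- tr$spike_times_s
  if (length(t) && any(diff(t) <= 0))
    stop("spike times must be strictly increasing")
  if (!is.null(tr$quality) && !tr$quality %in% c("SUA", "MUA"))
    stop("quality flag must be 'SUA' or 'MUA'")
  invisible(tr)
}

#' Zero-phase high-pass filter of a recording
#'
#' Attenuates frequencies below `cutoff_hz` with a Butterworth-magnitude
#' response applied in the frequency domain (zero phase, so event timing
#' is untouched). Detection-oriented preprocessing: template scanning
#' keys on the sharp (< 200 ms) spike transient, and suppressing the
#' slow-wave band prevents background slow oscillations from dominating
#' the normalized correlation on DC-coupled signals. Analyses of slow-wave
#' power or IED amplitude should use the unfiltered recording.
#'
#' @param rec an [recording()] object.
#' @param cutoff_hz -3 dB cutoff frequency (Hz).
#' @param order filter order (response `1 / (1 + (fc/f)^(2*order))`).
#' @return The filtered recording.
#' @export
highpass_recording <- function(rec, cutoff_hz, order = 2) {
  stopifnot(inherits(rec, "ied_recording"))
  stopifnot_scalar(cutoff_hz, "cutoff_hz")
  n <- ncol(rec$samples)
  m <- nextn(n, c(2, 3, 5))
  f <- c(0, seq_len(m - 1)) * (rec$sample_rate_hz / m)
  f <- pmin(f, rec$sample_rate_hz - f)
  h <- 1 / (1 + (cutoff_hz / pmax(f, 1e-12))^(2 * order))
  h[1] <- 0
  for (c in seq_len(nrow(rec$samples))) {
    x <- rec$samples[c, ]
    ## pad with the edge value to limit wrap-around transients
    xf <- Re(fft(fft(c(x, rep(x[n], m - n))) * h, inverse = TRUE)) / m
    rec$samples[c, ] <- xf[seq_len(n)]
  }
  rec
}

#' Refractory period violation fraction of a spike train
#'
#' Fraction of inter-spike intervals shorter than `cutoff_s` (default 1 ms),
#' a standard single-unit isolation quality check.
#'
#' @param spike_times_s sorted spike times (seconds).
#' @param cutoff_s refractory cutoff in seconds.
#' @return Numeric scalar in `[0, 1]` (`NA` with fewer than 2 spikes).
#' @export
rpv_fraction <- function(spike_times_s, cutoff_s = 0.001) {
  if (length(spike_times_s) < 2) return(NA_real_)
  mean(diff(spike_times_s) < cutoff_s)
}
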