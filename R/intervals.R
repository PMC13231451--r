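#' Sleep stage vocabulary
#'
#' Stage labels used by the package: the pre-sleep block, wake after sleep
#' onset, NREM stages S1--S3, REM sleep, and the post-sleep block.
#'
#' @return Character vector of the seven stage labels.
#' @export
stage_levels <- function() STAGES

#' Validate a set of labelled time intervals
#'
#' Intervals are half-open `[onset_s, offset_s)` in seconds from recording
#' start. Hypnogram (stage) intervals must be ordered and non-overlapping;
#' artefact intervals may overlap other annotations but must still be
#' well-formed.
#'
#' @param x data.frame with columns `onset_s`, `offset_s` and a label column
#'   (`stage` or `label`).
#' @param overlap_ok logical; allow intervals to overlap each other.
#' @return `x`, invisibly, after validation.
#' @export
validate_intervals <- function(x, overlap_ok = FALSE) {
  if (!is.data.frame(x) || !all(c("onset_s", "offset_s") %in% names(x)))
    stop("intervals must be a data.frame with columns onset_s and offset_s")
  if (nrow(x) == 0) return(invisible(x))
  if (any(!is.finite(x$onset_s)) || any(!is.finite(x$offset_s)))
    stop("interval bounds must be finite")
  if (any(x$offset_s <= x$onset_s))
    stop("intervals must satisfy onset_s < offset_s")
  if (!overlap_ok) {
    o <- order(x$onset_s)
    if (any(x$onset_s[o][-1] < x$offset_s[o][-nrow(x)]))
      stop("intervals overlap")
  }
  invisible(x)
}

#' Stage label of time windows under the strict majority rule
#'
#' A window is labelled with a sleep stage only when that stage covers
#' strictly more than `min_frac` of the window's duration; windows split
#' across stages with no strict majority get `NA`. Interval logic is
#' half-open, so a window `[30, 40)` touching a stage boundary at 40 s does
#' not overlap the next stage.
#'
#' @param hypnogram data.frame with `onset_s`, `offset_s`, `stage`.
#' @param onset_s,offset_s numeric vectors of window bounds (recycled to a
#'   common length).
#' @param min_frac minimum stage overlap as a fraction of window length;
#'   the stage must exceed this strictly (default 0.5).
#' @return Character vector of stage labels (`NA` where no stage qualifies).
#' @export
stage_at <- function(hypnogram, onset_s, offset_s, min_frac = 0.5) {
  validate_intervals(hypnogram)
  if (!"stage" %in% names(hypnogram)) stop("hypnogram needs a 'stage' column")
  n <- max(length(onset_s), length(offset_s))
  onset_s <- rep_len(onset_s, n)
  offset_s <- rep_len(offset_s, n)
  if (any(offset_s <= onset_s)) stop("malformed window: offset_s <= onset_s")
  labs <- unique(hypnogram$stage)
  ov <- matrix(0, n, length(labs), dimnames = list(NULL, labs))
  for (i in seq_len(nrow(hypnogram))) {
    ov[, hypnogram$stage[i]] <- ov[, hypnogram$stage[i]] +
      overlap_length(onset_s, offset_s, hypnogram$onset_s[i], hypnogram$offset_s[i])
  }
  best <- max.col(ov, ties.method = "first")
  frac <- ov[cbind(seq_len(n), best)] / (offset_s - onset_s)
  out <- labs[best]
  out[frac <= min_frac] <- NA_character_
  out
}

#' Stage label at single time points
#'
#' Point-in-interval lookup against half-open stage intervals: a time lying
#' exactly on an offset belongs to the next interval.
#'
#' @param hypnogram data.frame with `onset_s`, `offset_s`, `stage`.
#' @param times_s numeric vector of time points (seconds).
#' @return Character vector of stage labels (`NA` outside all intervals).
#' @export
stage_of_time <- function(hypnogram, times_s) {
  validate_intervals(hypnogram)
  out <- rep(NA_character_, length(times_s))
  for (i in seq_len(nrow(hypnogram))) {
    hit <- times_s >= hypnogram$onset_s[i] & times_s < hypnogram$offset_s[i]
    out[hit] <- hypnogram$stage[i]
  }
  out
}

#' Drop events or windows that overlap excluded intervals
#'
#' Any overlap at all with an excluded interval (artefact, seizure) removes
#' the item: point events are dropped when they fall inside an interval
#' (half-open), windows when their intersection has positive length.
#'
#' @param x data.frame of point events (column `time_s`) or windows
#'   (columns `onset_s`, `offset_s`).
#' @param intervals data.frame of excluded intervals (`onset_s`, `offset_s`);
#'   may be `NULL` or empty (identity).
#' @return Filtered `x` with attribute `n_dropped` giving the number of
#'   removed rows.
#' @export
exclude_overlaps <- function(x, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0) {
    attr(x, "n_dropped") <- 0L
    return(x)
  }
  validate_intervals(intervals, overlap_ok = TRUE)
  if ("time_s" %in% names(x)) {
    drop <- rep(FALSE, nrow(x))
    for (i in seq_len(nrow(intervals)))
      drop <- drop | (x$time_s >= intervals$onset_s[i] & x$time_s < intervals$offset_s[i])
  } else if (all(c("onset_s", "offset_s") %in% names(x))) {
    drop <- rep(FALSE, nrow(x))
    for (i in seq_len(nrow(intervals)))
      drop <- drop | overlap_length(x$onset_s, x$offset_s,
                                    intervals$onset_s[i], intervals$offset_s[i]) > 0
  } else {
    stop("x must have a 'time_s' column or 'onset_s'/'offset_s' columns")
  }
  out <- x[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(drop)
  out
}

#' Read or write a hypnogram TSV
#'
#' Tab-separated file with header `onset_s  offset_s  stage`, UTF-8, `.`
#' decimal mark; times in seconds from recording start, intervals half-open.
#'
#' @param path file path.
#' @param hypnogram data.frame with columns `onset_s`, `offset_s`, `stage`.
#' @return `read_hypnogram` returns the validated data.frame;
#'   `write_hypnogram` returns `path` invisibly.
#' @export
read_hypnogram <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  validate_intervals(x)
  x
}

#' @rdname read_hypnogram
#' @export
write_hypnogram <- function(hypnogram, path) {
  validate_intervals(hypnogram)
  write.table(hypnogram, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write an event annotation TSV
#'
#' Point events (IED detections, seizures, ground-truth injections) with
#' columns `onset_s` (the event time, spike-peak convention), `label`, and
#' optionally `template_id` and `stage`. In memory the time column is named
#' `time_s`.
#'
#' @param path file path.
#' @param events data.frame with column `time_s` plus optional columns.
#' @return `read_events` returns a data.frame sorted by time with column
#'   `time_s`; `write_events` returns `path` invisibly.
#' @export
read_events <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  if (!"onset_s" %in% names(x)) stop("events TSV needs an 'onset_s' column")
  names(x)[names(x) == "onset_s"] <- "time_s"
  x[order(x$time_s), , drop = FALSE]
}

#' @rdname read_events
#' @export
write_events <- function(events, path) {
  if (!"time_s" %in% names(events)) stop("events need a 'time_s' column")
  out <- events
  names(out)[names(out) == "time_s"] <- "onset_s"
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
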