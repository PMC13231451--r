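#' Time-of-day phase of events
#'
#' Maps event times (seconds from recording start) to circular phase
#' angles on the 24 h clock: local midnight is 0, 06:00 is pi/2, and
#' events exactly 24 h apart share an angle.
#'
#' @param times_s event times in seconds from recording start.
#' @param start_time `POSIXct` wall-clock time of the recording start
#'   (required).
#' @return Numeric vector of angles in `[0, 2*pi)`.
#' @export
phase_of_day <- function(times_s, start_time) {
  if (missing(start_time) || is.null(start_time) || anyNA(start_time))
    stop("recording start_time is required for circadian phase")
  tz <- attr(start_time, "tzone") %||% "UTC"
  midnight <- as.POSIXct(format(start_time, "%Y-%m-%d"), tz = tz)
  s0 <- as.numeric(difftime(start_time, midnight, units = "secs"))
  2 * pi * (((s0 + times_s) %% 86400) / 86400)
}

#' Rayleigh test of circular uniformity
#'
#' Mean resultant length `Rbar`, test statistic `z = n * Rbar^2`, and the
#' finite-sample approximation of the p-value
#' `p = exp(sqrt(1 + 4n + 4(n^2 - R^2)) - (1 + 2n))` with `R = n * Rbar`
#' (Zar's approximation). Also reports the circular mean and median
#' angles. Rotating all angles by a constant rotates the mean angle and
#' leaves `Rbar` and `p` unchanged.
#'
#' @param angles numeric angles in radians (n >= 2).
#' @return List with `n`, `Rbar`, `z`, `p`, `mean_angle`, `median_angle`.
#' @export
rayleigh_test <- function(angles) {
  n <- length(angles)
  if (n < 2) stop("Rayleigh test needs at least 2 angles")
  C <- mean(cos(angles))
  S <- mean(sin(angles))
  rbar <- sqrt(C^2 + S^2)
  z <- n * rbar^2
  R <- n * rbar
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  p <- min(max(p, 0), 1)
  mean_angle <- if (rbar > 0) atan2(S, C) %% (2 * pi) else NA_real_
  list(n = n, Rbar = rbar, z = z, p = p,
       mean_angle = mean_angle, median_angle = circular_median(angles))
}

## Circular median: the sample angle minimizing the mean circular
## distance to all angles (first such angle on ties).
circular_median <- function(angles) {
  a <- angles %% (2 * pi)
  cost <- vapply(a, function(m) {
    d <- abs(a - m) %% (2 * pi)
    mean(pmin(d, 2 * pi - d))
  }, 0)
  a[which.min(cost)]
}

#' Circadian histogram of event times
#'
#' Counts events in time-of-day bins pooled over all recording days, for
#' polar display of the 24 h distribution; optionally normalized to a
#' rate per hour given the total recorded duration.
#'
#' @param times_s event times in seconds from recording start.
#' @param start_time `POSIXct` recording start.
#' @param bin_minutes bin width in minutes; must divide 24 h.
#' @param duration_s total recording duration (needed for `rate`).
#' @param rate also return events per hour of bin coverage.
#' @return data.frame with `bin_start_hr`, `count`, and `rate_per_hr`
#'   when requested; counts sum to the number of events.
#' @export
circadian_profile <- function(times_s, start_time, bin_minutes = 60,
                              duration_s = NULL, rate = FALSE) {
  if (1440 %% bin_minutes != 0) stop("bin width must divide 24 h")
  nb <- 1440 / bin_minutes
  ang <- phase_of_day(times_s, start_time)
  hr <- ang / (2 * pi) * 24
  b <- floor(hr / (bin_minutes / 60)) + 1
  counts <- tabulate(b, nbins = nb)
  out <- data.frame(bin_start_hr = (seq_len(nb) - 1) * bin_minutes / 60,
                    count = counts)
  if (rate) {
    if (is.null(duration_s)) stop("duration_s required for rates")
    ## hours of coverage each time-of-day bin received
    coverage <- duration_s / 86400 * (bin_minutes / 60)
    out$rate_per_hr <- counts / coverage
  }
  out
}
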