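`%||%` <- function(x, y) if (is.null(x)) y else x

## Evaluate `code` under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

## Periodic Hann taper of length n.
hann_window <- function(n) {
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))
}

## Shift the columns (time axis) of a channels x time matrix by `shift`
## samples (positive = delay, i.e. move content to later samples), filling
## the vacated samples by edge replication.
shift_columns <- function(mat, shift) {
  if (shift == 0) return(mat)
  n <- ncol(mat)
  if (abs(shift) >= n) stop("shift exceeds signal length")
  if (shift > 0) {
    cbind(mat[, rep(1L, shift), drop = FALSE], mat[, 1:(n - shift), drop = FALSE])
  } else {
    s <- -shift
    cbind(mat[, (s + 1):n, drop = FALSE], mat[, rep(n, s), drop = FALSE])
  }
}

## Length of intersection of the half-open interval [a, b) with each of the
## half-open intervals [onset, offset).
overlap_length <- function(a, b, onset, offset) {
  pmax(0, pmin(b, offset) - pmax(a, onset))
}

## Circular cross-correlation c(l) = sum_t a(t) b(t + l) via FFT, returned
## for lags -max_lag .. max_lag (a and b same length, zero-padded).
cross_correlation_lags <- function(a, b, max_lag) {
  n <- length(a)
  m <- nextn(n + 2 * max_lag, c(2, 3, 5))
  fa <- fft(c(a, numeric(m - n)))
  fb <- fft(c(b, numeric(m - n)))
  cc <- Re(fft(Conj(fa) * fb, inverse = TRUE)) / m
  ## lag l >= 0 at index l + 1; lag l < 0 at index m + l + 1
  idx <- c((m - max_lag + 1):m, 1:(max_lag + 1))
  structure(cc[idx], lags = -max_lag:max_lag)
}

stopifnot_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name))
  if (positive && x <= 0) stop(sprintf("'%s' must be positive", name))
  invisible(x)
}
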