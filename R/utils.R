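## Shared numerical helpers: seeded substreams, kernel smoothing, the
## analytic-signal envelope used for band amplitudes, and small test-statistic
## wrappers shared by several analysis stages.

#' Derive a reproducible integer sub-seed from a root seed and a stream name
#'
#' All stochastic stages draw their randomness from one root seed through
#' named substreams so that, e.g., regenerating only the sleep session of a
#' synthetic study does not perturb the run session.
#'
#' @param seed integer root seed.
#' @param name character stream name.
#' @return an integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 7919 + h) %% 2147483647)
}

#' Gaussian kernel smoothing of a regularly sampled vector
#'
#' Kernel truncated at +/- 3 SD and renormalized at the edges so that
#' smoothing a constant returns the constant. Used for rate maps (SD in
#' spatial bins), population-rate traces (SD in time bins) and the
#' theta/delta ratio (SD in samples).
#'
#' @param x numeric vector.
#' @param sd kernel standard deviation in samples; `sd <= 0` returns `x`.
#' @return smoothed vector of the same length.
#' @export
gauss_smooth <- function(x, sd) {
  if (sd <= 0 || length(x) < 2L) return(x)
  half <- max(1L, ceiling(3 * sd))
  k <- stats::dnorm(seq(-half, half), sd = sd)
  n <- length(x)
  num <- stats::filter(c(rep(0, half), x, rep(0, half)), k, sides = 2)
  den <- stats::filter(c(rep(0, half), rep(1, n), rep(0, half)), k, sides = 2)
  out <- (num / den)[(half + 1L):(half + n)]
  as.numeric(out)
}

#' Amplitude envelope of a band-limited signal
#'
#' Computes the magnitude of the analytic signal via the frequency-domain
#' construction (positive frequencies doubled, negative zeroed). The input
#' should already be band-pass filtered.
#'
#' @param x numeric vector (real signal).
#' @return numeric vector of instantaneous amplitudes.
#' @export
envelope <- function(x) {
  n0 <- length(x)
  if (n0 < 2L) return(abs(x))
  ## zero-pad to a fast (2,3,5-smooth) FFT length; trailing pad discarded
  n <- stats::nextn(n0, c(2, 3, 5))
  xp <- c(x, numeric(n - n0))
  X <- stats::fft(xp)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)[seq_len(n0)]
}

#' Zero-phase Butterworth band-pass filter
#'
#' @param x signal vector.
#' @param fs sampling rate, Hz.
#' @param band length-2 numeric, pass band in Hz.
#' @param order filter order (default 4).
#' @return filtered vector.
#' @export
bandpass <- function(x, fs, band, order = 4L) {
  stopifnot(length(band) == 2L, band[1] > 0, band[2] < fs / 2)
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

## One-sided two-proportion z-test on pooled counts (H1: p1 > p2).
## Returns the z statistic and its one-sided p-value.
two_proportion_z <- function(x1, n1, x2, n2) {
  p <- (x1 + x2) / (n1 + n2)
  se <- sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else ((x1 / n1) - (x2 / n2)) / se
  list(z = z, p.value = stats::pnorm(z, lower.tail = FALSE))
}

## Percentile (0..1) of a value within a reference sample: fraction of the
## reference strictly below the value. Shared by all shuffle scorings.
shuffle_percentile <- function(value, reference) {
  if (!length(reference)) return(NA_real_)
  mean(reference < value)
}

## Merge a logical run-length mask into (start, end) index intervals.
mask_to_intervals <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

## Overlap length between [a1,a2] and each row of an interval matrix (seconds).
interval_overlap <- function(a1, a2, ivs) {
  if (is.null(dim(ivs)) || nrow(ivs) == 0) return(numeric(0))
  pmax(0, pmin(a2, ivs[, 2]) - pmax(a1, ivs[, 1]))
}
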