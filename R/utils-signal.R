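## Internal signal-processing primitives shared by the glove and EMG chains.

#' Construct a SampledSeries
#'
#' @param values numeric samples
#' @param fs sampling rate (Hz)
#' @param t0 time of the first sample (s)
#' @param units physical units of the samples
#' @return a \linkS4class{SampledSeries}
#' @export
sampledSeries <- function(values, fs, t0 = 0, units = "au") {
  new("SampledSeries",
    sampleTimes = t0 + (seq_along(values) - 1) / fs,
    values = as.numeric(values), fs = fs, units = units
  )
}

## zero-phase Butterworth high-pass; filtfilt doubles the effective order
butterHighpass <- function(x, fs, cutoffHz, order = 2) {
  w <- cutoffHz / (fs / 2)
  stopifnot(w > 0, w < 1)
  b <- signal::butter(order, w, type = "high")
  signal::filtfilt(b, x)
}

butterBandpass <- function(x, fs, lowHz, highHz, order = 2) {
  w <- c(lowHz, highHz) / (fs / 2)
  stopifnot(all(w > 0), all(w < 1), w[1] < w[2])
  b <- signal::butter(order, w, type = "pass")
  signal::filtfilt(b, x)
}

## IIR notch realized as a narrow Butterworth band-stop with bandwidth f0/Q
butterNotch <- function(x, fs, f0, Q = 30, order = 2) {
  bw <- f0 / Q
  w <- c(f0 - bw / 2, f0 + bw / 2) / (fs / 2)
  stopifnot(all(w > 0), all(w < 1))
  b <- signal::butter(order, w, type = "stop")
  signal::filtfilt(b, x)
}

## analytic signal via the frequency-domain Hilbert construction
analyticSignal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    if (n > 1) h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

## centred moving average with partial windows at the edges (no NA padding)
movingAverage <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width == 1L || length(x) < 2) return(x)
  half <- width %/% 2
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

## Pearson r that degrades gracefully on zero-variance input
safePearson <- function(x, y, what = "series") {
  if (length(x) != length(y))
    stop("inputs must have equal length (", length(x), " vs ", length(y), ")")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance ", what, "; correlation defined as 0")
    return(0)
  }
  stats::cor(x, y)
}

## resample a boxcar onto the grid of a series by nearest-block lookup
#' Resample a task boxcar onto the grid of a sampled series
#'
#' @param boxcar a \linkS4class{TaskBoxcar}
#' @param series a \linkS4class{SampledSeries} supplying the target grid
#' @return integer 0/1 vector, one value per sample of \code{series}
#' @export
boxcarOnGrid <- function(boxcar, series) {
  stopifnot(is(boxcar, "TaskBoxcar"), is(series, "SampledSeries"))
  t <- sampleTimes(series)
  ## block index determines the state; grid starts with rest
  blk <- floor((t %% boxcar@totalS) / boxcar@blockS)
  as.integer(blk %% 2 == 1)
}

## local seed handling: all randomness is scoped, never leaks to the session
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}
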