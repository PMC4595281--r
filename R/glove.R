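#' Drift-correct and resample a glove trace
#'
#' High-pass filters the finger-angle signal to remove slow drift (the
#' glove sensor drifts over a 6-minute run) and resamples it by linear
#' interpolation onto a uniform 15 ms grid, the temporal resolution used
#' for all downstream kinematic scoring.
#'
#' @param raw a \linkS4class{SampledSeries} (degrees).
#' @param cutoffHz drift high-pass cutoff in Hz (default 0.05; movement
#'   is ~0.5-1 Hz, so drift is removed without touching it).
#' @param targetDt output sampling interval in seconds (default 0.015).
#' @return a \linkS4class{SampledSeries} on the 15 ms grid.
#' @export
detrendResample <- function(raw, cutoffHz = 0.05, targetDt = 0.015) {
  stopifnot(is(raw, "SampledSeries"))
  dur <- length(raw@values) / raw@fs
  if (dur < 2 / cutoffHz)
    stop(
      "trace too short for drift correction: ", round(dur, 2),
      " s < two high-pass periods (", 2 / cutoffHz, " s)"
    )
  filtered <- butterHighpass(raw@values, raw@fs, cutoffHz)
  t0 <- raw@sampleTimes[1]
  nOut <- floor(dur / targetDt)
  tOut <- t0 + (seq_len(nOut) - 1) * targetDt
  vOut <- stats::approx(raw@sampleTimes, filtered, xout = tOut,
                        rule = 2)$y
  new("SampledSeries", sampleTimes = tOut, values = vOut,
      fs = 1 / targetDt, units = raw@units)
}

#' Count hand movements from a glove trace
#'
#' Counts the local maxima and minima of the movement signal and divides
#' by two, so one full flexion-extension cycle counts as one movement.
#' Extrema are detected with a hysteresis rule: an extremum is accepted
#' only when the signal swings away from it by more than a prominence
#' threshold, so measurement-noise wiggles are not counted.
#'
#' @param trace a detrended, resampled \linkS4class{SampledSeries}.
#' @param prominence swing threshold in signal units; by default
#'   \code{promFrac} of the trace's 5th-95th percentile range.
#' @param promFrac fraction used for the default prominence (0.05).
#' @return integer movement count, \code{floor((nMax + nMin)/2)}.
#' @export
countMovements <- function(trace, prominence = NULL, promFrac = 0.05) {
  stopifnot(is(trace, "SampledSeries"))
  x <- trace@values
  if (is.null(prominence)) {
    q <- stats::quantile(x, c(0.05, 0.95), names = FALSE)
    prominence <- promFrac * (q[2] - q[1])
  }
  if (prominence <= 0) return(0L)
  nExtrema <- countAlternatingExtrema(x, prominence)
  as.integer(floor(nExtrema / 2))
}

## hysteresis turning-point counter: walk the series keeping the running
## candidate extremum; commit it when the excursion since it exceeds thr
countAlternatingExtrema <- function(x, thr) {
  n <- length(x)
  if (n < 3) return(0L)
  count <- 0L
  hi <- x[1]
  lo <- x[1]
  direction <- 0L # 0 unknown, +1 seeking a maximum, -1 seeking a minimum
  for (i in 2:n) {
    xi <- x[i]
    if (direction == 0L) {
      if (xi > hi) hi <- xi
      if (xi < lo) lo <- xi
      if (hi - xi > thr) { # fell away from the running high
        direction <- -1L
        lo <- xi
      } else if (xi - lo > thr) {
        direction <- 1L
        hi <- xi
      }
    } else if (direction == 1L) {
      if (xi > hi) hi <- xi
      else if (hi - xi > thr) { # committed a maximum
        count <- count + 1L
        direction <- -1L
        lo <- xi
      }
    } else {
      if (xi < lo) lo <- xi
      else if (xi - lo > thr) { # committed a minimum
        count <- count + 1L
        direction <- 1L
        hi <- xi
      }
    }
  }
  ## the walk ends while still tracking one last uncommitted extremum
  if (direction != 0L) count <- count + 1L
  count
}

#' Envelope-boxcar compliance correlation
#'
#' Pearson correlation of the movement-signal envelope with the task
#' boxcar: a task-adherence measure (1 = the subject moved exactly when
#' and as much as cued; 0 = movement unrelated to the cue).
#'
#' @param trace a detrended, resampled \linkS4class{SampledSeries}.
#' @param boxcar a \linkS4class{TaskBoxcar}; resampled internally onto
#'   the trace grid.
#' @param smoothS envelope moving-average width in seconds.
#' @return Pearson r in [-1, 1]; zero-variance envelopes yield 0 with a
#'   warning so cohort tables never contain missing-by-computation cells.
#' @export
complianceCorrelation <- function(trace, boxcar, smoothS = 0.5) {
  stopifnot(is(trace, "SampledSeries"), is(boxcar, "TaskBoxcar"))
  env <- computeEnvelope(trace, smoothS = smoothS, source = "glove")
  box <- boxcarOnGrid(boxcar, trace)
  safePearson(env@values, box, what = "envelope")
}

#' Glove mirror-movement score
#'
#' The compliance correlation applied to the hand that was \emph{not}
#' instructed to move: a high value means the inactive hand's envelope
#' follows the task, i.e. overt mirror movements.
#'
#' @inheritParams complianceCorrelation
#' @param inactiveTrace detrended, resampled trace of the inactive hand.
#' @return Pearson r in [-1, 1] (MM_glove).
#' @export
mirrorGloveScore <- function(inactiveTrace, boxcar, smoothS = 0.5) {
  complianceCorrelation(inactiveTrace, boxcar, smoothS = smoothS)
}

#' Full kinematic scoring of one glove recording
#'
#' Convenience wrapper: detrends and resamples both hands, then computes
#' the movement count and compliance correlation of the active hand and
#' the mirror score of the inactive hand.
#'
#' @param active,inactive raw \linkS4class{SampledSeries} for the two
#'   hands (the inactive one may be NULL).
#' @param boxcar a \linkS4class{TaskBoxcar}.
#' @param ... passed to [countMovements()].
#' @return data.frame with columns \code{n_movements},
#'   \code{compliance_r}, \code{mirror_r}.
#' @export
analyzeGlove <- function(active, inactive = NULL, boxcar, ...) {
  act <- detrendResample(active)
  res <- data.frame(
    n_movements = countMovements(act, ...),
    compliance_r = complianceCorrelation(act, boxcar),
    mirror_r = NA_real_
  )
  if (!is.null(inactive)) {
    inact <- detrendResample(inactive)
    res$mirror_r <- mirrorGloveScore(inact, boxcar)
  }
  res
}
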