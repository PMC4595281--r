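#' Preprocess a surface-EMG recording
#'
#' Applies the artifact-removal chain for EMG recorded during scanning,
#' in order: notch filters at 45 and 90 Hz (scanner gradient artifacts),
#' 10 Hz high-pass (movement artifacts), full-wave rectification (regains
#' the low-frequency contraction envelope), and a 2-130 Hz band-pass.
#' All filters are zero-phase (forward-backward) so envelope timing is
#' unbiased.
#'
#' @param raw a \linkS4class{SampledSeries}; sampling rate must be at
#'   least 260 Hz.
#' @param notchHz frequencies of the gradient-artifact notches (Hz).
#' @param notchQ notch quality factor (bandwidth = f0/Q).
#' @param hpHz movement-artifact high-pass cutoff (Hz).
#' @param bpHz length-2 band-pass edges applied after rectification (Hz).
#' @return a \linkS4class{SampledSeries} on the same grid.
#' @export
preprocessEmg <- function(raw, notchHz = c(45, 90), notchQ = 30,
                          hpHz = 10, bpHz = c(2, 130)) {
  stopifnot(is(raw, "SampledSeries"))
  if (raw@fs < 2 * bpHz[2])
    stop(
      "fs = ", raw@fs, " Hz is below the Nyquist rate for the ",
      bpHz[2], " Hz band-pass edge (need fs >= ", 2 * bpHz[2], " Hz)"
    )
  x <- raw@values
  for (f0 in notchHz) x <- butterNotch(x, raw@fs, f0, Q = notchQ)
  x <- butterHighpass(x, raw@fs, hpHz)
  x <- abs(x)
  x <- butterBandpass(x, raw@fs, bpHz[1], bpHz[2])
  new("SampledSeries", sampleTimes = raw@sampleTimes, values = x,
      fs = raw@fs, units = raw@units)
}

#' Amplitude envelope of a sampled signal
#'
#' Magnitude of the analytic (Hilbert) signal, smoothed by a centred
#' moving average. This is the envelope definition shared by the glove
#' compliance/mirror correlations and the EMG mirror-contraction score.
#'
#' @param series a \linkS4class{SampledSeries}.
#' @param smoothS moving-average width in seconds (>= 0; default 0.5).
#' @param source \code{"glove"} or \code{"emg"}, recorded in the result.
#' @return an \linkS4class{EnvelopeSeries} on the same grid.
#' @export
computeEnvelope <- function(series, smoothS = 0.5, source = "emg") {
  stopifnot(is(series, "SampledSeries"), smoothS >= 0)
  env <- Mod(analyticSignal(series@values))
  if (smoothS > 0)
    env <- movingAverage(env, round(smoothS * series@fs))
  new("EnvelopeSeries",
    sampleTimes = series@sampleTimes, values = env,
    fs = series@fs, units = series@units, source = source
  )
}

#' Task EMG amplitude as a percentage of maximal voluntary extension
#'
#' Divides the mean rectified EMG amplitude during the move blocks by
#' the mean rectified amplitude of the maximal-voluntary-extension (MVE)
#' recording and multiplies by 100. The normalization cancels
#' between-subject amplitude factors (skin conductivity, muscle mass,
#' electrode placement), so the score is comparable across subjects.
#'
#' Because the preprocessed signal is zero-mean by construction (the
#' final band-pass removes DC), the "average EMG signal" is taken as the
#' mean absolute amplitude, which is proportional to contraction
#' strength and invariant under common gain.
#'
#' @param taskEmg preprocessed task recording
#'   (\linkS4class{SampledSeries}, see [preprocessEmg()]).
#' @param mveEmg preprocessed MVE recording.
#' @param boxcar a \linkS4class{TaskBoxcar} defining the move blocks;
#'   if NULL the full task recording is averaged.
#' @param mveWindowS optional window (seconds from recording start) over
#'   which the MVE is averaged; default the full recording.
#' @return percentage (>= 0)
#' @export
percentMve <- function(taskEmg, mveEmg, boxcar = NULL, mveWindowS = NULL) {
  stopifnot(is(taskEmg, "SampledSeries"), is(mveEmg, "SampledSeries"))
  mveVals <- abs(mveEmg@values)
  if (!is.null(mveWindowS))
    mveVals <- mveVals[mveEmg@sampleTimes - mveEmg@sampleTimes[1] <= mveWindowS]
  mveMean <- mean(mveVals)
  if (!is.finite(mveMean) || mveMean <= .Machine$double.eps * 100)
    stop("mean MVE amplitude is ~0; cannot normalize to %MVE")
  taskVals <- abs(taskEmg@values)
  if (!is.null(boxcar)) taskVals <- taskVals[moveMask(boxcar, taskEmg)]
  100 * mean(taskVals) / mveMean
}

#' EMG mirror-contraction score (MM_EMG)
#'
#' The Pearson correlation of the EMG envelope with the task boxcar,
#' multiplied by the \%MVE of the recording:
#' \deqn{MM_{EMG} = r_{T, E_{EMG}} \cdot \%\bar{MVE}}
#' Applied to the hand contralateral to the instructed hand, it scores
#' task-locked isometric contractions (covert mirror activity) weighted
#' by their strength relative to a maximal contraction.
#'
#' @param envelope an \linkS4class{EnvelopeSeries} of the preprocessed
#'   EMG signal.
#' @param boxcar a \linkS4class{TaskBoxcar}; resampled onto the envelope
#'   grid.
#' @param pct the \%MVE of the same recording (see [percentMve()]).
#' @return list with \code{pct_mve_mean}, \code{task_corr} and
#'   \code{mm_score = task_corr * pct_mve_mean} (exact).
#' @export
mirrorEmgScore <- function(envelope, boxcar, pct) {
  stopifnot(is(envelope, "EnvelopeSeries"), is(boxcar, "TaskBoxcar"),
            pct >= 0)
  box <- boxcarOnGrid(boxcar, envelope)
  r <- safePearson(envelope@values, box, what = "envelope")
  list(pct_mve_mean = pct, task_corr = r, mm_score = r * pct)
}

#' Full EMG scoring of one task/MVE recording pair
#'
#' Preprocesses both recordings, computes the envelope, \%MVE and the
#' mirror-contraction score in one call.
#'
#' @param taskRaw,mveRaw raw \linkS4class{SampledSeries} recordings.
#' @param boxcar a \linkS4class{TaskBoxcar}.
#' @param smoothS envelope smoothing width in seconds.
#' @return data.frame with columns \code{pct_mve}, \code{task_corr},
#'   \code{mm_emg}.
#' @export
analyzeEmg <- function(taskRaw, mveRaw, boxcar, smoothS = 0.5) {
  task <- preprocessEmg(taskRaw)
  mve <- preprocessEmg(mveRaw)
  pct <- percentMve(task, mve, boxcar)
  env <- computeEnvelope(task, smoothS = smoothS, source = "emg")
  sc <- mirrorEmgScore(env, boxcar, pct)
  data.frame(
    pct_mve = sc$pct_mve_mean, task_corr = sc$task_corr,
    mm_emg = sc$mm_score
  )
}
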