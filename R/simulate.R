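#' Ground-truth parameters for the synthetic cohort generator
#'
#' Bundles the quantities the recovery tests estimate back from simulated
#' data: mirror leakage into the inactive hand, the target EMG contraction
#' level as a percentage of maximal voluntary extension (MVE), the target
#' laterality per segment, and the movement rate.
#'
#' @param mirrorGain dimensionless leakage of the active-hand signal into
#'   the inactive hand (0 = no mirror movements).
#' @param targetPctMve task EMG amplitude as a percentage of the MVE
#'   amplitude (>= 0); 0 means no task-locked contraction.
#' @param liTrue target laterality index in [-1, 1], recycled across
#'   segments if scalar.
#' @param movementRate flexion-extension rate in Hz. The default 0.5 Hz
#'   yields approximately 90 counted movements over 180 s of movement,
#'   the magnitude observed with this paradigm.
#' @param seed integer seed; fully determines all random draws.
#' @return a list of class \code{"GroundTruth"}
#' @export
groundTruth <- function(mirrorGain = 0, targetPctMve = 0, liTrue = 0,
                        movementRate = 0.5, seed = 1L) {
  stopifnot(targetPctMve >= 0, all(liTrue >= -1 & liTrue <= 1),
            movementRate > 0)
  structure(
    list(
      mirrorGain = mirrorGain, targetPctMve = targetPctMve,
      liTrue = liTrue, movementRate = movementRate,
      seed = as.integer(seed)
    ),
    class = "GroundTruth"
  )
}

#' Simulate a data-glove finger-angle trace
#'
#' During move blocks the trace oscillates at the ground-truth movement
#' rate with a per-block amplitude drawn from a three-level schedule
#' (emulating the low/medium/full extension cue); during rest it carries
#' only slow drift and measurement noise. A companion inactive-hand trace
#' equals \code{mirrorGain} times the active trace plus independent noise,
#' so overt mirror movements can be injected at a known strength.
#'
#' @param boxcar a \linkS4class{TaskBoxcar}
#' @param truth a [groundTruth()] object
#' @param amplitudeSchedule movement amplitudes in degrees, cycled over
#'   move blocks (three cue levels by default); all in (0, 90].
#' @param noiseSd measurement noise SD in degrees. Noise is band-limited
#'   to \code{noiseBwHz} before scaling: a resistive bend sensor tracks
#'   mechanical motion and carries no broadband power.
#' @param driftAmp slow (0.01 Hz) drift amplitude in degrees.
#' @param fs native glove sampling rate in Hz.
#' @param noiseBwHz sensor noise bandwidth in Hz.
#' @return list with elements \code{active} and \code{inactive}, both
#'   \linkS4class{SampledSeries} in degrees.
#' @export
simulateGloveTrace <- function(boxcar, truth = groundTruth(),
                               amplitudeSchedule = c(30, 60, 90),
                               noiseSd = 0.5, driftAmp = 5, fs = 100,
                               noiseBwHz = 5) {
  stopifnot(is(boxcar, "TaskBoxcar"))
  if (noiseSd < 0) stop("noiseSd must be non-negative")
  if (any(amplitudeSchedule <= 0 | amplitudeSchedule > 90))
    stop("amplitude levels must lie in (0, 90] degrees")
  withSeed(truth$seed, {
    n <- as.integer(round(boxcar@totalS * fs))
    t <- (seq_len(n) - 1) / fs
    blk <- floor(t / boxcar@blockS)
    moving <- blk %% 2 == 1
    moveBlockIdx <- (blk %/% 2) + 1 # 1-based index among move blocks
    amp <- numeric(n)
    amp[moving] <- amplitudeSchedule[
      ((moveBlockIdx[moving] - 1) %% length(amplitudeSchedule)) + 1
    ]
    tau <- t - blk * boxcar@blockS # time within block
    ## flexion-extension from 0 to the scheduled amplitude and back
    osc <- amp / 2 * (1 - cos(2 * pi * truth$movementRate * tau))
    osc[!moving] <- 0
    bandNoise <- function() {
      if (noiseSd == 0) return(numeric(n))
      z <- stats::rnorm(n)
      if (noiseBwHz < fs / 2) {
        b <- signal::butter(2, noiseBwHz / (fs / 2), type = "low")
        z <- signal::filtfilt(b, z)
      }
      noiseSd * z / stats::sd(z)
    }
    drift <- driftAmp * sin(2 * pi * 0.01 * t + stats::runif(1, 0, 2 * pi))
    active <- osc + drift + bandNoise()
    inactive <- truth$mirrorGain * osc +
      driftAmp * sin(2 * pi * 0.01 * t + stats::runif(1, 0, 2 * pi)) +
      bandNoise()
    list(
      active = sampledSeries(active, fs, units = "deg"),
      inactive = sampledSeries(inactive, fs, units = "deg")
    )
  })
}

#' Simulate a surface-EMG recording with scanner artifacts
#'
#' The task recording is a broadband Gaussian carrier amplitude-modulated
#' by the task boxcar (a burst train), scaled so that the mean rectified
#' burst amplitude equals \code{targetPctMve}\% of the MVE burst
#' amplitude, plus sinusoidal gradient artifacts at exactly 45 and 90 Hz
#' and a slow motion drift. The MVE recording is a short maximal burst of
#' the same carrier type, used downstream as the normalization reference.
#'
#' @param boxcar a \linkS4class{TaskBoxcar}
#' @param truth a [groundTruth()] object; \code{targetPctMve} sets the
#'   task burst amplitude.
#' @param fs sampling rate in Hz; must be at least 260 Hz so the 130 Hz
#'   band-pass edge is below Nyquist.
#' @param artifactAmps numeric length-2, amplitudes of the 45 and 90 Hz
#'   gradient artifacts (units of the EMG signal).
#' @param mveAmp amplitude (SD) of the MVE burst.
#' @param driftAmp amplitude of a 0.2 Hz motion drift component.
#' @param mveS duration of the MVE recording in seconds.
#' @param restFrac baseline (rest) EMG amplitude as a fraction of
#'   \code{mveAmp}; physiological recordings are never exactly silent.
#' @return list with \linkS4class{SampledSeries} elements \code{task} and
#'   \code{mve}.
#' @export
simulateEmgTrace <- function(boxcar, truth = groundTruth(), fs = 1000,
                             artifactAmps = c(0.5, 0.5), mveAmp = 1,
                             driftAmp = 0.2, mveS = 5, restFrac = 0.01) {
  stopifnot(is(boxcar, "TaskBoxcar"))
  if (fs < 2 * 130)
    stop(
      "fs = ", fs, " Hz violates the Nyquist constraint: the 130 Hz ",
      "band-pass edge requires fs >= 260 Hz"
    )
  withSeed(truth$seed, {
    n <- as.integer(round(boxcar@totalS * fs))
    t <- (seq_len(n) - 1) / fs
    box <- floor(t / boxcar@blockS) %% 2 == 1
    taskAmp <- truth$targetPctMve / 100 * mveAmp
    ampl <- ifelse(box, sqrt(taskAmp^2 + (restFrac * mveAmp)^2),
                   restFrac * mveAmp)
    carrier <- stats::rnorm(n)
    task <- ampl * carrier +
      artifactAmps[1] * sin(2 * pi * 45 * t) +
      artifactAmps[2] * sin(2 * pi * 90 * t) +
      driftAmp * sin(2 * pi * 0.2 * t + stats::runif(1, 0, 2 * pi))
    nMve <- as.integer(round(mveS * fs))
    mve <- mveAmp * stats::rnorm(nMve) +
      artifactAmps[1] * sin(2 * pi * 45 * (seq_len(nMve) - 1) / fs) +
      artifactAmps[2] * sin(2 * pi * 90 * (seq_len(nMve) - 1) / fs)
    list(
      task = sampledSeries(task, fs, units = "au"),
      mve = sampledSeries(mve, fs, units = "au")
    )
  })
}

#' Build a mirror-symmetric motor-segment label atlas
#'
#' Partitions a voxel grid into six bilateral anatomical motor segments
#' (twelve labels): the left half of the first (left-right) axis is the
#' left hemisphere, segments are stacked as slabs along the third axis.
#' The atlas is mirror-symmetric about the mid-sagittal plane by
#' construction, so each label has a mirrored twin of equal voxel count.
#'
#' @param shape integer length-3 voxel grid dimensions; the first axis
#'   must be even (left/right symmetry).
#' @param segments six segment names.
#' @param voxelMm isotropic voxel size in mm.
#' @return a \linkS4class{LabelAtlas}. Odd labels are left-hemisphere,
#'   even labels right; label \code{2s-1}/\code{2s} is segment \code{s}.
#' @export
makeLabelAtlas <- function(shape = c(16, 16, 18),
                           segments = c("cerebellum", "SMA", "PM",
                                        "precentral", "postcentral",
                                        "insula"),
                           voxelMm = 4) {
  stopifnot(length(shape) == 3, length(segments) == 6)
  if (shape[1] %% 2 != 0)
    stop("first (left-right) axis length must be even, got ", shape[1])
  slab <- shape[3] %/% length(segments)
  if (slab < 1) stop("third axis too short for 6 segment slabs")
  grid <- array(0L, shape)
  half <- shape[1] %/% 2
  for (s in seq_along(segments)) {
    z <- ((s - 1) * slab + 1):(s * slab)
    grid[1:half, , z] <- 2L * s - 1L # left
    grid[(half + 1):shape[1], , z] <- 2L * s # right
  }
  affine <- diag(c(-voxelMm, voxelMm, voxelMm, 1))
  affine[1, 4] <- voxelMm * (shape[1] - 1) / 2
  affine[2, 4] <- -voxelMm * (shape[2] - 1) / 2
  affine[3, 4] <- -voxelMm * (shape[3] - 1) / 2
  tab <- data.frame(
    label = seq_len(12L),
    segment = rep(segments, each = 2),
    hemisphere = rep(c("L", "R"), 6),
    stringsAsFactors = FALSE
  )
  new("LabelAtlas", grid = grid, affine = affine, table = tab)
}

#' Simulate a beta volume with controlled lateralization
#'
#' For each segment pair, a number of "active" voxels equal to the pooled
#' top-fraction count is planted with mean \code{effect}, split between
#' the two hemispheres so that the expected laterality index equals
#' \code{liTrue} (ipsilesional share \code{(1 + li)/2}). All other voxels
#' carry pure noise, so proportional-threshold selection recovers the
#' planted pattern.
#'
#' @param atlas a \linkS4class{LabelAtlas}
#' @param truth a [groundTruth()] object; \code{liTrue} is recycled over
#'   segments.
#' @param effect mean beta of active voxels (arbitrary units),
#'   recycled over segments.
#' @param noiseSd SD of the voxel noise.
#' @param lesionSide \code{"L"} or \code{"R"}: the ipsilesional
#'   hemisphere.
#' @param fraction proportional threshold used to size the active set.
#' @param subject,condition labels stored in the result.
#' @return a \linkS4class{BetaVolume}
#' @export
simulateBetaVolume <- function(atlas, truth = groundTruth(), effect = 2,
                               noiseSd = 0.2, lesionSide = "L",
                               fraction = 0.15,
                               subject = NA_character_,
                               condition = NA_character_) {
  stopifnot(is(atlas, "LabelAtlas"), is.finite(effect), noiseSd >= 0,
            lesionSide %in% c("L", "R"))
  tab <- labelTable(atlas)
  segs <- unique(tab$segment)
  li <- rep_len(truth$liTrue, length(segs))
  eff <- rep_len(effect, length(segs))
  withSeed(truth$seed, {
    grid <- array(stats::rnorm(prod(dim(atlas@grid)), sd = noiseSd),
                  dim(atlas@grid))
    for (i in seq_along(segs)) {
      labI <- tab$label[tab$segment == segs[i] & tab$hemisphere == lesionSide]
      labC <- tab$label[tab$segment == segs[i] & tab$hemisphere != lesionSide]
      idxI <- which(atlas@grid == labI)
      idxC <- which(atlas@grid == labC)
      k <- floor(fraction * (length(idxI) + length(idxC)))
      kI <- round((1 + li[i]) / 2 * k)
      kC <- k - kI
      if (kI > 0) grid[idxI[seq_len(kI)]] <-
          eff[i] + stats::rnorm(kI, sd = noiseSd)
      if (kC > 0) grid[idxC[seq_len(kC)]] <-
          eff[i] + stats::rnorm(kC, sd = noiseSd)
    }
    new("BetaVolume", grid = grid, affine = atlas@affine,
        subject = subject, condition = condition)
  })
}
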