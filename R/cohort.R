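#' Simulate a full patient/control cohort
#'
#' Generates every input the analysis pipeline consumes, with known
#' ground truth: per-subject glove traces (both hands), EMG task and MVE
#' recordings, one beta volume per task level, a shared label atlas, and
#' a cohort table of clinical scores (Fugl-Meyer 0-66, ARAT 0-57, \%NHPT
#' > 0). Lesion sides alternate L/R across patients so the
#' hemisphere-flipping path is exercised. Everything is a deterministic
#' function of \code{seed}.
#'
#' Clinical scores are drawn to emulate a moderately-to-well recovered
#' chronic stroke cohort (FM ~ N(60.5, 5.6) clamped to [0, 66], ARAT ~
#' N(56, 2.1) clamped to [0, 57], \%NHPT ~ N(69.3, 22.6) truncated
#' positive); controls sit at their scale maxima. An optional linear
#' dependence of the planted activation effect on FM
#' (\code{fmSlope} per SD of FM, in \code{fmSegment}) lets power checks
#' verify that brain-behavior regression finds a real signal.
#'
#' @param nPatients,nControls group sizes (>= 2 each).
#' @param seed master integer seed.
#' @param truth baseline [groundTruth()] shared by all subjects (its
#'   seed field is ignored; per-subject seeds derive from \code{seed}).
#' @param blockS,totalS,dt task paradigm parameters.
#' @param gloveFs,emgFs native sampling rates (Hz).
#' @param atlasShape voxel grid of the shared atlas.
#' @param effect planted activation effect (beta units).
#' @param betaNoiseSd voxel noise SD.
#' @param globalGainSd SD of the per-subject multiplicative global
#'   signal gain (mean 1). BOLD responsiveness varies globally between
#'   subjects, which is the reason ROI thresholds are proportional
#'   rather than absolute; the gain also makes per-ROI activation
#'   levels correlate across ROIs within subject, as in real data.
#' @param nLevels number of task levels (beta volumes per subject).
#' @param liSd between-run SD of the per-segment laterality target:
#'   each volume's \code{liTrue} is jittered around the cohort value
#'   (clamped to [-1, 1]), since lateralization varies between subjects
#'   and repeat runs.
#' @param fmSlope effect change (beta units) per SD of FM in
#'   \code{fmSegment} for patients; 0 disables.
#' @param fmSegment segment name carrying the FM dependence.
#' @param outDir optional directory; when given, all inputs are written
#'   (signals as 2-column text, volumes as .nii.gz, cohort CSV, one
#'   ground-truth JSON sidecar per subject).
#' @param overwrite allow writing into an existing non-empty directory.
#' @param signals logical; simulate glove/EMG signals (disable for
#'   imaging-only studies to save time).
#' @return list with \code{cohort} (data.frame: subject, group,
#'   lesion_side, fm, arat, nhpt_pct), \code{atlas}, \code{subjects} (a
#'   list per subject with elements \code{glove}, \code{emg},
#'   \code{betas} (one per level), \code{truth}), \code{boxcar}, and
#'   \code{dir} (NULL unless written).
#' @export
simulateCohort <- function(nPatients = 20, nControls = 15, seed = 1L,
                           truth = groundTruth(),
                           blockS = 20, totalS = 360, dt = 0.5,
                           gloveFs = 100, emgFs = 1000,
                           atlasShape = c(16, 16, 18),
                           effect = 2, betaNoiseSd = 0.2,
                           globalGainSd = 0.2, nLevels = 3, liSd = 0.15,
                           fmSlope = 0, fmSegment = "PM",
                           outDir = NULL, overwrite = FALSE,
                           signals = TRUE) {
  stopifnot(nPatients >= 2, nControls >= 2)
  if (!is.null(outDir) && dir.exists(outDir) &&
      length(dir(outDir)) && !overwrite)
    stop("output directory ", outDir,
         " exists and is not empty; set overwrite = TRUE")
  boxcar <- makeTaskBoxcar(blockS, totalS, dt)
  atlas <- makeLabelAtlas(atlasShape)
  n <- nPatients + nControls
  seeds <- withSeed(seed, sample.int(.Machine$integer.max - 1L, n + 1L))
  clin <- withSeed(seeds[n + 1L], {
    fm <- pmin(pmax(round(stats::rnorm(nPatients, 60.5, 5.6)), 0), 66)
    arat <- pmin(pmax(round(stats::rnorm(nPatients, 56, 2.1)), 0), 57)
    nhpt <- pmax(stats::rnorm(nPatients, 69.3, 22.6), 5)
    gain <- pmax(stats::rnorm(n, 1, globalGainSd), 0.2)
    list(fm = fm, arat = arat, nhpt = round(nhpt, 1), gain = gain)
  })
  cohort <- data.frame(
    subject = sprintf("S%02d", seq_len(n)),
    group = rep(c("patient", "control"), c(nPatients, nControls)),
    lesion_side = c(rep(c("L", "R"), length.out = nPatients),
                    rep(c("L", "R"), length.out = nControls)),
    fm = c(clin$fm, rep(66, nControls)),
    arat = c(clin$arat, rep(57, nControls)),
    nhpt_pct = c(clin$nhpt, rep(100, nControls)),
    stringsAsFactors = FALSE
  )
  segs <- unique(labelTable(atlas)$segment)
  fmZ <- rep(0, n)
  if (fmSlope != 0 && stats::sd(cohort$fm[seq_len(nPatients)]) > 0)
    fmZ[seq_len(nPatients)] <-
      scale(cohort$fm[seq_len(nPatients)])[, 1]
  subjects <- lapply(seq_len(n), function(i) {
    ti <- truth
    ti$seed <- seeds[i]
    sub <- list(truth = ti)
    if (signals) {
      sub$glove <- simulateGloveTrace(boxcar, ti, fs = gloveFs)
      sub$emg <- simulateEmgTrace(boxcar, ti, fs = emgFs)
    }
    effSeg <- rep(effect, length(segs))
    if (fmSlope != 0 && cohort$group[i] == "patient")
      effSeg[segs == fmSegment] <- effect + fmSlope * fmZ[i]
    sub$betas <- lapply(seq_len(nLevels), function(lev) {
      tl <- ti
      tl$seed <- seeds[i] %% 1000000L + 1000L * lev
      if (liSd > 0)
        tl$liTrue <- pmin(pmax(
          withSeed(tl$seed + 1L,
                   rep_len(truth$liTrue, length(segs)) +
                     stats::rnorm(length(segs), 0, liSd)),
          -1), 1)
      vol <- simulateBetaVolume(
        atlas, tl, effect = effSeg, noiseSd = betaNoiseSd,
        lesionSide = cohort$lesion_side[i],
        subject = cohort$subject[i],
        condition = paste0("amplitude_l", lev)
      )
      vol@grid <- vol@grid * clin$gain[i]
      vol
    })
    sub
  })
  names(subjects) <- cohort$subject
  res <- list(cohort = cohort, atlas = atlas, subjects = subjects,
              boxcar = boxcar, dir = NULL)
  if (!is.null(outDir)) {
    writeCohortDir(res, outDir)
    res$dir <- outDir
  }
  res
}

writeCohortDir <- function(sim, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(sim$cohort, file.path(outDir, "cohort.csv"),
                   row.names = FALSE, quote = FALSE)
  writeLabelAtlas(sim$atlas, file.path(outDir, "atlas.nii.gz"),
                  file.path(outDir, "atlas_labels.csv"))
  for (s in sim$cohort$subject) {
    sd <- file.path(outDir, s)
    dir.create(sd, showWarnings = FALSE)
    sub <- sim$subjects[[s]]
    if (!is.null(sub$glove)) {
      writeSignal(sub$glove$active, file.path(sd, "glove_active.tsv"))
      writeSignal(sub$glove$inactive,
                  file.path(sd, "glove_inactive.tsv"))
      writeSignal(sub$emg$task, file.path(sd, "emg_task.tsv"))
      writeSignal(sub$emg$mve, file.path(sd, "emg_mve.tsv"))
    }
    for (j in seq_along(sub$betas))
      writeBetaVolume(sub$betas[[j]],
                      file.path(sd, sprintf("beta_l%d.nii.gz", j)))
    jsonlite::write_json(
      sub$truth[c("mirrorGain", "targetPctMve", "liTrue",
                  "movementRate", "seed")],
      file.path(sd, "truth.json"), auto_unbox = TRUE, digits = NA
    )
  }
  invisible(outDir)
}

#' Assemble the per-cell cohort table for group statistics
#'
#' Runs the ROI analysis for every subject and task level of a simulated
#' (or loaded) cohort: volumes of right-lesion subjects are flipped over
#' the mid-sagittal plane so the affected hemisphere is on a common side,
#' then proportional-threshold mean betas and laterality indices are
#' computed per segment. Returns one row per subject x level x segment x
#' hemisphere, the layout expected by [rmAnova()].
#'
#' @param sim result of [simulateCohort()].
#' @param fraction proportional ROI threshold (default 0.15).
#' @return data.frame with columns \code{subject}, \code{group},
#'   \code{lesion_side}, \code{level}, \code{segment},
#'   \code{hemisphere} (\code{"ipsi"}/\code{"contra"} after flipping),
#'   \code{n_selected}, \code{mean_beta}, \code{li}, and the clinical
#'   scores.
#' @export
buildCohortTable <- function(sim, fraction = 0.15) {
  rows <- lapply(seq_len(nrow(sim$cohort)), function(i) {
    info <- sim$cohort[i, ]
    sub <- sim$subjects[[info$subject]]
    atlas <- sim$atlas
    do.call(rbind, lapply(seq_along(sub$betas), function(lev) {
      vol <- sub$betas[[lev]]
      if (info$lesion_side == "R") {
        vol <- flipHemispheres(vol)
        ## after flipping, the affected hemisphere is on the left
      }
      s <- roiSummary(vol, atlas, lesionSide = "L", fraction = fraction)
      s$hemisphere <- ifelse(s$hemisphere == "L", "ipsi", "contra")
      cbind(
        info[rep(1, nrow(s)), c("subject", "group", "lesion_side",
                                "fm", "arat", "nhpt_pct")],
        level = lev, s, row.names = NULL
      )
    }))
  })
  do.call(rbind, rows)
}
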