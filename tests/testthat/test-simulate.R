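test_that("simulators are deterministic functions of the seed", {
  bc <- shortBoxcar()
  tr <- groundTruth(mirrorGain = 0.4, targetPctMve = 30, seed = 11)
  g1 <- simulateGloveTrace(bc, tr)
  g2 <- simulateGloveTrace(bc, tr)
  expect_identical(sampleValues(g1$active), sampleValues(g2$active))
  expect_identical(sampleValues(g1$inactive), sampleValues(g2$inactive))
  e1 <- simulateEmgTrace(bc, tr, fs = 400)
  e2 <- simulateEmgTrace(bc, tr, fs = 400)
  expect_identical(sampleValues(e1$task), sampleValues(e2$task))
  a <- smallAtlas()
  v1 <- simulateBetaVolume(a, tr)
  v2 <- simulateBetaVolume(a, tr)
  expect_identical(voxelGrid(v1), voxelGrid(v2))
})

test_that("glove simulation honours leakage and amplitude preconditions", {
  bc <- fullBoxcar()
  expect_error(simulateGloveTrace(bc, noiseSd = -1), "non-negative")
  expect_error(simulateGloveTrace(bc, amplitudeSchedule = c(30, 100)),
               "degrees")
  # no leakage: inactive hand uncorrelated with the task
  g <- simulateGloveTrace(bc, groundTruth(mirrorGain = 0, seed = 21))
  r0 <- mirrorGloveScore(detrendResample(g$inactive), bc)
  expect_lt(abs(r0), 0.15)
  # full leakage: inactive tracks the task like the active hand
  g1 <- simulateGloveTrace(bc, groundTruth(mirrorGain = 1, seed = 22))
  rAct <- complianceCorrelation(detrendResample(g1$active), bc)
  rIn <- mirrorGloveScore(detrendResample(g1$inactive), bc)
  expect_equal(rIn, rAct, tolerance = 0.05)
})

test_that("EMG simulator enforces Nyquist and scales bursts to target %MVE", {
  bc <- shortBoxcar()
  expect_error(simulateEmgTrace(bc, fs = 200), "Nyquist")
  # zero target: mirror score vanishes
  e <- simulateEmgTrace(bc, groundTruth(targetPctMve = 0, seed = 5),
                        fs = 400, artifactAmps = c(0, 0), driftAmp = 0)
  res <- analyzeEmg(e$task, e$mve, bc)
  expect_lt(abs(res$mm_emg), 1)
  expect_lt(res$pct_mve, 5)
})

test_that("label atlas is mirror-symmetric with 12 adequate labels", {
  a <- makeLabelAtlas(c(16, 16, 18))
  tab <- labelTable(a)
  expect_equal(nrow(tab), 12)
  counts <- table(voxelGrid(a)[voxelGrid(a) != 0])
  expect_equal(length(counts), 12)
  # mirrored twin of equal voxel count, and non-degenerate 15% selection
  for (s in unique(tab$segment)) {
    labL <- tab$label[tab$segment == s & tab$hemisphere == "L"]
    labR <- tab$label[tab$segment == s & tab$hemisphere == "R"]
    expect_equal(counts[[as.character(labL)]], counts[[as.character(labR)]])
    expect_gte(counts[[as.character(labL)]], 20)
  }
  # explicit mirror symmetry of the grid
  flipped <- voxelGrid(a)[dim(voxelGrid(a))[1]:1, , ]
  remap <- ifelse(flipped == 0, 0,
                  ifelse(flipped %% 2 == 1, flipped + 1, flipped - 1))
  expect_equal(remap, voxelGrid(a))
  expect_error(makeLabelAtlas(c(15, 16, 18)), "even")
})

test_that("hemisphere flip of an atlas is an involution that swaps labels", {
  a <- smallAtlas()
  f <- flipHemispheres(a)
  expect_equal(labelTable(f)$hemisphere,
               ifelse(labelTable(a)$hemisphere == "L", "R", "L"))
  ff <- flipHemispheres(f)
  expect_identical(voxelGrid(ff), voxelGrid(a))
  expect_equal(voxelAffine(ff), voxelAffine(a))
  expect_equal(labelTable(ff), labelTable(a))
})

test_that("planted laterality is recovered from simulated beta volumes", {
  a <- smallAtlas(c(12, 12, 12))
  # noiseless endpoints
  v1 <- simulateBetaVolume(a, groundTruth(liTrue = 1, seed = 1), noiseSd = 0)
  expect_equal(lateralityIndex(v1, a, "SMA", "L"), 1.0)
  v0 <- simulateBetaVolume(a, groundTruth(liTrue = 0, seed = 2), noiseSd = 0)
  expect_equal(lateralityIndex(v0, a, "PM", "L"), 0, tolerance = 0.05)
  # stochastic recovery, mean over 20 seeds
  rec <- vapply(1:20, function(s) {
    v <- simulateBetaVolume(a, groundTruth(liTrue = 0.5, seed = 100 + s))
    lateralityIndex(v, a, "insula", "L")
  }, numeric(1))
  expect_equal(mean(rec), 0.5, tolerance = 0.1)
})

test_that("cohort generation is reproducible and respects scale bounds", {
  d1 <- file.path(tempdir(), "cohA")
  d2 <- file.path(tempdir(), "cohB")
  on.exit(unlink(c(d1, d2), recursive = TRUE), add = TRUE)
  args <- list(nPatients = 2, nControls = 2, seed = 5, totalS = 40,
               blockS = 10, gloveFs = 50, emgFs = 400,
               atlasShape = c(8, 8, 6), nLevels = 1)
  s1 <- do.call(simulateCohort, c(args, list(outDir = d1)))
  s2 <- do.call(simulateCohort, c(args, list(outDir = d2)))
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  expect_identical(unname(tools::md5sum(file.path(d1, f1))),
                   unname(tools::md5sum(file.path(d2, f1))))
  # overwrite guard
  expect_error(do.call(simulateCohort, c(args, list(outDir = d1))),
               "overwrite")
  # clinical scores inside their scales, lesion sides alternate
  big <- simulateCohort(20, 15, seed = 3, signals = FALSE,
                        atlasShape = c(8, 8, 6), nLevels = 1)
  co <- big$cohort
  expect_true(all(co$fm >= 0 & co$fm <= 66))
  expect_true(all(co$arat >= 0 & co$arat <= 57))
  expect_true(all(co$nhpt_pct > 0))
  pat <- co[co$group == "patient", ]
  expect_equal(unique(pat$lesion_side), c("L", "R"))
  expect_equal(sum(pat$lesion_side == "L"), 10)
})

test_that("monotone ground truth maps to monotone recovered scores", {
  bc <- shortBoxcar()
  # mirror gain -> MM_glove, over a 5-point grid averaged across seeds
  gains <- c(0, 0.25, 0.5, 0.75, 1)
  mg <- vapply(gains, function(g) {
    mean(vapply(1:5, function(s) {
      sim <- simulateGloveTrace(bc, groundTruth(mirrorGain = g,
                                                seed = 300 + s))
      mirrorGloveScore(detrendResample(sim$inactive), bc)
    }, numeric(1)))
  }, numeric(1))
  expect_gt(cor(gains, mg, method = "spearman"), 0.9)
  # target %MVE -> recovered %MVE
  pcts <- c(5, 20, 40, 60, 80)
  rec <- vapply(pcts, function(p) {
    mean(vapply(1:5, function(s) {
      e <- simulateEmgTrace(bc, groundTruth(targetPctMve = p,
                                            seed = 400 + s), fs = 400)
      analyzeEmg(e$task, e$mve, bc)$pct_mve
    }, numeric(1)))
  }, numeric(1))
  expect_gt(cor(pcts, rec, method = "spearman"), 0.9)
})
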