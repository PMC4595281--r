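test_that("proportional selection matches a full-sort oracle", {
  a <- makeLabelAtlas(c(10, 10, 6)) # 50 voxels per label, 100 pooled
  withr::with_seed(4, {
    for (rep in 1:5) {
      v <- new("BetaVolume",
               grid = array(rnorm(prod(dim(voxelGrid(a)))),
                            dim(voxelGrid(a))),
               affine = voxelAffine(a))
      idx <- which(voxelGrid(a) %in% labelTable(a)$label[
        labelTable(a)$segment == "PM"])
      sel <- selectTopVoxels(v, a, "PM", NULL, 0.15)
      expect_length(sel, 15) # floor(0.15 * 100)
      expect_equal(sort(sel), sort(bruteTopK(voxelGrid(v), idx, 15)))
      # threshold property
      expect_gte(min(voxelGrid(v)[sel]),
                 max(voxelGrid(v)[setdiff(idx, sel)]))
    }
  })
})

test_that("ties are broken deterministically by voxel index", {
  a <- makeLabelAtlas(c(10, 10, 6))
  v <- new("BetaVolume", grid = array(1, dim(voxelGrid(a))),
           affine = voxelAffine(a))
  sel <- selectTopVoxels(v, a, "SMA", "L", 0.15)
  idx <- which(voxelGrid(a) == labelTable(a)$label[
    labelTable(a)$segment == "SMA" & labelTable(a)$hemisphere == "L"])
  expect_identical(sort(sel), utils::head(idx, length(sel)))
})

test_that("tiny segments are refused rather than silently selected", {
  a <- makeLabelAtlas(c(4, 2, 6))
  v <- new("BetaVolume", grid = array(0, dim(voxelGrid(a))),
           affine = voxelAffine(a))
  expect_error(selectTopVoxels(v, a, "SMA", "L", 0.15), "SMA")
  expect_error(selectTopVoxels(v, a, "missing", "L", 0.15), "missing")
})

test_that("ROI mean beta equals the brute-force mean", {
  a <- smallAtlas()
  v <- new("BetaVolume", grid = array(7, dim(voxelGrid(a))),
           affine = voxelAffine(a))
  sel <- selectTopVoxels(v, a, "PM", "L")
  expect_equal(roiMeanBeta(v, sel), 7)
  withr::with_seed(8, {
    v@grid <- array(rnorm(length(v@grid)), dim(v@grid))
    sel <- selectTopVoxels(v, a, "PM", "L")
    expect_equal(roiMeanBeta(v, sel),
                 sum(voxelGrid(v)[sel]) / length(sel))
  })
  expect_error(roiMeanBeta(v, integer()), "empty")
})

test_that("selections, LI and rank order are invariant to global scaling", {
  a <- smallAtlas()
  v <- simulateBetaVolume(a, groundTruth(liTrue = 0.4, seed = 31))
  v3 <- new("BetaVolume", grid = 3.7 * voxelGrid(v), affine = voxelAffine(v))
  for (sg in unique(labelTable(a)$segment)) {
    expect_identical(selectTopVoxels(v, a, sg, "L"),
                     selectTopVoxels(v3, a, sg, "L"))
    expect_equal(lateralityIndex(v, a, sg, "L"),
                 lateralityIndex(v3, a, sg, "L"))
  }
  mb <- function(vol) vapply(unique(labelTable(a)$segment), function(sg)
    roiMeanBeta(vol, selectTopVoxels(vol, a, sg, "L")), numeric(1))
  expect_equal(order(mb(v)), order(mb(v3)))
})

test_that("LI is bounded and antisymmetric in the lesion side", {
  a <- smallAtlas()
  withr::with_seed(12, {
    for (rep in 1:5) {
      v <- new("BetaVolume",
               grid = array(rnorm(length(voxelGrid(a))), dim(voxelGrid(a))),
               affine = voxelAffine(a))
      for (sg in c("SMA", "insula")) {
        liL <- lateralityIndex(v, a, sg, "L")
        liR <- lateralityIndex(v, a, sg, "R")
        expect_gte(liL, -1); expect_lte(liL, 1)
        expect_equal(liL, -liR)
      }
    }
  })
})

test_that("hemisphere flipping is an involution preserving ROI quantities", {
  a <- smallAtlas()
  v <- simulateBetaVolume(a, groundTruth(liTrue = -0.3, seed = 41))
  f <- flipHemispheres(v)
  ff <- flipHemispheres(f)
  expect_identical(voxelGrid(ff), voxelGrid(v))
  expect_equal(voxelAffine(ff), voxelAffine(v))
  # LI after flipping (volume and atlas) with the swapped lesion side
  fa <- flipHemispheres(a)
  expect_equal(lateralityIndex(f, fa, "PM", "R"),
               lateralityIndex(v, a, "PM", "L"))
  # mean beta of the flipped left ROI equals the original right ROI
  expect_equal(
    roiMeanBeta(f, selectTopVoxels(f, a, "SMA", "L")),
    roiMeanBeta(v, selectTopVoxels(v, a, "SMA", "R"))
  )
  # an affine with no dominant left-right axis is refused
  vAmb <- v
  vAmb@affine[1, 1:3] <- c(1, 1, 0)
  expect_error(flipHemispheres(vAmb), "ambiguous")
})

test_that("Gaussian smoothing preserves mass and hits its target width", {
  a <- makeLabelAtlas(c(20, 20, 18))
  v <- new("BetaVolume", grid = array(0, c(20, 20, 18)),
           affine = voxelAffine(a))
  expect_identical(voxelGrid(smoothVolume(v, 0)), voxelGrid(v))
  # interior delta: mass preserved, FWHM within 10% of target
  v@grid[10, 10, 9] <- 1
  sm <- smoothVolume(v, 8) # 8 mm on 4 mm voxels -> sigma ~ 0.85 vox
  expect_equal(sum(voxelGrid(sm)), 1, tolerance = 0.01)
  prof <- voxelGrid(sm)[, 10, 9]
  half <- max(prof) / 2
  above <- range(which(prof >= half))
  crossLo <- above[1] - 1 +
    (half - prof[above[1] - 1]) / (prof[above[1]] - prof[above[1] - 1])
  crossHi <- above[2] +
    (prof[above[2]] - half) / (prof[above[2]] - prof[above[2] + 1])
  fwhmVox <- crossHi - crossLo
  expect_equal(fwhmVox * 4, 8, tolerance = 0.1 * 8)
})

test_that("the block GLM recovers planted effects despite drift and AR noise", {
  bc <- fullBoxcar()
  n <- length(sampleValues(bc))
  withr::with_seed(3, {
    ts <- matrix(rnorm(n * 40, sd = 0.1), n, 40) +
      2 * sampleValues(bc)
    b <- fitBlockGlm(ts, bc)
    expect_equal(mean(b), 2, tolerance = 0.1)
    expect_true(all(abs(b - 2) < 0.2))
    # white noise alone: betas centred at zero
    b0 <- fitBlockGlm(matrix(rnorm(n * 40), n, 40), bc)
    expect_lt(abs(mean(b0)), 0.1)
    # slow confound (period 256 s) removed by the 128 s high-pass
    slow <- 3 * sin(2 * pi * sampleTimes(bc) / 256)
    b2 <- fitBlockGlm(ts + slow, bc)
    expect_equal(b2, b, tolerance = 0.05)
    # constant series flagged with zero beta
    expect_warning(bc0 <- fitBlockGlm(rep(5, n), bc), "constant")
    expect_equal(unname(bc0), 0)
  })
  expect_error(fitBlockGlm(rnorm(10), bc), "match the boxcar")
})
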