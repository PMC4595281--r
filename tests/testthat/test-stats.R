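test_that("repeated-measures F matches an independent SS decomposition", {
  withr::with_seed(2, {
    d <- expand.grid(subject = paste0("s", 1:10), a = paste0("a", 1:4),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    d$group <- ifelse(as.integer(sub("s", "", d$subject)) <= 5, "g1", "g2")
    d$y <- rnorm(nrow(d)) + rep(rnorm(10), 4)[
      as.integer(sub("s", "", d$subject))]
    res <- rmAnova(d, "y", within = "a", between = "group")
    orc <- mixedAnovaOracle(d)
    expect_equal(res$F[res$effect == "group"], orc$F_group,
                 tolerance = 1e-6)
    expect_equal(res$F[res$effect == "a"], orc$F_a, tolerance = 1e-6)
    expect_equal(res$F[res$effect == "group:a"], orc$F_ga,
                 tolerance = 1e-6)
  })
})

test_that("group-interaction F is invariant to per-subject offsets", {
  withr::with_seed(5, {
    d <- expand.grid(subject = paste0("s", 1:12), a = paste0("a", 1:6),
                     b = c("L", "R"), stringsAsFactors = FALSE)
    d$group <- ifelse(as.integer(sub("s", "", d$subject)) <= 6, "g1", "g2")
    d$y <- rnorm(nrow(d))
    r1 <- rmAnova(d, "y", within = c("a", "b"), between = "group")
    d2 <- d
    offs <- rnorm(12, sd = 10)
    d2$y <- d$y + offs[as.integer(sub("s", "", d$subject))]
    r2 <- rmAnova(d2, "y", within = c("a", "b"), between = "group")
    for (eff in c("group:a", "group:b", "group:a:b"))
      expect_equal(r2$F[r2$effect == eff], r1$F[r1$effect == eff],
                   tolerance = 1e-8)
  })
})

test_that("incomplete designs and flat data are rejected with diagnostics", {
  d <- expand.grid(subject = paste0("s", 1:4), a = c("x", "y"),
                   stringsAsFactors = FALSE)
  d$y <- rnorm(8)
  expect_error(rmAnova(d[-3, ], "y", within = "a"), "s3")
  d0 <- d; d0$y <- 1
  expect_warning(res <- rmAnova(d0, "y", within = "a"), "zero variance")
  expect_equal(nrow(res), 0)
})

test_that("t statistics agree with the closed-form definitions", {
  # identical samples, paired: t = 0
  x <- c(3, 5, 7, 9)
  r <- tTests(x, x, paired = TRUE)
  expect_equal(r$t, 0)
  expect_equal(r$df, 3)
  # one-sample against the sample mean: t = 0
  expect_equal(tTests(c(1, 2, 3), mu = 2)$t, 0)
  # closed-form two-sample check
  a <- c(12, 15, 11, 14, 13)
  b <- c(10, 9, 12, 11, 8)
  r2 <- tTests(a, b)
  sp2 <- (4 * var(a) + 4 * var(b)) / 8
  tManual <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 5 + 1 / 5))
  expect_equal(r2$t, tManual, tolerance = 1e-4)
  expect_equal(r2$df, 8)
  expect_equal(r2$p, 2 * pt(-abs(tManual), 8), tolerance = 1e-10)
  # pairwise missing-value removal
  r3 <- tTests(c(1, 2, NA, 4), c(1, NA, 3, 4), paired = TRUE)
  expect_equal(r3$df, 1) # two complete pairs
  expect_error(tTests(c(NA, NA), mu = 0), "non-missing")
})

test_that("signed-rank test matches exact enumeration at small n", {
  # symmetric sample around mu: no evidence
  x <- c(-3, -2, -1, 1, 2, 3) + 10
  expect_gt(oneSampleWilcoxon(x, 10)$p, 0.5)
  # all 20 values below mu, no ties: exact two-sided p = 2 / 2^20
  withr::with_seed(6, y <- 50 - runif(20, 1, 10))
  r <- oneSampleWilcoxon(y, 50, exact = TRUE)
  expect_equal(r$W, 0)
  expect_equal(r$p, 2 / 2^20, tolerance = 1e-10)
  expect_lt(r$p, 0.001)
  expect_error(oneSampleWilcoxon(rep(5, 4), 5), "zero")
})

test_that("stepwise selection matches exhaustive forward enumeration", {
  withr::with_seed(9, {
    for (rep in 1:10) {
      X <- matrix(rnorm(25 * 4), 25, 4,
                  dimnames = list(NULL, paste0("ROI", 1:4)))
      y <- 1.5 * X[, 2] - X[, 4] + rnorm(25, sd = 0.5)
      got <- stepwiseRegression(X, y, pIn = 0.05, pOut = 0.05)
      expect_identical(got$selected, forwardOracle(X, y, 0.05))
    }
  })
})

test_that("stepwise isolates a planted predictor and obeys its thresholds", {
  withr::with_seed(10, {
    X <- matrix(rnorm(20 * 4), 20, 4,
                dimnames = list(NULL, paste0("ROI", 1:4)))
    y <- 2 * X[, 3] + rnorm(20, sd = 0.2)
    s <- stepwiseRegression(X, y)
    expect_identical(s$selected, "ROI3")
    expect_equal(unname(s$coefficients["ROI3"]), 2, tolerance = 0.2)
    # every retained factor entered below pIn; log records it
    expect_true(all(s$steps$p[s$steps$action == "enter"] < 0.05))
    # pIn = 1 saturates (bounded by the sample-size guard)
    sAll <- stepwiseRegression(X[, 1:4], y[1:20], pIn = 0.999999,
                               pOut = 1)
    expect_equal(length(sAll$selected), 4)
    # collinear candidate skipped with a warning
    X2 <- cbind(X[, 1:3], dup = X[, 3])
    expect_warning(s2 <- stepwiseRegression(X2, y), "collinear")
    expect_true(length(s2$selected) >= 1)
  })
})

test_that("voxelwise permutation test controls and detects", {
  a <- smallAtlas()
  dims <- dim(voxelGrid(a))
  withr::with_seed(13, {
    vols <- lapply(1:10, function(i)
      new("BetaVolume", grid = array(rnorm(prod(dims)), dims),
          affine = voxelAffine(a)))
    g <- rep(c("p", "c"), each = 5)
    # identical group means exactly: empty map
    volsEq <- c(vols[1:5], vols[1:5])
    rEq <- voxelwiseGroupTtest(volsEq, g, fwhmMm = 0, nPerm = 200,
                               seed = 1)
    expect_equal(sum(rEq$surviving), 0)
    # planted 5-SD effect in one segment survives; the rest does not
    volsFx <- vols
    idx <- which(voxelGrid(a) == 5) # PM left
    for (i in 1:5) volsFx[[i]]@grid[idx] <- volsFx[[i]]@grid[idx] + 5
    rFx <- voxelwiseGroupTtest(volsFx, g, fwhmMm = 4, nPerm = 300,
                               seed = 2)
    expect_gt(mean(rFx$surviving[idx]), 0.5)
    expect_lt(mean(rFx$surviving[-idx]), 0.05)
    expect_warning(voxelwiseGroupTtest(vols, g, fwhmMm = 0, nPerm = 50,
                                       seed = 3), "low")
    bad <- c(vols[1:9], list(new("BetaVolume",
                                 grid = array(0, c(4, 4, 4)),
                                 affine = diag(4))))
    expect_error(voxelwiseGroupTtest(bad, g), "common grid")
  })
})
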