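#' Fit a simplified first-level block GLM
#'
#' Regresses each voxel's time series on the task boxcar and an intercept
#' after discrete-cosine high-pass filtering (cutoff 128 s by default),
#' optionally prewhitening with a lag-1 autoregressive model estimated
#' from the pooled OLS residuals. This is an emulation of a first-level
#' analysis for fast-TR block designs, not a reproduction of any specific
#' neuroimaging package: the regressor is the raw (unconvolved) boxcar.
#'
#' @param ts numeric matrix (time x voxels) or vector of voxel time
#'   series, sampled on the boxcar grid.
#' @param boxcar a \linkS4class{TaskBoxcar} with as many samples as
#'   \code{ts} has rows.
#' @param hpCutoffS high-pass cutoff in seconds (default 128).
#' @param ar1 logical; apply AR(1) prewhitening (default TRUE).
#' @param affine,subject,condition metadata for the returned volume when
#'   \code{dims} is given.
#' @param dims optional 3-D dimensions; when supplied the betas are
#'   reshaped into a \linkS4class{BetaVolume}.
#' @return numeric vector of boxcar coefficients (one per voxel), or a
#'   \linkS4class{BetaVolume} when \code{dims} is given. Constant time
#'   series get beta 0 with a warning.
#' @export
fitBlockGlm <- function(ts, boxcar, hpCutoffS = 128, ar1 = TRUE,
                        dims = NULL, affine = diag(4),
                        subject = NA_character_,
                        condition = NA_character_) {
  stopifnot(is(boxcar, "TaskBoxcar"))
  if (is.vector(ts)) ts <- matrix(ts, ncol = 1)
  n <- nrow(ts)
  if (n != length(boxcar@values))
    stop("time series length (", n, ") must match the boxcar (",
         length(boxcar@values), ")")
  dt <- boxcar@totalS / length(boxcar@values)
  X0 <- dctBasis(n, dt, hpCutoffS) # includes the constant column
  resid <- function(m) m - X0 %*% qr.coef(qr(X0), m)
  constant <- apply(ts, 2, function(v) stats::sd(v) == 0)
  if (any(constant))
    warning(sum(constant), " constant time series; beta set to 0")
  y <- resid(ts)
  x <- drop(resid(matrix(as.numeric(boxcar@values), ncol = 1)))
  beta <- rep(0, ncol(ts))
  ok <- !constant
  if (any(ok)) {
    b0 <- crossprod(y[, ok, drop = FALSE], x) / sum(x * x)
    if (ar1) {
      r <- y[, ok, drop = FALSE] - outer(x, drop(b0))
      num <- colSums(r[-1, , drop = FALSE] * r[-n, , drop = FALSE])
      den <- colSums(r^2)
      rho <- sum(num) / sum(den) # pooled lag-1 estimate
      rho <- max(min(rho, 0.99), -0.99)
      yw <- y[-1, ok, drop = FALSE] - rho * y[-n, ok, drop = FALSE]
      xw <- x[-1] - rho * x[-n]
      beta[ok] <- crossprod(yw, xw) / sum(xw * xw)
    } else {
      beta[ok] <- b0
    }
  }
  if (is.null(dims)) return(drop(beta))
  new("BetaVolume", grid = array(beta, dims), affine = affine,
      subject = subject, condition = condition)
}

## discrete-cosine high-pass basis (constant + cosines below 1/cutoff)
dctBasis <- function(n, dt, cutoffS) {
  K <- floor(2 * n * dt / cutoffS)
  t <- seq_len(n) - 0.5
  X <- matrix(1 / sqrt(n), n, 1)
  if (K >= 1)
    X <- cbind(X, sapply(seq_len(K), function(k)
      sqrt(2 / n) * cos(pi * k * t / n)))
  X
}

labelIndices <- function(atlas, segment, hemisphere = NULL) {
  tab <- labelTable(atlas)
  sel <- tab$segment == segment
  if (!is.null(hemisphere)) sel <- sel & tab$hemisphere == hemisphere
  labs <- tab$label[sel]
  if (!length(labs))
    stop("segment '", segment, "'",
         if (!is.null(hemisphere)) paste0(" (", hemisphere, ")"),
         " not present in atlas")
  which(array(voxelGrid(atlas) %in% labs, dim(voxelGrid(atlas))))
}

#' Select the most active voxels of a segment
#'
#' Proportional thresholding: returns the \code{floor(fraction * N)}
#' voxels with the highest beta values within the given (segment,
#' hemisphere) label. A proportional rather than absolute threshold makes
#' the selection invariant to global signal scaling. Ties at the
#' threshold are broken by linear voxel index, so the selection is
#' deterministic across runs and platforms.
#'
#' @param beta a \linkS4class{BetaVolume}.
#' @param atlas a \linkS4class{LabelAtlas} on the same grid.
#' @param segment segment name.
#' @param hemisphere \code{"L"}, \code{"R"}, or NULL to pool both.
#' @param fraction proportional threshold in (0, 1] (default 0.15).
#' @return integer vector of linear voxel indices, highest beta first.
#' @export
selectTopVoxels <- function(beta, atlas, segment, hemisphere = NULL,
                            fraction = 0.15) {
  stopifnot(is(beta, "BetaVolume"), is(atlas, "LabelAtlas"),
            fraction > 0, fraction <= 1)
  if (!all(dim(voxelGrid(beta)) == dim(voxelGrid(atlas))))
    stop("beta and atlas grids differ: ",
         paste(dim(voxelGrid(beta)), collapse = "x"), " vs ",
         paste(dim(voxelGrid(atlas)), collapse = "x"))
  idx <- labelIndices(atlas, segment, hemisphere)
  k <- floor(fraction * length(idx))
  if (k < 1)
    stop("segment '", segment, "' too small: ", length(idx),
         " voxels yield an empty top-", fraction * 100, "% selection")
  b <- voxelGrid(beta)[idx]
  ord <- order(-b, idx) # highest beta first, ties by voxel index
  idx[ord[seq_len(k)]]
}

#' Mean beta over a voxel selection
#'
#' @param beta a \linkS4class{BetaVolume}.
#' @param selection integer vector of linear voxel indices (from
#'   [selectTopVoxels()]).
#' @return arithmetic mean of the selected betas.
#' @export
roiMeanBeta <- function(beta, selection) {
  stopifnot(is(beta, "BetaVolume"))
  if (!length(selection)) stop("empty voxel selection")
  mean(voxelGrid(beta)[selection])
}

#' Laterality index of a bilateral segment
#'
#' Pools the voxels of both hemispheres of a segment, selects the top
#' \code{fraction} by beta value, and counts selected voxels per
#' hemisphere. The index is
#' \deqn{LI = (vox_i - vox_c) / (vox_i + vox_c)}
#' where \eqn{vox_i} and \eqn{vox_c} count selected voxels in the
#' ipsilesional and contralesional hemisphere: 1 means all activated
#' voxels are ipsilesional, -1 all contralesional.
#'
#' @inheritParams selectTopVoxels
#' @param lesionSide \code{"L"} or \code{"R"}: the ipsilesional
#'   hemisphere.
#' @return laterality index in [-1, 1].
#' @export
lateralityIndex <- function(beta, atlas, segment, lesionSide,
                            fraction = 0.15) {
  stopifnot(lesionSide %in% c("L", "R"))
  sel <- selectTopVoxels(beta, atlas, segment, hemisphere = NULL,
                         fraction = fraction)
  ipsIdx <- labelIndices(atlas, segment, lesionSide)
  voxI <- sum(sel %in% ipsIdx)
  voxC <- length(sel) - voxI
  (voxI - voxC) / (voxI + voxC)
}

#' Summarize all segments of a subject
#'
#' Per-hemisphere proportional-threshold mean betas plus the pooled
#' bilateral laterality index for every segment of the atlas.
#'
#' @inheritParams lateralityIndex
#' @return data.frame with columns \code{segment}, \code{hemisphere},
#'   \code{n_selected}, \code{mean_beta}, \code{li} (the LI is repeated
#'   on both hemisphere rows of a segment).
#' @export
roiSummary <- function(beta, atlas, lesionSide, fraction = 0.15) {
  tab <- labelTable(atlas)
  segs <- unique(tab$segment)
  rows <- lapply(segs, function(sg) {
    li <- lateralityIndex(beta, atlas, sg, lesionSide, fraction)
    do.call(rbind, lapply(c("L", "R"), function(h) {
      sel <- selectTopVoxels(beta, atlas, sg, h, fraction)
      data.frame(
        segment = sg, hemisphere = h, n_selected = length(sel),
        mean_beta = roiMeanBeta(beta, sel), li = li,
        stringsAsFactors = FALSE
      )
    }))
  })
  do.call(rbind, rows)
}

## identify the voxel axis mapping to world left-right from the affine
lrAxis <- function(affine) {
  row <- abs(affine[1, 1:3])
  a <- which.max(row)
  if (sum(row > 0.5 * row[a]) > 1)
    stop("affine orientation ambiguous: no single dominant left-right ",
         "axis; pass the axis explicitly")
  a
}

flipGrid <- function(grid, a) {
  n <- dim(grid)[a]
  idx <- rep(list(quote(expr = )), 3)
  idx[[a]] <- n:1
  do.call(`[`, c(list(grid), idx, list(drop = FALSE)))
}

flipAffine <- function(affine, a, n) {
  affine[, 4] <- affine[, 4] + affine[, a] * (n - 1)
  affine[, a] <- -affine[, a]
  affine
}

#' @rdname flipHemispheres
setMethod("flipHemispheres", "BetaVolume", function(x, axis = NULL) {
  a <- if (is.null(axis)) lrAxis(x@affine) else axis
  n <- dim(x@grid)[a]
  new("BetaVolume",
    grid = flipGrid(x@grid, a), affine = flipAffine(x@affine, a, n),
    subject = x@subject, condition = x@condition
  )
})

#' @rdname flipHemispheres
setMethod("flipHemispheres", "LabelAtlas", function(x, axis = NULL) {
  a <- if (is.null(axis)) lrAxis(x@affine) else axis
  n <- dim(x@grid)[a]
  tab <- x@table
  tab$hemisphere <- ifelse(tab$hemisphere == "L", "R", "L")
  new("LabelAtlas",
    grid = flipGrid(x@grid, a), affine = flipAffine(x@affine, a, n),
    table = tab
  )
})

#' Gaussian spatial smoothing of a beta volume
#'
#' Separable Gaussian smoothing with the kernel width given as full
#' width at half maximum in millimetres (sigma = fwhm / (2 sqrt(2 ln 2))
#' per axis, converted to voxels via the affine). Used on the voxelwise
#' group-comparison path; proportional-threshold ROI analysis runs on
#' unsmoothed data.
#'
#' @param beta a \linkS4class{BetaVolume}.
#' @param fwhmMm full width at half maximum in mm; 0 returns the input
#'   unchanged.
#' @return a smoothed \linkS4class{BetaVolume}.
#' @export
smoothVolume <- function(beta, fwhmMm = 8) {
  stopifnot(is(beta, "BetaVolume"), fwhmMm >= 0)
  if (fwhmMm == 0) return(beta)
  voxMm <- sqrt(colSums(beta@affine[1:3, 1:3]^2))
  sigmaVox <- (fwhmMm / (2 * sqrt(2 * log(2)))) / voxMm
  g <- beta@grid
  for (a in 1:3) g <- convolveAxis(g, a, gaussKernel(sigmaVox[a]))
  new("BetaVolume", grid = g, affine = beta@affine,
      subject = beta@subject, condition = beta@condition)
}

gaussKernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

## 1-D convolution along one axis of a 3-D array, zero-padded edges
convolveAxis <- function(g, a, k) {
  if (length(k) == 1) return(g)
  d <- dim(g)
  perm <- c(a, setdiff(1:3, a))
  m <- matrix(aperm(g, perm), nrow = d[a])
  r <- (length(k) - 1) / 2
  padded <- rbind(
    matrix(0, r, ncol(m)), m, matrix(0, r, ncol(m))
  )
  out <- matrix(0, d[a], ncol(m))
  for (j in seq_along(k))
    out <- out + k[j] * padded[j:(j + d[a] - 1), , drop = FALSE]
  aperm(array(out, d[perm]), order(perm))
}
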