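#' @include AllClasses.R
NULL

#' Sample times of a series or boxcar
#' @param x a TaskBoxcar, SampledSeries or derived object
#' @return numeric vector of times in seconds
#' @export
setGeneric("sampleTimes", function(x) standardGeneric("sampleTimes"))

#' Sample values of a series or boxcar
#' @param x a TaskBoxcar, SampledSeries or derived object
#' @return numeric (or 0/1 integer) vector of sample values
#' @export
setGeneric("sampleValues", function(x) standardGeneric("sampleValues"))

#' Sampling rate in Hz
#' @param x a SampledSeries or TaskBoxcar
#' @return sampling rate (Hz)
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Voxel grid of a volume object
#' @param x a BetaVolume or LabelAtlas
#' @return the 3-D array
#' @export
setGeneric("voxelGrid", function(x) standardGeneric("voxelGrid"))

#' Voxel-to-world affine of a volume object
#' @param x a BetaVolume or LabelAtlas
#' @return 4x4 matrix
#' @export
setGeneric("voxelAffine", function(x) standardGeneric("voxelAffine"))

#' Label table of an atlas
#' @param x a LabelAtlas
#' @return data.frame with columns label, segment, hemisphere
#' @export
setGeneric("labelTable", function(x) standardGeneric("labelTable"))

#' Mirror a volume across the mid-sagittal plane
#'
#' Reverses the left-right voxel axis (identified from the affine) so the
#' two hemispheres swap sides; applied to patients with right-sided lesions
#' so the affected hemisphere lies on a common side across subjects.
#' Applying the flip twice restores the original object. For a
#' \linkS4class{LabelAtlas} the hemisphere column of the label table is
#' swapped along with the grid.
#'
#' @param x a \linkS4class{BetaVolume} or \linkS4class{LabelAtlas}
#' @param axis optional integer axis to flip; by default the left-right
#'   axis is determined from the affine and an error is raised if no axis
#'   is clearly left-right.
#' @return an object of the same class, mirrored
#' @export
setGeneric("flipHemispheres", function(x, axis = NULL) standardGeneric("flipHemispheres"))

setMethod("sampleTimes", "TaskBoxcar", function(x) x@sampleTimes)
setMethod("sampleTimes", "SampledSeries", function(x) x@sampleTimes)
setMethod("sampleValues", "TaskBoxcar", function(x) x@values)
setMethod("sampleValues", "SampledSeries", function(x) x@values)
setMethod("samplingRate", "SampledSeries", function(x) x@fs)
setMethod("samplingRate", "TaskBoxcar", function(x) {
  1 / mean(diff(x@sampleTimes))
})
setMethod("voxelGrid", "BetaVolume", function(x) x@grid)
setMethod("voxelGrid", "LabelAtlas", function(x) x@grid)
setMethod("voxelAffine", "BetaVolume", function(x) x@affine)
setMethod("voxelAffine", "LabelAtlas", function(x) x@affine)
setMethod("labelTable", "LabelAtlas", function(x) x@table)

setMethod("show", "TaskBoxcar", function(object) {
  cat(sprintf(
    "TaskBoxcar: %g s blocks over %g s (%d samples at %.4g Hz), %d move blocks\n",
    object@blockS, object@totalS, length(object@values),
    samplingRate(object), sum(rle(object@values)$values == 1L)
  ))
})

setMethod("show", "SampledSeries", function(object) {
  cat(sprintf(
    "%s: %d samples at %g Hz (%.4g s), units '%s', range [%.4g, %.4g]\n",
    class(object), length(object@values), object@fs,
    length(object@values) / object@fs, object@units,
    min(object@values), max(object@values)
  ))
})

setMethod("show", "BetaVolume", function(object) {
  d <- dim(object@grid)
  cat(sprintf(
    "BetaVolume: %d x %d x %d voxels, subject '%s', condition '%s'\n",
    d[1], d[2], d[3], object@subject, object@condition
  ))
})

setMethod("show", "LabelAtlas", function(object) {
  d <- dim(object@grid)
  segs <- unique(object@table$segment)
  cat(sprintf(
    "LabelAtlas: %d x %d x %d voxels, %d labels over %d segments (%s)\n",
    d[1], d[2], d[3], nrow(object@table), length(segs),
    paste(segs, collapse = ", ")
  ))
})
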