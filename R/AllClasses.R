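#' @import methods
NULL

#' Binary task indicator for a block-design motor paradigm
#'
#' A \code{TaskBoxcar} holds the move/rest indicator of an alternating
#' block design, sampled on a uniform time grid. The default paradigm is
#' 20 s of movement alternating with 20 s of rest for 6 minutes, starting
#' with rest.
#'
#' @slot sampleTimes numeric, uniform time grid in seconds.
#' @slot values integer vector of 0 (rest) and 1 (move), one per sample.
#' @slot blockS block duration in seconds.
#' @slot totalS total run duration in seconds.
#'
#' @seealso [makeTaskBoxcar()]
#' @export
setClass("TaskBoxcar",
  representation(
    sampleTimes = "numeric",
    values = "integer",
    blockS = "numeric",
    totalS = "numeric"
  )
)

setValidity("TaskBoxcar", function(object) {
  msg <- character()
  if (length(object@sampleTimes) != length(object@values))
    msg <- c(msg, "sampleTimes and values must have equal length")
  if (!all(object@values %in% c(0L, 1L)))
    msg <- c(msg, "values must be 0 or 1")
  if (length(object@sampleTimes) > 2) {
    dts <- diff(object@sampleTimes)
    if (diff(range(dts)) > 1e-8 * mean(dts))
      msg <- c(msg, "sampleTimes must be a uniform grid")
  }
  if (object@blockS <= 0 || object@totalS <= 0)
    msg <- c(msg, "blockS and totalS must be positive")
  if (length(msg)) msg else TRUE
})

#' Uniformly sampled one-dimensional physiological signal
#'
#' Container for a glove angle trace (degrees) or an EMG amplitude trace
#' (arbitrary units) on a strictly uniform time grid.
#'
#' @slot sampleTimes numeric, uniform time grid in seconds.
#' @slot values numeric signal values.
#' @slot fs sampling rate in Hz.
#' @slot units character, physical units of \code{values}.
#'
#' @export
setClass("SampledSeries",
  representation(
    sampleTimes = "numeric",
    values = "numeric",
    fs = "numeric",
    units = "character"
  ),
  prototype(units = "au")
)

setValidity("SampledSeries", function(object) {
  msg <- character()
  if (length(object@sampleTimes) != length(object@values))
    msg <- c(msg, "sampleTimes and values must have equal length")
  if (length(object@fs) != 1 || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (anyNA(object@values))
    msg <- c(msg, "values must not contain missing samples")
  if (length(object@sampleTimes) > 2) {
    dts <- diff(object@sampleTimes)
    if (diff(range(dts)) > 1e-6 / object@fs)
      msg <- c(msg, "sampleTimes must be a strictly uniform grid")
  }
  if (length(msg)) msg else TRUE
})

#' Non-negative amplitude envelope of a physiological signal
#'
#' The magnitude of the analytic signal after moving-average smoothing,
#' on the same grid as its source series.
#'
#' @slot source character, \code{"glove"} or \code{"emg"}.
#' @export
setClass("EnvelopeSeries",
  contains = "SampledSeries",
  representation(source = "character"),
  prototype(source = "emg")
)

setValidity("EnvelopeSeries", function(object) {
  msg <- character()
  if (any(object@values < -1e-9))
    msg <- c(msg, "envelope values must be non-negative")
  if (!object@source %in% c("glove", "emg"))
    msg <- c(msg, "source must be 'glove' or 'emg'")
  if (length(msg)) msg else TRUE
})

#' Voxel grid of first-level GLM coefficients
#'
#' A 3-D array of beta (task-regressor) coefficients with a voxel-to-world
#' affine, as produced by a first-level block GLM or read from a NIfTI
#' contrast map.
#'
#' @slot grid 3-D numeric array of beta values.
#' @slot affine 4x4 voxel-to-world matrix (mm).
#' @slot subject character subject identifier.
#' @slot condition character condition label (e.g. "affected_amplitude").
#'
#' @export
setClass("BetaVolume",
  representation(
    grid = "array",
    affine = "matrix",
    subject = "character",
    condition = "character"
  ),
  prototype(subject = NA_character_, condition = NA_character_)
)

setValidity("BetaVolume", function(object) {
  msg <- character()
  if (length(dim(object@grid)) != 3)
    msg <- c(msg, "grid must be a 3-D array")
  if (!all(dim(object@affine) == c(4, 4)))
    msg <- c(msg, "affine must be a 4x4 matrix")
  if (length(msg)) msg else TRUE
})

#' Integer label atlas of anatomical motor segments
#'
#' A 3-D integer volume whose nonzero labels partition the motor network
#' into anatomical segments (cerebellum, SMA, premotor, precentral,
#' postcentral, insula) split by hemisphere, plus a label table mapping
#' each label id to its (segment, hemisphere) pair.
#'
#' @slot grid 3-D integer array of labels; 0 is background.
#' @slot affine 4x4 voxel-to-world matrix (mm).
#' @slot table data.frame with columns \code{label}, \code{segment},
#'   \code{hemisphere}.
#'
#' @export
setClass("LabelAtlas",
  representation(
    grid = "array",
    affine = "matrix",
    table = "data.frame"
  )
)

setValidity("LabelAtlas", function(object) {
  msg <- character()
  if (length(dim(object@grid)) != 3)
    msg <- c(msg, "grid must be a 3-D array")
  if (!all(dim(object@affine) == c(4, 4)))
    msg <- c(msg, "affine must be a 4x4 matrix")
  need <- c("label", "segment", "hemisphere")
  if (!all(need %in% names(object@table)))
    msg <- c(msg, "table must have columns label, segment, hemisphere")
  else {
    labs <- sort(unique(as.vector(object@grid)))
    labs <- labs[labs != 0]
    if (!all(labs %in% object@table$label))
      msg <- c(msg, "every nonzero grid label must appear in the label table")
    if (!all(object@table$hemisphere %in% c("L", "R")))
      msg <- c(msg, "hemisphere must be 'L' or 'R'")
  }
  if (length(msg)) msg else TRUE
})
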