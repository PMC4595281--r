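#' Write a beta volume to NIfTI-1
#'
#' @param vol a \linkS4class{BetaVolume}.
#' @param path output path (.nii or .nii.gz).
#' @return the path, invisibly.
#' @export
writeBetaVolume <- function(vol, path) {
  stopifnot(is(vol, "BetaVolume"))
  writeNiftiGrid(vol@grid, vol@affine, path)
}

#' Write a label atlas to NIfTI-1 plus a label-table CSV
#'
#' @param atlas a \linkS4class{LabelAtlas}.
#' @param path output NIfTI path.
#' @param labelsCsv output path of the label table
#'   (\code{label,segment,hemisphere}); defaults to \code{path} with a
#'   \code{_labels.csv} suffix.
#' @return the NIfTI path, invisibly.
#' @export
writeLabelAtlas <- function(atlas, path,
                            labelsCsv = sub("\\.nii(\\.gz)?$",
                                            "_labels.csv", path)) {
  stopifnot(is(atlas, "LabelAtlas"))
  utils::write.csv(atlas@table, labelsCsv, row.names = FALSE,
                   quote = FALSE)
  writeNiftiGrid(atlas@grid, atlas@affine, path)
}

writeNiftiGrid <- function(grid, affine, path) {
  img <- RNifti::asNifti(grid)
  RNifti::pixdim(img) <- sqrt(colSums(affine[1:3, 1:3]^2))
  aff <- structure(affine, code = 2L)
  img <- RNifti::`sform<-`(img, aff)
  img <- RNifti::`qform<-`(img, aff)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a BetaVolume
#'
#' @param path NIfTI-1 file (.nii or .nii.gz).
#' @param subject,condition metadata labels.
#' @return a \linkS4class{BetaVolume}.
#' @export
readBetaVolume <- function(path, subject = NA_character_,
                           condition = NA_character_) {
  r <- readNiftiGrid(path)
  new("BetaVolume", grid = r$grid, affine = r$affine,
      subject = subject, condition = condition)
}

#' Read a NIfTI label volume and its label table as a LabelAtlas
#'
#' @param path NIfTI-1 file of integer labels.
#' @param labelsCsv CSV with columns \code{label,segment,hemisphere}.
#' @return a \linkS4class{LabelAtlas}.
#' @export
readLabelAtlas <- function(path, labelsCsv) {
  r <- readNiftiGrid(path)
  grid <- r$grid
  if (max(abs(grid - round(grid))) > 1e-6)
    stop("label volume contains non-integer values")
  storage.mode(grid) <- "integer"
  tab <- utils::read.csv(labelsCsv, stringsAsFactors = FALSE)
  new("LabelAtlas", grid = grid, affine = r$affine, table = tab)
}

readNiftiGrid <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3)
    stop("expected a 3-D volume, got dimensions ",
         paste(d, collapse = " x "))
  aff <- RNifti::xform(img, useQuaternionFirst = FALSE)
  list(grid = array(as.numeric(img), d),
       affine = matrix(as.numeric(aff), 4, 4))
}

#' Write a sampled series as two-column delimited text
#'
#' Columns \code{time_s} and \code{value}, tab-separated with a header.
#'
#' @param series a \linkS4class{SampledSeries}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeSignal <- function(series, path) {
  stopifnot(is(series, "SampledSeries"))
  df <- data.frame(time_s = series@sampleTimes, value = series@values)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a two-column delimited signal file
#'
#' Expects columns time on a uniform grid and value; the sampling rate
#' is inferred from the grid.
#'
#' @param path input path (tab- or comma-delimited, with header).
#' @param units physical units to record.
#' @return a \linkS4class{SampledSeries}.
#' @export
readSignal <- function(path, units = "au") {
  df <- utils::read.table(path, header = TRUE, sep = "",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) df <- utils::read.csv(path)
  t <- df[[1]]; v <- df[[2]]
  dt <- diff(t)
  if (diff(range(dt)) > 1e-6 * mean(dt))
    stop("signal file does not have a uniform time grid")
  new("SampledSeries", sampleTimes = t, values = as.numeric(v),
      fs = 1 / mean(dt), units = units)
}

fixtureChecksums <- c(
  table1_patients.csv = "391ce4c8f90fcb7b0846c60995c49ffa",
  table2_patient_performance.csv = "4afa202da6dc493c93dc7eed070cd18d",
  table3_control_performance.csv = "59b94be6691ab241d81849b3e243dc28"
)

#' Load the packaged performance and clinical reference tables
#'
#' Reads the CSV transcriptions shipped with the package: per-patient
#' clinical characteristics (20 rows: time post stroke, lesion side,
#' Fugl-Meyer, ARAT, \%NHPT), and per-subject task-performance rows for
#' 20 patients and 15 controls (MM_EMG per condition, MM_glove,
#' compliance correlation and movement counts for the amplitude task).
#' Missing cells (equipment malfunction) are preserved as \code{NA},
#' never imputed. File checksums are validated, since these tables are
#' part of the package's verification surface.
#'
#' @return list with data.frames \code{table1}, \code{table2},
#'   \code{table3}.
#' @export
loadFixtureTables <- function() {
  dir <- system.file("extdata", package = "hemiscope")
  files <- names(fixtureChecksums)
  paths <- file.path(dir, files)
  sums <- unname(tools::md5sum(paths))
  bad <- sums != unname(fixtureChecksums)
  if (any(is.na(sums)) || any(bad))
    stop("fixture table checksum mismatch: ",
         paste(files[is.na(sums) | bad], collapse = ", "))
  out <- lapply(paths, utils::read.csv, stringsAsFactors = FALSE)
  names(out) <- c("table1", "table2", "table3")
  if (nrow(out$table1) != 20 || nrow(out$table2) != 20 ||
      nrow(out$table3) != 15)
    stop("fixture tables have unexpected row counts")
  out
}
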