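#' Construct the task boxcar of an alternating block design
#'
#' Builds the binary move/rest indicator of a block paradigm that starts
#' with rest and alternates equal-length blocks: the defaults encode 20 s
#' of finger flexion-extension alternating with 20 s of rest over 6
#' minutes.
#'
#' @param blockS block duration in seconds (default 20).
#' @param totalS total run duration in seconds; must be an integer
#'   multiple of \code{2 * blockS} (default 360).
#' @param dt sampling interval in seconds; must divide \code{blockS}.
#' @return a \linkS4class{TaskBoxcar} with \code{totalS/dt} samples.
#'
#' @examples
#' bc <- makeTaskBoxcar()
#' mean(sampleValues(bc)) # 0.5: equal move and rest time
#' @export
makeTaskBoxcar <- function(blockS = 20, totalS = 360, dt = 0.5) {
  stopifnot(blockS > 0, totalS > 0, dt > 0)
  nCycles <- totalS / (2 * blockS)
  if (abs(nCycles - round(nCycles)) > 1e-9)
    stop(
      "totalS (", totalS, " s) must be an integer multiple of one ",
      "rest+move cycle (2 * blockS = ", 2 * blockS, " s)"
    )
  perBlock <- blockS / dt
  if (abs(perBlock - round(perBlock)) > 1e-9)
    stop(
      "dt (", dt, " s) must divide blockS (", blockS,
      " s); got ", blockS / dt, " samples per block"
    )
  n <- as.integer(round(totalS / dt))
  t <- (seq_len(n) - 1) * dt
  blk <- floor(t / blockS)
  new("TaskBoxcar",
    sampleTimes = t,
    values = as.integer(blk %% 2 == 1),
    blockS = blockS, totalS = totalS
  )
}

#' Logical move-block mask for a series grid
#'
#' @param boxcar a \linkS4class{TaskBoxcar}
#' @param series a \linkS4class{SampledSeries}; if missing, the boxcar's
#'   own grid is used.
#' @return logical vector, TRUE during move blocks
#' @export
moveMask <- function(boxcar, series) {
  if (missing(series)) return(boxcar@values == 1L)
  boxcarOnGrid(boxcar, series) == 1L
}
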