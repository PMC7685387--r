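#' Measure one paired frame (image + detector record)
#'
#' Runs the image pipeline ([measureDiameter()]) and the velocimetry pipeline
#' ([computePowerSpectrum()] -> [detectCutoff()] per channel ->
#' [deltaCutoff()] -> [computeVmax()]) on one frame and combines them into a
#' per-frame measurement row. Image QC failures are reported as
#' `image_failed`, missing cutoffs as `spectrum_failed`.
#'
#' @param image 16-bit intensity matrix.
#' @param record A [DetectorRecord-class].
#' @param config An [OpticalConfig-class].
#' @param axialLengthMm Axial eye length for the pixel conversion, mm.
#' @param frameIndex Frame counter.
#' @param convention Flow convention, see [computeFlow()].
#' @param ... Passed to [measureDiameter()].
#' @return A one-row data.frame, see [frameMeasurement()].
#' @export
measureFrame <- function(image, record, config = OpticalConfig(),
                         axialLengthMm = config@axialLengthAssumed,
                         frameIndex = 0L, convention = "poiseuille", ...) {
  dia <- measureDiameter(image, axialLengthMm, config, ...)
  if (qcStatus(dia) != "ok")
    return(frameMeasurement(frameIndex, qcStatus = "image_failed"))
  sp <- computePowerSpectrum(record)
  ca <- detectCutoff(sp$A)
  cb <- detectCutoff(sp$B)
  if (qualityFlag(ca) != "ok" || qualityFlag(cb) != "ok")
    return(frameMeasurement(frameIndex, diameterUm = diameterUm(dia),
                            qcStatus = "spectrum_failed"))
  df <- abs(cutoffHz(ca) - cutoffHz(cb))
  v <- computeVmax(df, config, frameIndex = frameIndex)
  frameMeasurement(frameIndex, diameterUm = diameterUm(dia),
                   vmaxMmS = 1e3 * vmax(v), qcStatus = "ok",
                   convention = convention)
}

#' Measure a whole acquisition
#'
#' @param acquisition A list with element `frames`, itself a list of
#'   `list(image=, record=)` pairs (the shape produced by
#'   [simulateBifurcation()]).
#' @inheritParams measureFrame
#' @return A [FlowEstimate-class].
#' @export
measureAcquisition <- function(acquisition, config = OpticalConfig(),
                               axialLengthMm = config@axialLengthAssumed,
                               convention = "poiseuille", ...) {
  frames <- acquisition$frames
  stopifnot(length(frames) >= 1L)
  rows <- lapply(seq_along(frames), function(i)
    measureFrame(frames[[i]]$image, frames[[i]]$record, config,
                 axialLengthMm, frameIndex = i - 1L,
                 convention = convention, ...))
  aggregateAcquisition(do.call(rbind, rows))
}

#' Measure a simulated or recorded bifurcation
#'
#' Runs [measureAcquisition()] on the parent and both daughter acquisitions
#' and evaluates flow conservation.
#'
#' @param bifurcation A named list `parent` / `daughter1` / `daughter2` as
#'   produced by [simulateBifurcation()].
#' @inheritParams measureFrame
#' @return A list: `result` (a [BifurcationResult-class]) and `flows` (the
#'   three [FlowEstimate-class] objects).
#' @export
measureBifurcation <- function(bifurcation, config = OpticalConfig(),
                               axialLengthMm = config@axialLengthAssumed,
                               convention = "poiseuille", ...) {
  est <- lapply(bifurcation[c("parent", "daughter1", "daughter2")],
                measureAcquisition, config = config,
                axialLengthMm = axialLengthMm, convention = convention, ...)
  list(result = bifurcationConservation(meanFlowUlMin(est$parent),
                                        meanFlowUlMin(est$daughter1),
                                        meanFlowUlMin(est$daughter2)),
       flows = est)
}
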