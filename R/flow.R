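#' Absolute flow from diameter and maximum velocity
#'
#' Assuming Poiseuille flow in a cylindrical cross section, the mean velocity
#' is half the centerline velocity and the flow is
#' `F = pi * (d/2)^2 * vmax / 2`. The `"cross_section"` convention drops the
#' 1/2 factor (`F = pi * (d/2)^2 * vmax`), which is the relation the
#' in-vitro capillary validation data follow (plug-like seeding of the
#' tracer); both are exposed so either bench or in-vivo conventions can be
#' reproduced.
#'
#' @param diameterUm Vessel lumen diameter in micrometers (> 0).
#' @param vmaxMmS Maximum (centerline) velocity in mm/s (>= 0).
#' @param convention `"poiseuille"` (default, with the 1/2 factor) or
#'   `"cross_section"`.
#' @return Flow in microliters per minute (1 m^3/s = 6e10 uL/min).
#' @examples
#' computeFlow(100, 10)  # 2.356 uL/min
#' @export
computeFlow <- function(diameterUm, vmaxMmS,
                        convention = c("poiseuille", "cross_section")) {
  convention <- match.arg(convention)
  if (any(!is.finite(diameterUm)) || any(diameterUm <= 0))
    stop("invalid input: diameter must be positive")
  if (any(!is.finite(vmaxMmS)) || any(vmaxMmS < 0))
    stop("invalid input: vmax must be non-negative")
  half <- if (convention == "poiseuille") 0.5 else 1
  fM3s <- pi * (diameterUm * 1e-6 / 2)^2 * (vmaxMmS * 1e-3) * half
  fM3s * 6e10
}

#' Velocity that produces a prescribed flow
#'
#' Inverse of [computeFlow()] for the simulator and the in-silico linearity
#' experiment.
#'
#' @inheritParams computeFlow
#' @param flowUlMin Flow in uL/min.
#' @return Maximum velocity in mm/s.
#' @export
invertFlowToVmax <- function(flowUlMin, diameterUm,
                             convention = c("poiseuille", "cross_section")) {
  convention <- match.arg(convention)
  if (any(diameterUm <= 0)) stop("invalid input: diameter must be positive")
  half <- if (convention == "poiseuille") 0.5 else 1
  (flowUlMin / 6e10) / (pi * (diameterUm * 1e-6 / 2)^2 * half) * 1e3
}

#' Build one per-frame measurement row
#'
#' Frames pair one fundus image with one pair of Doppler spectra; flow is
#' present only when both the diameter and the velocity are.
#'
#' @param frameIndex Frame counter.
#' @param diameterUm Diameter in um, or `NA`.
#' @param vmaxMmS Velocity in mm/s, or `NA`.
#' @param qcStatus `"ok"`, `"image_failed"` or `"spectrum_failed"`.
#' @param convention Flow convention, see [computeFlow()].
#' @return A one-row data.frame with columns `frameIndex`, `diameterUm`,
#'   `vmaxMmS`, `flowUlMin`, `qcStatus`.
#' @export
frameMeasurement <- function(frameIndex, diameterUm = NA_real_,
                             vmaxMmS = NA_real_,
                             qcStatus = c("ok", "image_failed",
                                          "spectrum_failed"),
                             convention = "poiseuille") {
  qcStatus <- match.arg(qcStatus)
  flow <- if (qcStatus == "ok" && is.finite(diameterUm) && is.finite(vmaxMmS))
    computeFlow(diameterUm, vmaxMmS, convention) else NA_real_
  data.frame(frameIndex = as.integer(frameIndex), diameterUm = diameterUm,
             vmaxMmS = vmaxMmS, flowUlMin = flow, qcStatus = qcStatus,
             stringsAsFactors = FALSE)
}

#' Aggregate per-frame flows over one acquisition
#'
#' The acquisition mean is the average of the per-frame flows over QC-passed
#' frames (not the flow of averaged diameter and velocity: each frame pairs
#' one image with one spectrum pair, and flow is nonlinear in the diameter).
#' Exclusion counts are reported alongside.
#'
#' @param frames A data.frame of per-frame rows (see [frameMeasurement()]).
#' @return A [FlowEstimate-class].
#' @export
aggregateAcquisition <- function(frames) {
  stopifnot(is.data.frame(frames), nrow(frames) >= 1L,
            all(c("flowUlMin", "qcStatus") %in% names(frames)))
  used <- frames$qcStatus == "ok" & is.finite(frames$flowUlMin)
  if (!any(used))
    stop("no measurement: all frames failed quality control")
  new("FlowEstimate",
      meanFlowUlMin = mean(frames$flowUlMin[used]),
      nFramesTotal = nrow(frames),
      nFramesUsed = sum(used),
      perFrame = frames)
}

#' @rdname flow-accessors
#' @export
setMethod("meanFlowUlMin", "FlowEstimate", function(object) object@meanFlowUlMin)

#' @rdname flow-accessors
#' @export
setMethod("perFrame", "FlowEstimate", function(object) object@perFrame)

setMethod("show", "FlowEstimate", function(object) {
  cat(sprintf("FlowEstimate: %.2f uL/min over %d/%d frames (%.0f%% excluded)\n",
              object@meanFlowUlMin, object@nFramesUsed, object@nFramesTotal,
              100 * (1 - object@nFramesUsed / object@nFramesTotal)))
})

#' Flow conservation at a venous bifurcation
#'
#' At a junction the parent flow should equal the sum of the daughter flows;
#' the residual `deltaF = fPV - (fDV1 + fDV2)` and its fraction of the parent
#' flow quantify the internal accuracy of the measurements.
#'
#' @param fPV Parent-vessel flow, uL/min (> 0).
#' @param fDV1,fDV2 Daughter-vessel flows, uL/min (> 0).
#' @return A [BifurcationResult-class].
#' @examples
#' bifurcationConservation(4.6, 1.4, 3.4)  # deltaF = -0.2, -4.3 %
#' @export
bifurcationConservation <- function(fPV, fDV1, fDV2) {
  if (!is.finite(fPV) || fPV <= 0)
    stop("invalid input: parent flow must be positive")
  if (any(!is.finite(c(fDV1, fDV2))) || any(c(fDV1, fDV2) <= 0))
    stop("invalid input: daughter flows must be positive")
  dF <- fPV - (fDV1 + fDV2)
  new("BifurcationResult", fPV = fPV, fDV1 = fDV1, fDV2 = fDV2,
      deltaF = dF, deltaFRel = 100 * dF / fPV)
}

#' @rdname BifurcationResult-accessors
#' @export
setMethod("deltaFRel", "BifurcationResult", function(object) object@deltaFRel)

setMethod("show", "BifurcationResult", function(object) {
  cat(sprintf(
    "BifurcationResult: F_PV %.2f = %.2f + %.2f + deltaF %.2f uL/min (%.1f%%)\n",
    object@fPV, object@fDV1, object@fDV2, object@deltaF, object@deltaFRel))
})

#' Summary statistics of conservation errors
#'
#' @param deltaFRelValues Relative conservation errors in percent (>= 2).
#' @return A list with `mean`, `sd` (sample, n - 1), `min`, `max`.
#' @export
conservationSummary <- function(deltaFRelValues) {
  x <- as.numeric(deltaFRelValues)
  if (length(x) < 2L || anyNA(x))
    stop("invalid input: need at least 2 finite values")
  list(mean = mean(x), sd = stats::sd(x), min = min(x), max = max(x))
}

#' Summary of a set of flows
#'
#' @param flows Flows in uL/min (>= 1 value).
#' @return A list with `mean`, `min`, `max`.
#' @export
flowTableSummary <- function(flows) {
  x <- as.numeric(flows)
  if (length(x) < 1L || anyNA(x))
    stop("invalid input: need at least 1 finite flow")
  list(mean = mean(x), min = min(x), max = max(x))
}

#' Reference venous-bifurcation measurements
#'
#' Flow measurements at one retinal venous bifurcation in each of six
#' healthy subjects, as produced by the instrument's automatic analysis:
#' daughter-vessel flows, parent-vessel flow (uL/min), and the relative
#' conservation error as printed by the analysis software. Note that the
#' printed `deltaFRelPrintedPct` column follows the opposite sign convention
#' from `deltaF = fPV - (fDV1 + fDV2)` as computed by
#' [bifurcationConservation()]; both are retained.
#'
#' @return A data.frame with columns `subject`, `fDV1`, `fDV2`, `fPV`,
#'   `deltaFRelPrintedPct`.
#' @examples
#' tab <- retinalBifurcationTable()
#' conservationSummary(tab$deltaFRelPrintedPct)
#' @export
retinalBifurcationTable <- function() {
  data.frame(
    subject = LETTERS[1:6],
    fDV1 = c(1.4, 0.9, 8.6, 4.0, 10.4, 8.3),
    fDV2 = c(3.4, 1.0, 6.8, 3.0, 1.7, 3.5),
    fPV = c(4.6, 2.1, 11.3, 5.9, 12.8, 13.2),
    deltaFRelPrintedPct = c(4.8, -8.3, 36.1, 19.0, -6.3, -10.7),
    stringsAsFactors = FALSE
  )
}
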