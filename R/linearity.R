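#' In-silico capillary linearity experiment
#'
#' Emulates the bench validation of the velocimeter against a syringe pump:
#' for each imposed flow level, the corresponding maximum velocity in a glass
#' capillary of known diameter is derived, a centre-weighted capillary
#' spectrum pair is simulated, the cutoff of each channel is detected, the
#' velocity is recovered from the cutoff difference and converted back to a
#' flow, and finally the measured flows are regressed on the imposed flows by
#' ordinary least squares. The default `"cross_section"` convention
#' (`F = pi r^2 vmax`, no 1/2 factor) matches the tracer behaviour of the
#' bench experiment; see [computeFlow()].
#'
#' Each pump setting is measured with one full acquisition of
#' `framesPerLevel` independent spectrum pairs, exactly as the instrument
#' records 40 spectrum pairs per 4 s measurement; the per-frame cutoff
#' differences are averaged. This averaging is what controls the speckle
#' fluctuation of single 30 ms spectra (per-frame cutoff scatter is on the
#' order of several bins regardless of detector noise, because one
#' unaveraged periodogram of a random-phase tone sum has exponentially
#' distributed bins).
#'
#' Levels where no frame yields a detectable cutoff pair are dropped (and
#' counted); fewer than 3 surviving levels abort the experiment.
#'
#' @param flowLevels Imposed flows in uL/min (>= 3 levels spanning at least a
#'   5-fold range).
#' @param capillaryDiameterUm Capillary inner diameter, um (default 200).
#' @param snr Signal-to-noise power ratio of the simulated records.
#' @param seed Integer seed; level sub-seeds are derived deterministically.
#' @param config An [OpticalConfig-class].
#' @param convention Flow convention used both to impose and to recover the
#'   flows.
#' @param fBase Lower channel cutoff placement, Hz.
#' @param beamWidthRatio Beam width over capillary radius.
#' @param framesPerLevel Number of spectrum pairs acquired and averaged per
#'   flow level (default: one full acquisition,
#'   `framesPerAcquisition(config)`).
#' @return A [LinearityReport-class].
#' @examples
#' \donttest{
#' rep <- runLinearityExperiment(seq(1.75, 25.9, length.out = 10), seed = 7)
#' rep
#' }
#' @export
runLinearityExperiment <- function(flowLevels, capillaryDiameterUm = 200,
                                   snr = 20, seed = 1L,
                                   config = OpticalConfig(),
                                   convention = c("cross_section",
                                                  "poiseuille"),
                                   fBase = 1000, beamWidthRatio = 0.5,
                                   framesPerLevel = framesPerAcquisition(config)) {
  convention <- match.arg(convention)
  framesPerLevel <- as.integer(framesPerLevel)
  stopifnot(framesPerLevel >= 1L)
  flowLevels <- sort(as.numeric(flowLevels))
  if (length(flowLevels) < 3L)
    stop("experiment failed: need at least 3 flow levels")
  if (max(flowLevels) < 5 * min(flowLevels))
    stop("experiment failed: flow levels must span at least a 5-fold range")

  measured <- rep(NA_real_, length(flowLevels))
  for (i in seq_along(flowLevels)) {
    vTrue <- invertFlowToVmax(flowLevels[i], capillaryDiameterUm, convention)
    dfFrames <- rep(NA_real_, framesPerLevel)
    for (f in seq_len(framesPerLevel)) {
      sc <- SpectrumScenario(vmaxTrue = vTrue, fBase = fBase, snr = snr,
                             intensityProfile = "center_weighted",
                             beamWidthRatio = beamWidthRatio,
                             seed = .deriveSeed(seed, 1000L * i + f))
      pair <- simulateCapillarySpectrum(sc, config, frameIndex = f - 1L)
      ca <- detectCutoff(pair$A)
      cb <- detectCutoff(pair$B)
      if (qualityFlag(ca) != "ok" || qualityFlag(cb) != "ok") next
      dfFrames[f] <- abs(cutoffHz(ca) - cutoffHz(cb))
    }
    if (!any(is.finite(dfFrames))) next
    df <- mean(dfFrames[is.finite(dfFrames)])
    vMeas <- 1e3 * vmax(computeVmax(df, config))
    measured[i] <- computeFlow(capillaryDiameterUm, vMeas, convention)
  }
  ok <- is.finite(measured)
  if (sum(ok) < 3L)
    stop("experiment failed: fewer than 3 levels yielded a cutoff")
  fit <- stats::lm(measured[ok] ~ flowLevels[ok])
  new("LinearityReport",
      imposedFlows = flowLevels[ok],
      measuredFlows = measured[ok],
      slope = unname(stats::coef(fit)[2L]),
      rSquared = summary(fit)$r.squared,
      nDropped = sum(!ok))
}

setMethod("show", "LinearityReport", function(object) {
  cat(sprintf(
    "LinearityReport: %d levels (%.2f - %.2f uL/min), slope %.3f, r^2 %.4f",
    length(object@imposedFlows), min(object@imposedFlows),
    max(object@imposedFlows), object@slope, object@rSquared))
  if (object@nDropped > 0L)
    cat(sprintf(" [%d levels dropped: no cutoff]", object@nDropped))
  cat("\n")
})
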