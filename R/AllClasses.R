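#' @import methods
NULL

## Central S4 containers for the velocimetry / image-analysis pipeline.
## Units are SI internally (m, s, Hz, m^3/s); micrometers, mm/s and uL/min
## appear only at I/O boundaries and in the *Um / *MmS / *UlMin slot names
## that say so explicitly.

#' Optical and geometric configuration of the velocimeter
#'
#' Holds every instrument constant shared by the pipeline: laser wavelength,
#' refractive index of the plasma surrounding the red blood cells, separation
#' of the two detection apertures at the pupil, the axial eye length assumed
#' for the scattering-angle computation, the acquisition timing, and the
#' pixel-to-micrometer calibration constants of the fundus camera.
#'
#' @slot wavelength Laser wavelength in meters.
#' @slot refractiveIndex Refractive index of the scattering medium
#'   (dimensionless, >= 1).
#' @slot beamSeparationX Distance between the two detection apertures at the
#'   pupil, in meters.
#' @slot axialLengthAssumed Axial eye length assumed for the scattering angle,
#'   in millimeters; set identical for all subjects.
#' @slot samplingRate Detector sampling rate in Hz.
#' @slot dopplerWindow Duration of one Doppler acquisition window in seconds.
#' @slot framesPerAcquisition Number of paired image/spectrum frames per
#'   acquisition.
#' @slot calibA,calibB,calibC Pixel-to-micrometer calibration constants
#'   (dimensionless, millimeters, dimensionless); see [pixelsToUm()].
#' @seealso [OpticalConfig()], [scatteringAngle()], [pixelsToUm()]
#' @exportClass OpticalConfig
setClass("OpticalConfig",
  representation(
    wavelength = "numeric",
    refractiveIndex = "numeric",
    beamSeparationX = "numeric",
    axialLengthAssumed = "numeric",
    samplingRate = "numeric",
    dopplerWindow = "numeric",
    framesPerAcquisition = "integer",
    calibA = "numeric",
    calibB = "numeric",
    calibC = "numeric"
  )
)

setValidity("OpticalConfig", function(object) {
  msg <- character()
  chk1 <- function(x, nm) if (length(slot(object, x)) != 1L || !is.finite(slot(object, x)))
    sprintf("'%s' must be a single finite number", nm) else NULL
  for (s in c("wavelength", "refractiveIndex", "beamSeparationX",
              "axialLengthAssumed", "samplingRate", "dopplerWindow",
              "calibA", "calibB", "calibC")) {
    m <- chk1(s, s); if (!is.null(m)) msg <- c(msg, m)
  }
  if (length(msg)) return(msg)
  if (object@wavelength <= 0) msg <- c(msg, "wavelength must be > 0")
  if (object@refractiveIndex < 1) msg <- c(msg, "refractiveIndex must be >= 1")
  if (object@beamSeparationX <= 0) msg <- c(msg, "beamSeparationX must be > 0")
  if (object@samplingRate <= 0) msg <- c(msg, "samplingRate must be > 0")
  if (object@dopplerWindow <= 0) msg <- c(msg, "dopplerWindow must be > 0")
  if (object@axialLengthAssumed <= object@calibB)
    msg <- c(msg, "axialLengthAssumed must exceed calibB")
  if (object@framesPerAcquisition < 1L)
    msg <- c(msg, "framesPerAcquisition must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Two-channel detector time series
#'
#' One Doppler acquisition window of raw detector samples from the two
#' scattered-beam photodetectors.
#'
#' @slot channelA,channelB Numeric sample vectors of equal length (arbitrary
#'   intensity units).
#' @slot samplingRate Sampling rate in Hz.
#' @slot frameIndex Frame counter within an acquisition.
#' @exportClass DetectorRecord
setClass("DetectorRecord",
  representation(
    channelA = "numeric",
    channelB = "numeric",
    samplingRate = "numeric",
    frameIndex = "integer"
  )
)

setValidity("DetectorRecord", function(object) {
  msg <- character()
  if (length(object@channelA) != length(object@channelB))
    msg <- c(msg, "channelA and channelB must have the same length")
  if (length(object@channelA) < 2L)
    msg <- c(msg, "channels must contain at least 2 samples")
  if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' One-sided Doppler power spectrum
#'
#' Power spectral density of one detector channel over ascending, uniformly
#' spaced frequency bins (DC bin excluded; bin k corresponds to k * deltaF).
#'
#' @slot frequencies Ascending, uniformly spaced frequencies in Hz.
#' @slot power Non-negative spectral power per bin.
#' @slot channelLabel `"A"` or `"B"`.
#' @slot frameIndex Frame counter.
#' @exportClass PowerSpectrum
setClass("PowerSpectrum",
  representation(
    frequencies = "numeric",
    power = "numeric",
    channelLabel = "character",
    frameIndex = "integer"
  )
)

setValidity("PowerSpectrum", function(object) {
  msg <- character()
  n <- length(object@power)
  if (length(object@frequencies) != n)
    msg <- c(msg, "frequencies and power must have the same length")
  if (n < 8L) msg <- c(msg, "a spectrum needs at least 8 bins")
  if (any(!is.finite(object@power)) || any(object@power < 0))
    msg <- c(msg, "power must be finite and non-negative")
  if (n >= 2L) {
    df <- diff(object@frequencies)
    if (object@frequencies[1L] < 0) msg <- c(msg, "frequencies must be >= 0")
    if (any(df <= 0)) msg <- c(msg, "frequencies must be strictly ascending")
    else if (max(df) - min(df) > 1e-6 * mean(df))
      msg <- c(msg, "frequency bins must be uniformly spaced")
  }
  if (!object@channelLabel %in% c("A", "B"))
    msg <- c(msg, "channelLabel must be \"A\" or \"B\"")
  if (length(msg)) msg else TRUE
})

#' Cutoff-frequency estimate for one spectrum
#'
#' Result of the cumulative-spectrum two-line intersection procedure: the
#' estimated maximum Doppler frequency shift together with the fitted rise
#' and plateau lines (in bin-index / cumulative-fraction space) and a quality
#' flag.
#'
#' @slot cutoffHz Estimated cutoff frequency in Hz (`NA` unless `qualityFlag`
#'   is `"ok"`).
#' @slot kx Last bin of the rising-region fit.
#' @slot riseSlope,riseIntercept,plateauSlope,plateauIntercept Fitted line
#'   parameters in (bin, rc) space.
#' @slot qualityFlag `"ok"`, `"no_cutoff"` or `"out_of_band"`.
#' @exportClass CutoffResult
setClass("CutoffResult",
  representation(
    cutoffHz = "numeric",
    kx = "integer",
    riseSlope = "numeric",
    riseIntercept = "numeric",
    plateauSlope = "numeric",
    plateauIntercept = "numeric",
    qualityFlag = "character"
  )
)

setValidity("CutoffResult", function(object) {
  if (!object@qualityFlag %in% c("ok", "no_cutoff", "out_of_band"))
    return("qualityFlag must be ok, no_cutoff or out_of_band")
  if (object@qualityFlag == "ok" &&
      (!is.finite(object@cutoffHz) || object@cutoffHz <= 0))
    return("an ok result must carry a positive cutoffHz")
  TRUE
})

#' Absolute velocity estimate
#'
#' Maximum (centerline) red-blood-cell velocity obtained from the difference
#' of the two channel cutoff frequencies and the bidirectional geometry.
#'
#' @slot vmax Maximum velocity in m/s.
#' @slot deltaF Cutoff-frequency difference |fA - fB| in Hz.
#' @slot alpha Scattering angle between the two detection directions, radians.
#' @slot beta Angle between the velocity vector and the scattering plane,
#'   radians.
#' @slot frameIndex Frame counter.
#' @exportClass VelocityEstimate
setClass("VelocityEstimate",
  representation(
    vmax = "numeric",
    deltaF = "numeric",
    alpha = "numeric",
    beta = "numeric",
    frameIndex = "integer"
  )
)

#' Probing-beam spot detection
#'
#' @slot centroidRow,centroidCol Intensity-weighted centroid of the spot mask
#'   (sub-pixel, 1-based image coordinates).
#' @slot mask Logical matrix marking the largest 8-connected component of
#'   pixels above 80\% of the maximal image intensity.
#' @exportClass SpotDetection
setClass("SpotDetection",
  representation(
    centroidRow = "numeric",
    centroidCol = "numeric",
    mask = "matrix"
  )
)

#' Vessel centerline fit and per-profile edge distances
#'
#' @slot orientationDeg Vessel orientation in degrees, counterclockwise from
#'   the image row axis, in [0, 180).
#' @slot centerlineOffsetPx Signed perpendicular distance of the centerline
#'   from the spot centroid, in pixels.
#' @slot profilePositions Position of each profile along the centerline (px).
#' @slot edgeDistancesPx Per-profile vessel width in pixels (`NA` for
#'   unusable profiles).
#' @slot aberrantFlags Logical; widths outside mean +/- 3 sd.
#' @slot diameterPx Mean of the non-aberrant widths.
#' @exportClass VesselFit
setClass("VesselFit",
  representation(
    orientationDeg = "numeric",
    centerlineOffsetPx = "numeric",
    profilePositions = "numeric",
    edgeDistancesPx = "numeric",
    aberrantFlags = "logical",
    diameterPx = "numeric"
  )
)

#' Vessel diameter estimate for one frame
#'
#' @slot diameterPx Diameter in pixels (mean of non-aberrant profile widths).
#' @slot diameterUm Diameter in micrometers via the pixel calibration.
#' @slot axialLengthMm Axial eye length used for the conversion.
#' @slot nProfiles Number of usable profiles.
#' @slot nRejected Number of profiles rejected as aberrant.
#' @slot qcStatus `"ok"`, `"spot_not_found"`, `"vessel_not_found"` or
#'   `"diameter_not_measurable"`.
#' @slot fit The underlying [VesselFit-class] (may be empty on QC failure).
#' @exportClass DiameterEstimate
setClass("DiameterEstimate",
  representation(
    diameterPx = "numeric",
    diameterUm = "numeric",
    axialLengthMm = "numeric",
    nProfiles = "integer",
    nRejected = "integer",
    qcStatus = "character",
    fit = "ANY"
  )
)

setValidity("DiameterEstimate", function(object) {
  ok <- c("ok", "spot_not_found", "vessel_not_found", "diameter_not_measurable")
  if (!object@qcStatus %in% ok)
    return(sprintf("qcStatus must be one of %s", paste(ok, collapse = ", ")))
  TRUE
})

#' Aggregated flow estimate for one acquisition
#'
#' @slot meanFlowUlMin Mean flow over QC-passed frames, in uL/min.
#' @slot nFramesTotal,nFramesUsed Frame accounting.
#' @slot perFrame A data.frame of per-frame measurements (see
#'   [frameMeasurement()]).
#' @exportClass FlowEstimate
setClass("FlowEstimate",
  representation(
    meanFlowUlMin = "numeric",
    nFramesTotal = "integer",
    nFramesUsed = "integer",
    perFrame = "data.frame"
  )
)

setValidity("FlowEstimate", function(object) {
  if (object@nFramesUsed > object@nFramesTotal)
    return("nFramesUsed cannot exceed nFramesTotal")
  TRUE
})

#' Flow-conservation result at a venous bifurcation
#'
#' @slot fPV,fDV1,fDV2 Parent and daughter flows in uL/min.
#' @slot deltaF fPV - (fDV1 + fDV2), uL/min.
#' @slot deltaFRel 100 * deltaF / fPV, percent.
#' @exportClass BifurcationResult
setClass("BifurcationResult",
  representation(
    fPV = "numeric",
    fDV1 = "numeric",
    fDV2 = "numeric",
    deltaF = "numeric",
    deltaFRel = "numeric"
  )
)

#' Scenario for simulated Doppler spectra
#'
#' @slot vmaxTrue True maximum velocity in mm/s.
#' @slot fBase Lower channel cutoff placement in Hz.
#' @slot snr Signal-to-noise power ratio of the detector record.
#' @slot edgeSigmaBins Gaussian smoothing of the spectral step edge, in bins
#'   (used by the direct spectral-domain generator).
#' @slot intensityProfile `"uniform"` or `"center_weighted"`.
#' @slot beamWidthRatio Probing-beam 1/e^2-like width over capillary radius
#'   (center-weighted mode only).
#' @slot nTones Number of random-phase tones summed per channel.
#' @slot seed Integer seed; all randomness derives from it.
#' @exportClass SpectrumScenario
setClass("SpectrumScenario",
  representation(
    vmaxTrue = "numeric",
    fBase = "numeric",
    snr = "numeric",
    edgeSigmaBins = "numeric",
    intensityProfile = "character",
    beamWidthRatio = "numeric",
    nTones = "integer",
    seed = "integer"
  )
)

setValidity("SpectrumScenario", function(object) {
  msg <- character()
  if (object@vmaxTrue < 0) msg <- c(msg, "vmaxTrue must be >= 0")
  if (object@snr <= 0) msg <- c(msg, "snr must be > 0")
  if (object@fBase < 0) msg <- c(msg, "fBase must be >= 0")
  if (!object@intensityProfile %in% c("uniform", "center_weighted"))
    msg <- c(msg, "intensityProfile must be uniform or center_weighted")
  if (object@nTones < 1L) msg <- c(msg, "nTones must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Scenario for simulated fundus vessel phantoms
#'
#' @slot diameterPx Nominal vessel diameter (FWHM of the dark band), px.
#' @slot orientationDeg Vessel orientation, degrees ccw from the row axis.
#' @slot spotOffsetPx Signed perpendicular offset of the probing-beam spot
#'   from the vessel centerline, px.
#' @slot illuminationCoeffs Six quadratic-surface coefficients
#'   (1, r, c, r^2, rc, c^2) on coordinates normalized to [-1, 1].
#' @slot noiseSigma Additive Gaussian noise sd, intensity counts.
#' @slot backgroundLevel,vesselDepth,spotAmplitude Intensity counts of the
#'   background, vessel absorption depth and spot peak.
#' @slot spotFwhmPx Full width at half maximum of the probing-beam spot, px.
#' @slot nrow,ncol Image size (canonical 1040 x 1392; >= 360 each).
#' @slot seed Integer seed.
#' @exportClass ImageScenario
setClass("ImageScenario",
  representation(
    diameterPx = "numeric",
    orientationDeg = "numeric",
    spotOffsetPx = "numeric",
    illuminationCoeffs = "numeric",
    noiseSigma = "numeric",
    backgroundLevel = "numeric",
    vesselDepth = "numeric",
    spotAmplitude = "numeric",
    spotFwhmPx = "numeric",
    nrow = "integer",
    ncol = "integer",
    seed = "integer"
  )
)

setValidity("ImageScenario", function(object) {
  msg <- character()
  if (object@diameterPx <= 0) msg <- c(msg, "diameterPx must be > 0")
  if (length(object@illuminationCoeffs) != 6L)
    msg <- c(msg, "illuminationCoeffs must have length 6")
  if (object@nrow < 360L || object@ncol < 360L)
    msg <- c(msg, "image must be at least 360 x 360")
  if (object@nrow > 1392L || object@ncol > 1392L)
    msg <- c(msg, "image must fit within the 1392 x 1040 sensor format")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Scenario for a simulated venous bifurcation
#'
#' @slot parentDiameterUm,parentVmaxMmS Parent vessel truth.
#' @slot daughterDiametersUm,daughterVmaxMmS Daughter vessel truths (length 2).
#' @slot conserved Whether the scenario satisfies exact flow conservation.
#' @slot seed Integer seed.
#' @exportClass BifurcationScenario
setClass("BifurcationScenario",
  representation(
    parentDiameterUm = "numeric",
    parentVmaxMmS = "numeric",
    daughterDiametersUm = "numeric",
    daughterVmaxMmS = "numeric",
    conserved = "logical",
    seed = "integer"
  )
)

setValidity("BifurcationScenario", function(object) {
  msg <- character()
  if (length(object@daughterDiametersUm) != 2L ||
      length(object@daughterVmaxMmS) != 2L)
    msg <- c(msg, "exactly two daughter vessels are required")
  if (any(c(object@parentDiameterUm, object@daughterDiametersUm) <= 0))
    msg <- c(msg, "diameters must be > 0")
  if (any(c(object@parentVmaxMmS, object@daughterVmaxMmS) < 0))
    msg <- c(msg, "velocities must be >= 0")
  if (length(msg) == 0L && isTRUE(object@conserved)) {
    fp <- computeFlow(object@parentDiameterUm, object@parentVmaxMmS)
    fd <- computeFlow(object@daughterDiametersUm[1L], object@daughterVmaxMmS[1L]) +
      computeFlow(object@daughterDiametersUm[2L], object@daughterVmaxMmS[2L])
    if (abs(fp - fd) > 1e-9 * fp)
      msg <- c(msg, "conserved scenario violates flow conservation")
  }
  if (length(msg)) msg else TRUE
})

#' In-silico linearity experiment report
#'
#' @slot imposedFlows,measuredFlows Flow levels in uL/min.
#' @slot slope OLS slope of measured on imposed flow.
#' @slot rSquared Pearson coefficient of determination.
#' @slot nDropped Number of levels dropped because no cutoff was found.
#' @exportClass LinearityReport
setClass("LinearityReport",
  representation(
    imposedFlows = "numeric",
    measuredFlows = "numeric",
    slope = "numeric",
    rSquared = "numeric",
    nDropped = "integer"
  )
)

setValidity("LinearityReport", function(object) {
  msg <- character()
  if (length(object@imposedFlows) != length(object@measuredFlows))
    msg <- c(msg, "imposed and measured flows must have the same length")
  if (length(object@imposedFlows) < 3L)
    msg <- c(msg, "a linearity report needs at least 3 levels")
  if (is.finite(object@rSquared) &&
      (object@rSquared < 0 || object@rSquared > 1))
    msg <- c(msg, "rSquared must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
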