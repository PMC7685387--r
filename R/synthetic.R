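## Physics-grounded synthetic inputs: every pipeline stage gets a ground-truth
## oracle. All randomness flows from one explicit integer seed through
## deterministic substream derivation; the global RNG state is saved and
## restored around every draw.

.deriveSeed <- function(seed, k) {
  # deterministic substream: distinct small-integer children of `seed`;
  # exact in double arithmetic (products stay far below 2^53)
  as.integer((as.double(seed %% 2147483647L) * 48271 + as.double(k)) %% 2147483647)
}

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Scenario constructors for the simulator
#'
#' `SpectrumScenario()` describes a two-channel laminar-flow Doppler
#' acquisition: ground-truth maximum velocity, placement of the lower channel
#' cutoff, signal-to-noise power ratio, spectral edge smoothing (for the
#' direct spectral-domain generator), the beam intensity profile across the
#' vessel, and the random seed.
#'
#' @param vmaxTrue True maximum velocity, mm/s.
#' @param fBase Lower channel cutoff placement, Hz.
#' @param snr Signal-to-noise power ratio (use `Inf` for noise-free).
#' @param edgeSigmaBins Gaussian smoothing of the step edge in bins
#'   ([simulateStepSpectrum()] only).
#' @param intensityProfile `"uniform"` (flat illumination: flat step
#'   spectrum) or `"center_weighted"` (Gaussian beam brighter at the vessel
#'   axis: spectral peak just before the cutoff).
#' @param beamWidthRatio Beam width over capillary radius for the
#'   center-weighted profile.
#' @param nTones Number of random-phase tones per channel.
#' @param seed Integer seed.
#' @return A [SpectrumScenario-class].
#' @export
SpectrumScenario <- function(vmaxTrue = 10, fBase = 1000, snr = 20,
                             edgeSigmaBins = 2,
                             intensityProfile = c("uniform", "center_weighted"),
                             beamWidthRatio = 0.5, nTones = 2000L,
                             seed = 1L) {
  new("SpectrumScenario", vmaxTrue = vmaxTrue, fBase = fBase, snr = snr,
      edgeSigmaBins = edgeSigmaBins,
      intensityProfile = match.arg(intensityProfile),
      beamWidthRatio = beamWidthRatio, nTones = as.integer(nTones),
      seed = as.integer(seed))
}

#' @rdname SpectrumScenario
#' @param diameterPx,orientationDeg,spotOffsetPx,illuminationCoeffs,noiseSigma,backgroundLevel,vesselDepth,spotAmplitude,spotFwhmPx,nrow,ncol
#'   See [ImageScenario-class]. The 31 px spot FWHM corresponds to the
#'   instrument's ~50 um probing beam at ~1.6 um/px sampling. The default
#'   `noiseSigma` of 400 counts puts the vessel contrast-to-noise ratio at
#'   20 for the default 8000-count vessel depth.
#' @export
ImageScenario <- function(diameterPx = 73, orientationDeg = 30,
                          spotOffsetPx = 20,
                          illuminationCoeffs = c(0, 0, 0, 0, 0, 0),
                          noiseSigma = 400, backgroundLevel = 20000,
                          vesselDepth = 8000, spotAmplitude = 30000,
                          spotFwhmPx = 31, nrow = 1040L, ncol = 1392L,
                          seed = 1L) {
  new("ImageScenario", diameterPx = diameterPx,
      orientationDeg = orientationDeg %% 180,
      spotOffsetPx = spotOffsetPx,
      illuminationCoeffs = illuminationCoeffs, noiseSigma = noiseSigma,
      backgroundLevel = backgroundLevel, vesselDepth = vesselDepth,
      spotAmplitude = spotAmplitude, spotFwhmPx = spotFwhmPx,
      nrow = as.integer(nrow), ncol = as.integer(ncol),
      seed = as.integer(seed))
}

#' @rdname SpectrumScenario
#' @param parentDiameterUm,parentVmaxMmS,daughterDiametersUm,daughterVmaxMmS,conserved
#'   See [BifurcationScenario-class].
#' @export
BifurcationScenario <- function(parentDiameterUm, parentVmaxMmS,
                                daughterDiametersUm, daughterVmaxMmS,
                                conserved = FALSE, seed = 1L) {
  new("BifurcationScenario", parentDiameterUm = parentDiameterUm,
      parentVmaxMmS = parentVmaxMmS,
      daughterDiametersUm = daughterDiametersUm,
      daughterVmaxMmS = daughterVmaxMmS, conserved = conserved,
      seed = as.integer(seed))
}

#' Conserved bifurcation scenario with daughter velocities solved from flows
#'
#' Splits the parent flow between the daughters (default split makes the two
#' daughter centerline velocities equal, i.e. flow proportional to the
#' squared diameter) and solves each daughter's velocity so that flow
#' conservation holds exactly under the Poiseuille relation.
#'
#' @param parentDiameterUm,parentVmaxMmS Parent truth (um, mm/s).
#' @param daughterDiametersUm Two daughter diameters, um.
#' @param split Fraction of parent flow sent to daughter 1; `NULL` (default)
#'   uses `d1^2 / (d1^2 + d2^2)`.
#' @param seed Integer seed.
#' @return A [BifurcationScenario-class] with `conserved = TRUE`.
#' @export
conservedBifurcationScenario <- function(parentDiameterUm = 104,
                                         parentVmaxMmS = 11,
                                         daughterDiametersUm = c(80, 70),
                                         split = NULL, seed = 1L) {
  fP <- computeFlow(parentDiameterUm, parentVmaxMmS)
  d <- daughterDiametersUm
  if (is.null(split)) split <- d[1L]^2 / (d[1L]^2 + d[2L]^2)
  if (split <= 0 || split >= 1)
    stop("invalid scenario: flow split must lie strictly between 0 and 1")
  fD <- c(split, 1 - split) * fP
  vD <- invertFlowToVmax(fD, d)
  if (any(vD < 0)) stop("invalid scenario: infeasible daughter split")
  BifurcationScenario(parentDiameterUm, parentVmaxMmS, d, vD,
                      conserved = TRUE, seed = seed)
}

.channelCutoffs <- function(scenario, config) {
  deltaF <- invertVmaxToDeltaF(scenario@vmaxTrue * 1e-3, config)
  c(A = scenario@fBase, B = scenario@fBase + deltaF)
}

.toneFrequencies <- function(m, fCut) stats::runif(m, 0, fCut)

.toneWeights <- function(freqs, fCut, profile, beamWidthRatio) {
  if (profile == "uniform") return(rep(1, length(freqs)))
  # Poiseuille: a scatterer at radius r has f = fCut * (1 - r^2/R^2), so
  # r^2/R^2 = 1 - f/fCut; a Gaussian beam of width sigma_b = ratio * R
  # weights its scattered power by exp(-r^2 / (2 sigma_b^2)). Frequencies
  # near the cutoff (vessel axis) are therefore enhanced.
  exp(-(1 - freqs / fCut) / (2 * beamWidthRatio^2))
}

.synthChannel <- function(fCut, scenario, config, seed) {
  fs <- config@samplingRate
  n <- round(config@dopplerWindow * fs)
  m <- scenario@nTones
  .withSeed(seed, {
    x <- numeric(n)
    if (scenario@vmaxTrue > 0 || fCut > 0) {
      freqs <- .toneFrequencies(m, fCut)
      phases <- stats::runif(m, 0, 2 * pi)
      w <- .toneWeights(freqs, fCut, scenario@intensityProfile,
                        scenario@beamWidthRatio)
      amp <- sqrt(w * m / sum(w))  # total tone power fixed at m/2
      x <- .sumTonesCpp(as.integer(n), fs, freqs, phases, amp)
    }
    if (is.finite(scenario@snr)) {
      noiseSd <- sqrt((m / 2) / scenario@snr)
      x <- x + stats::rnorm(n, sd = noiseSd)
    }
    x
  })
}

#' Simulate a two-channel detector record for a prescribed velocity
#'
#' Each channel is a sum of `nTones` unit tones with independent random
#' phases and frequencies drawn uniformly on `[0, fCut]` -- the frequency law
#' of Poiseuille flow with uniformly distributed scatterers, whose power
#' spectrum is a flat step up to the cutoff. The channel cutoffs are
#' `fBase` and `fBase + deltaF`, with `deltaF` derived from the scenario's
#' true velocity via [invertVmaxToDeltaF()]; white Gaussian noise is added at
#' the prescribed signal-to-noise power ratio. A zero true velocity yields
#' tone-free, noise-only channels. Records are 30 ms at 120 kHz under the
#' default configuration and bit-identical for identical seeds.
#'
#' @param scenario A [SpectrumScenario-class].
#' @param config An [OpticalConfig-class].
#' @param frameIndex Frame counter.
#' @return A [DetectorRecord-class].
#' @export
simulateDetectorRecord <- function(scenario, config = OpticalConfig(),
                                   frameIndex = 0L) {
  stopifnot(is(scenario, "SpectrumScenario"), is(config, "OpticalConfig"))
  validObject(scenario)
  fc <- .channelCutoffs(scenario, config)
  nyq <- config@samplingRate / 2
  if (max(fc) >= nyq)
    stop("invalid scenario: derived cutoff reaches the Nyquist frequency")
  if (scenario@vmaxTrue == 0) fc[] <- 0  # pure-noise channels
  a <- .synthChannel(fc[["A"]], scenario, config, .deriveSeed(scenario@seed, 1L))
  b <- .synthChannel(fc[["B"]], scenario, config, .deriveSeed(scenario@seed, 2L))
  DetectorRecord(a, b, config@samplingRate, frameIndex)
}

#' Simulate a capillary spectrum pair with centre-weighted illumination
#'
#' As [simulateDetectorRecord()] but with tone powers weighted by a Gaussian
#' beam profile across the capillary, so that near-cutoff frequencies
#' (scatterers near the axis, where the beam is brightest) are enhanced and
#' the spectrum shows a peak just before the cutoff. Tone amplitudes are
#' renormalized so the total spectral power is independent of the true
#' velocity. Returns the computed power spectra directly.
#'
#' @param scenario A [SpectrumScenario-class]; its `intensityProfile` is
#'   forced to `"center_weighted"`.
#' @param config An [OpticalConfig-class].
#' @param frameIndex Frame counter.
#' @return A list with [PowerSpectrum-class] elements `A` and `B`.
#' @export
simulateCapillarySpectrum <- function(scenario, config = OpticalConfig(),
                                      frameIndex = 0L) {
  stopifnot(is(scenario, "SpectrumScenario"))
  scenario@intensityProfile <- "center_weighted"
  rec <- simulateDetectorRecord(scenario, config, frameIndex)
  computePowerSpectrum(rec)
}

#' Directly synthesize a step-shaped power spectrum
#'
#' Spectral-domain generator for estimator studies: the mean spectrum is a
#' unit step up to the cutoff, optionally smoothed at the edge with a
#' Gaussian of `edgeSigmaBins` bins, plus a flat noise floor set by the
#' signal-to-noise power ratio. Two bin-noise models are available:
#' `"speckle"` draws each bin from the exponential distribution (periodogram
#' statistics of a single unaveraged window of a Gaussian signal -- the
#' fluctuation regime of one raw 30 ms spectrum), while `"gaussian"` adds
#' independent Gaussian noise of standard deviation `step / sqrt(snr)` to the
#' mean shape (the regime of spectra whose speckle has been suppressed, e.g.
#' by transit-time smoothing or averaging).
#'
#' @param cutoffHz True cutoff frequency.
#' @param nBins Number of frequency bins.
#' @param deltaFHz Bin width in Hz.
#' @param snr Signal-to-noise power ratio (`Inf` for the noise-free mean
#'   shape, returned without sampling).
#' @param edgeSigmaBins Gaussian edge smoothing in bins (0 = sharp step).
#' @param noiseModel `"speckle"` or `"gaussian"` (see Details).
#' @param seed Integer seed.
#' @param channelLabel,frameIndex Spectrum labelling.
#' @return A [PowerSpectrum-class].
#' @export
simulateStepSpectrum <- function(cutoffHz, nBins = 1800L, deltaFHz = 100 / 3,
                                 snr = 20, edgeSigmaBins = 0,
                                 noiseModel = c("speckle", "gaussian"),
                                 seed = 1L, channelLabel = "A",
                                 frameIndex = 0L) {
  noiseModel <- match.arg(noiseModel)
  stopifnot(cutoffHz > 0, cutoffHz < nBins * deltaFHz)
  bins <- seq_len(nBins)
  kCut <- cutoffHz / deltaFHz
  # snap to the nearest bin when the division is an integer up to
  # floating-point rounding (e.g. cutoffHz = 30 * (100/3), deltaFHz = 100/3),
  # so the cutoff bin itself is not lost to representation error
  if (abs(kCut - round(kCut)) < 1e-9 * max(1, abs(kCut))) kCut <- round(kCut)
  shape <- if (edgeSigmaBins > 0)
    stats::pnorm((kCut - bins) / edgeSigmaBins) else as.numeric(bins <= kCut)
  if (is.finite(snr)) {
    if (noiseModel == "speckle") {
      noiseLevel <- sum(shape) / (snr * nBins)
      meanPower <- shape + noiseLevel
      p <- .withSeed(seed, stats::rexp(nBins, rate = 1) * meanPower)
    } else {
      p <- shape + .withSeed(seed, stats::rnorm(nBins, sd = 1 / sqrt(snr)))
      p <- pmax(p, 0)
    }
  } else {
    p <- shape
  }
  PowerSpectrum(bins * deltaFHz, p, channelLabel, frameIndex)
}

#' Simulate a 16-bit fundus vessel phantom
#'
#' The frame is a quadratic illumination surface on a constant background,
#' minus a dark vessel band (flat-bottomed cross-section with
#' Gaussian-smoothed walls whose full width at half maximum equals the
#' nominal diameter) at the given orientation through the image center, plus
#' a bright Gaussian probing-beam spot displaced `spotOffsetPx` from the
#' centerline, plus white Gaussian noise; values are rounded and clipped to
#' the 16-bit range.
#'
#' @param scenario An [ImageScenario-class].
#' @return Integer matrix (`nrow` x `ncol`) of 16-bit intensities.
#' @export
simulateFundusImage <- function(scenario) {
  stopifnot(is(scenario, "ImageScenario"))
  validObject(scenario)
  nr <- scenario@nrow; nc <- scenario@ncol
  uv <- .unitVectors(scenario@orientationDeg)
  # spot at the image center; centerline offset so that the spot sits
  # spotOffsetPx from it on the perpendicular axis
  sr <- (nr + 1) / 2; sc <- (nc + 1) / 2
  dr <- row(matrix(0, nr, nc)) - sr
  dc <- col(matrix(0, nr, nc)) - sc
  p <- dr * uv$n[1L] + dc * uv$n[2L] - scenario@spotOffsetPx
  if (max(abs(c(scenario@spotOffsetPx, 0)) + scenario@diameterPx / 2) >
      min(nr, nc) / 2)
    stop("invalid scenario: vessel band does not fit the frame")
  rn <- 2 * (row(matrix(0, nr, nc)) - 1) / (nr - 1) - 1
  cn <- 2 * (col(matrix(0, nr, nc)) - 1) / (nc - 1) - 1
  a <- scenario@illuminationCoeffs
  illum <- a[1L] + a[2L] * rn + a[3L] * cn + a[4L] * rn^2 +
    a[5L] * rn * cn + a[6L] * cn^2
  spotSigma <- scenario@spotFwhmPx / (2 * sqrt(2 * log(2)))
  spot <- scenario@spotAmplitude * exp(-(dr^2 + dc^2) / (2 * spotSigma^2))
  vessel <- scenario@vesselDepth * .vesselCrossSection(p, scenario@diameterPx)
  img <- scenario@backgroundLevel + illum + spot - vessel
  if (scenario@noiseSigma > 0) {
    img <- img + .withSeed(.deriveSeed(scenario@seed, 3L),
                           matrix(stats::rnorm(nr * nc, sd = scenario@noiseSigma),
                                  nr, nc))
  }
  matrix(as.integer(pmin(pmax(round(img), 0), 65535)), nr, nc)
}

#' Simulate a full bifurcation experiment
#'
#' For the parent and both daughter vessels, generates
#' `framesPerAcquisition(config)` paired frames: a fundus phantom at the
#' vessel's true diameter (converted to pixels via the inverse of
#' [pixelsToUm()] at the configured axial length) and a detector record at
#' the vessel's true velocity. Vessel orientations are drawn from the
#' 15-degree template grid and per-frame seeds are derived deterministically
#' from the scenario seed.
#'
#' @param scenario A [BifurcationScenario-class] (see
#'   [conservedBifurcationScenario()]).
#' @param config An [OpticalConfig-class].
#' @param imageNrow,imageNcol Phantom frame size (canonical 1040 x 1392;
#'   smaller frames >= 360 px speed up simulation studies).
#' @param snr Detector-record signal-to-noise power ratio.
#' @param imageNoiseSigma Phantom noise sd, counts.
#' @return A named list (`parent`, `daughter1`, `daughter2`); each element
#'   has `frames` (a list of `list(image=, record=)` pairs) and `truth`
#'   (`diameterUm`, `vmaxMmS`, `flowUlMin`).
#' @export
simulateBifurcation <- function(scenario, config = OpticalConfig(),
                                imageNrow = 1040L, imageNcol = 1392L,
                                snr = 20, imageNoiseSigma = 400) {
  stopifnot(is(scenario, "BifurcationScenario"), is(config, "OpticalConfig"))
  validObject(scenario)
  vessels <- list(
    parent = c(scenario@parentDiameterUm, scenario@parentVmaxMmS),
    daughter1 = c(scenario@daughterDiametersUm[1L], scenario@daughterVmaxMmS[1L]),
    daughter2 = c(scenario@daughterDiametersUm[2L], scenario@daughterVmaxMmS[2L]))
  umPerPx <- pixelsToUm(1, config@axialLengthAssumed, config)
  nFrames <- config@framesPerAcquisition
  out <- vector("list", length(vessels))
  names(out) <- names(vessels)
  for (i in seq_along(vessels)) {
    dUm <- vessels[[i]][1L]; vMmS <- vessels[[i]][2L]
    dPx <- dUm / umPerPx
    orient <- 15 * (.deriveSeed(scenario@seed, 100L + i) %% 12L)
    frames <- vector("list", nFrames)
    for (f in seq_len(nFrames)) {
      sSeed <- .deriveSeed(scenario@seed, 1000L * i + f)
      img <- simulateFundusImage(ImageScenario(
        diameterPx = dPx, orientationDeg = orient, spotOffsetPx = 15,
        noiseSigma = imageNoiseSigma, nrow = imageNrow, ncol = imageNcol,
        seed = sSeed))
      rec <- simulateDetectorRecord(
        SpectrumScenario(vmaxTrue = vMmS, snr = snr,
                         seed = .deriveSeed(sSeed, 7L)),
        config, frameIndex = f - 1L)
      frames[[f]] <- list(image = img, record = rec)
    }
    out[[i]] <- list(
      frames = frames,
      truth = list(diameterUm = dUm, vmaxMmS = vMmS,
                   flowUlMin = computeFlow(dUm, vMmS)))
  }
  out
}
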