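# Shared helpers for the aoldv test suite.

# Acquisition-averaged step spectrum: mean of K independent single-window
# speckle periodogram draws around the same mean shape. The instrument
# records framesPerAcquisition spectrum pairs per measurement; averaging is
# what tames the exponential per-bin statistics of a single 30 ms window.
avgStepSpectrum <- function(cutoffHz, K = 40L, seedBase = 1L, nBins = 1800L,
                            deltaFHz = 100 / 3, snr = 20, edgeSigmaBins = 2) {
  acc <- NULL
  for (f in seq_len(K)) {
    sp <- simulateStepSpectrum(cutoffHz, nBins = nBins, deltaFHz = deltaFHz,
                               snr = snr, edgeSigmaBins = edgeSigmaBins,
                               noiseModel = "speckle",
                               seed = seedBase * 1000L + f)
    acc <- if (is.null(acc)) spectralPower(sp) else acc + spectralPower(sp)
  }
  PowerSpectrum(seq_len(nBins) * deltaFHz, acc / K)
}

# Acquisition-averaged spectrum of simulated detector records (channel "A"
# or "B"), averaging K single-frame periodograms.
avgRecordSpectrum <- function(scenarioArgs, channel = "B", K = 20L,
                              seedBase = 100L, config = OpticalConfig()) {
  acc <- NULL
  freqs <- NULL
  for (f in seq_len(K)) {
    sc <- do.call(SpectrumScenario, c(scenarioArgs, list(seed = seedBase + f)))
    sp <- computePowerSpectrum(simulateDetectorRecord(sc, config))[[channel]]
    freqs <- frequencies(sp)
    acc <- if (is.null(acc)) spectralPower(sp) else acc + spectralPower(sp)
  }
  PowerSpectrum(freqs, acc / K)
}

# Exhaustive two-segment change-point oracle: the split k minimizing the
# total squared error of a piecewise-constant fit with one change point.
bruteForceChangePoint <- function(power) {
  n <- length(power)
  sse <- function(x) if (length(x) == 0L) 0 else sum((x - mean(x))^2)
  tot <- vapply(seq_len(n - 1L),
                function(k) sse(power[1:k]) + sse(power[(k + 1L):n]),
                numeric(1))
  which.min(tot)
}

# Standard 440x440 phantom used across diameter tests (16-bit counts).
testPhantom <- function(diameterPx = 73, orientationDeg = 30, seed = 1L,
                        noiseSigma = 400,
                        illuminationCoeffs = c(0, 0, 0, 0, 0, 0), ...) {
  simulateFundusImage(ImageScenario(
    diameterPx = diameterPx, orientationDeg = orientationDeg,
    noiseSigma = noiseSigma, illuminationCoeffs = illuminationCoeffs,
    nrow = 440L, ncol = 440L, seed = seed, ...))
}
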