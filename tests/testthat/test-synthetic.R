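test_that("seed derivation is deterministic and separates substreams", {
  s1 <- aoldv:::.deriveSeed(42L, 1L)
  expect_identical(s1, aoldv:::.deriveSeed(42L, 1L))
  expect_true(is.integer(s1))
  ks <- vapply(1:100, function(k) aoldv:::.deriveSeed(42L, k), integer(1))
  expect_identical(anyDuplicated(ks), 0L)
  expect_false(aoldv:::.deriveSeed(42L, 1L) == aoldv:::.deriveSeed(43L, 1L))
})

test_that("simulators are bit-reproducible and leave the global RNG alone", {
  sc <- SpectrumScenario(seed = 9L)
  r1 <- simulateDetectorRecord(sc)
  r2 <- simulateDetectorRecord(sc)
  expect_identical(r1@channelA, r2@channelA)
  expect_identical(r1@channelB, r2@channelB)
  r3 <- simulateDetectorRecord(SpectrumScenario(seed = 10L))
  expect_false(identical(r1@channelA, r3@channelA))

  img1 <- simulateFundusImage(ImageScenario(nrow = 440L, ncol = 440L, seed = 5L))
  img2 <- simulateFundusImage(ImageScenario(nrow = 440L, ncol = 440L, seed = 5L))
  expect_identical(img1, img2)

  set.seed(123); x1 <- stats::rnorm(1)
  set.seed(123); invisible(simulateDetectorRecord(sc)); x2 <- stats::rnorm(1)
  expect_identical(x1, x2)
})

test_that("scenario validity rejects non-physical parameters", {
  expect_error(SpectrumScenario(vmaxTrue = -1))
  expect_error(SpectrumScenario(snr = -1))
  expect_error(SpectrumScenario(nTones = 0L))
  expect_error(ImageScenario(diameterPx = -1))
  expect_error(ImageScenario(noiseSigma = -1))
  expect_error(BifurcationScenario(100, 10, c(80, 70, 60), c(5, 5)))
})

test_that("tone frequencies are uniform on [0, cutoff]", {
  set.seed(1)
  f <- aoldv:::.toneFrequencies(20000L, 5000)
  expect_true(all(f >= 0 & f <= 5000))
  counts <- table(cut(f, breaks = seq(0, 5000, length.out = 11)))
  p <- stats::chisq.test(as.numeric(counts))$p.value
  expect_gt(p, 0.01)
})

test_that("zero true velocity yields noise-only channels with no cutoff", {
  sc <- SpectrumScenario(vmaxTrue = 0, seed = 2L)
  sp <- computePowerSpectrum(simulateDetectorRecord(sc))
  expect_identical(qualityFlag(detectCutoff(sp$A)), "no_cutoff")
  expect_identical(qualityFlag(detectCutoff(sp$B)), "no_cutoff")
})

test_that("end-to-end: averaged uniform-profile spectra recover vmax within 10%", {
  args <- list(vmaxTrue = 10, fBase = 1000, snr = 20)
  spA <- avgRecordSpectrum(args, channel = "A", K = 20L, seedBase = 300L)
  spB <- avgRecordSpectrum(args, channel = "B", K = 20L, seedBase = 300L)
  df <- deltaCutoff(detectCutoff(spA), detectCutoff(spB))
  v <- 1e3 * vmax(computeVmax(df, OpticalConfig()))
  expect_lt(abs(v - 10) / 10, 0.10)
})

test_that("centre-weighted capillary spectra peak just below the cutoff", {
  cfg <- OpticalConfig()
  fCutB <- 1000 + invertVmaxToDeltaF(10e-3, cfg)
  acc <- NULL
  for (f in 1:20) {
    sc <- SpectrumScenario(vmaxTrue = 10, fBase = 1000, snr = 20,
                           seed = 400L + f)
    sp <- simulateCapillarySpectrum(sc, cfg)$B
    acc <- if (is.null(acc)) spectralPower(sp) else acc + spectralPower(sp)
    freqs <- frequencies(sp)
  }
  fPeak <- freqs[which.max(acc)]
  expect_gt(fPeak, 0.6 * fCutB)
  expect_lt(fPeak, 1.1 * fCutB)
})

test_that("total capillary spectral power is independent of vmax (within 2% on 300-frame means)", {
  meanTotal <- vapply(c(2, 6, 12), function(v) {
    tot <- vapply(1:300, function(f) {
      sc <- SpectrumScenario(vmaxTrue = v, snr = 20, seed = 500L + f)
      sum(spectralPower(simulateCapillarySpectrum(sc)$B))
    }, numeric(1))
    mean(tot)
  }, numeric(1))
  expect_lt((max(meanTotal) - min(meanTotal)) / mean(meanTotal), 0.02)
})

test_that("the centre-weighted profile converges to the uniform one", {
  base <- list(vmaxTrue = 10, seed = 21L)
  uni <- simulateDetectorRecord(do.call(SpectrumScenario, c(
    base, list(intensityProfile = "uniform"))))
  wide <- simulateDetectorRecord(do.call(SpectrumScenario, c(
    base, list(intensityProfile = "center_weighted", beamWidthRatio = 1e9))))
  expect_identical(uni@channelA, wide@channelA)
  expect_identical(uni@channelB, wide@channelB)
})

test_that("fundus phantoms have the documented geometry and range", {
  img <- simulateFundusImage(ImageScenario(nrow = 440L, ncol = 440L, seed = 1L))
  expect_identical(dim(img), c(440L, 440L))
  expect_true(is.integer(img))
  expect_true(all(img >= 0L & img <= 65535L))
  # the probing-beam spot (amplitude over background) dominates the frame
  peak <- which(img == max(img), arr.ind = TRUE)[1, ]
  expect_lt(max(abs(peak - c(220.5, 220.5))), 3)
  expect_error(
    simulateFundusImage(ImageScenario(diameterPx = 900, nrow = 440L,
                                      ncol = 440L)),
    "does not fit")
})

test_that("conservedBifurcationScenario closes the flow balance exactly", {
  sc <- conservedBifurcationScenario()
  fP <- computeFlow(sc@parentDiameterUm, sc@parentVmaxMmS)
  fD <- computeFlow(sc@daughterDiametersUm, sc@daughterVmaxMmS)
  expect_equal(fP, sum(fD), tolerance = 1e-12)
  expect_true(sc@conserved)
  r <- bifurcationConservation(fP, fD[1], fD[2])
  expect_equal(deltaFRel(r), 0, tolerance = 1e-10)

  expect_error(conservedBifurcationScenario(split = 1.2), "split")
})

test_that("simulateBifurcation produces paired frames with truth sidecars", {
  cfg <- OpticalConfig(framesPerAcquisition = 2L)
  sim <- simulateBifurcation(conservedBifurcationScenario(seed = 3L), cfg,
                             imageNrow = 440L, imageNcol = 440L)
  expect_named(sim, c("parent", "daughter1", "daughter2"))
  for (v in sim) {
    expect_length(v$frames, 2L)
    expect_true(is.matrix(v$frames[[1]]$image))
    expect_s4_class(v$frames[[1]]$record, "DetectorRecord")
    expect_equal(v$truth$flowUlMin,
                 computeFlow(v$truth$diameterUm, v$truth$vmaxMmS))
  }
  # conserved scenario: parent truth flow equals the daughters' sum
  expect_equal(sim$parent$truth$flowUlMin,
               sim$daughter1$truth$flowUlMin + sim$daughter2$truth$flowUlMin,
               tolerance = 1e-12)
})
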