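test_that("cumulativeRc matches hand-computed values and ends at 1", {
  sp <- PowerSpectrum(1:8 * 100, c(1, 1, 1, 1, 0, 0, 0, 0))
  expect_equal(cumulativeRc(sp), c(0.25, 0.5, 0.75, 1, 1, 1, 1, 1))
  sp2 <- PowerSpectrum(1:8 * 100, c(2, 1, 1, 0, 0, 0, 0, 4))
  rc <- cumulativeRc(sp2)
  expect_true(all(diff(rc) >= 0))
  expect_equal(rc[8], 1)
  expect_error(cumulativeRc(PowerSpectrum(1:8 * 100, rep(0, 8))), "zero")
})

test_that("ideal step: kx at the 10% drop bin and exact intersection", {
  s <- c(rep(1, 100), rep(0, 200))
  sp <- PowerSpectrum(seq_along(s) * 100 / 3, s)
  res <- detectCutoff(sp)
  expect_identical(qualityFlag(res), "ok")
  # rc = 0.90 exactly at bin 90: the largest bin >= 10% below the plateau
  expect_identical(res@kx, 90L)
  expect_equal(cutoffHz(res), 100 * 100 / 3, tolerance = 1e-9)
})

test_that("noise-free steps are recovered exactly across the band", {
  for (k in c(10L, 25L, 60L, 100L, 150L, 200L)) {
    sp <- simulateStepSpectrum(k * 100 / 3, nBins = 300L, snr = Inf,
                               edgeSigmaBins = 0)
    res <- detectCutoff(sp)
    expect_identical(qualityFlag(res), "ok")
    expect_equal(cutoffHz(res), k * 100 / 3, tolerance = 1e-6)
  }
})

test_that("the estimate is invariant to positive rescaling of the spectrum", {
  sp <- avgStepSpectrum(3000, K = 10L, seedBase = 7L, nBins = 300L)
  scaled <- PowerSpectrum(frequencies(sp), 1234.5 * spectralPower(sp))
  expect_equal(cutoffHz(detectCutoff(scaled)), cutoffHz(detectCutoff(sp)),
               tolerance = 1e-9)
})

test_that("flat and noise-only spectra are flagged no_cutoff", {
  flat <- PowerSpectrum(1:300 * 100 / 3, rep(1, 300))
  expect_identical(qualityFlag(detectCutoff(flat)), "no_cutoff")
  expect_true(is.na(cutoffHz(detectCutoff(flat))))

  set.seed(99)
  noisy <- PowerSpectrum(1:300 * 100 / 3, rexp(300))
  expect_identical(qualityFlag(detectCutoff(noisy)), "no_cutoff")
})

test_that("detected cutoff agrees with an exhaustive change-point oracle", {
  sp <- avgStepSpectrum(3000, K = 40L, seedBase = 11L, nBins = 300L)
  res <- detectCutoff(sp)
  expect_identical(qualityFlag(res), "ok")
  oracle <- bruteForceChangePoint(spectralPower(sp))
  expect_lt(abs(cutoffHz(res) / (100 / 3) - oracle), 1.5)
})

test_that("median estimate is monotone in the true cutoff", {
  med <- vapply(c(2000, 3000, 4000, 5000), function(fc) {
    est <- vapply(1:9, function(r) {
      cutoffHz(detectCutoff(avgStepSpectrum(fc, K = 40L,
                                            seedBase = 50L + r,
                                            nBins = 300L)))
    }, numeric(1))
    stats::median(est)
  }, numeric(1))
  expect_true(all(diff(med) > 0))
})

test_that("acquisition-averaged spectra recover the cutoff within 3 bins in >= 95% of replicates", {
  nHit <- 0L
  nRep <- 100L
  for (r in seq_len(nRep)) {
    sp <- avgStepSpectrum(3000, K = 40L, seedBase = 2000L + r, nBins = 300L,
                          snr = 20)
    res <- detectCutoff(sp)
    if (qualityFlag(res) == "ok" &&
        abs(cutoffHz(res) - 3000) <= 3 * 100 / 3) nHit <- nHit + 1L
  }
  expect_gte(nHit / nRep, 0.95)
})

test_that("deltaCutoff returns |fA - fB| and NA with a warning on failure", {
  s <- c(rep(1, 100), rep(0, 200))
  spA <- PowerSpectrum(seq_along(s) * 100 / 3, s)
  s2 <- c(rep(1, 190), rep(0, 110))
  spB <- PowerSpectrum(seq_along(s2) * 100 / 3, s2)
  a <- detectCutoff(spA); b <- detectCutoff(spB)
  expect_equal(deltaCutoff(a, a), 0)
  expect_equal(deltaCutoff(a, b), 3000, tolerance = 1e-6)
  expect_equal(deltaCutoff(a, b), deltaCutoff(b, a))

  flat <- detectCutoff(PowerSpectrum(1:300 * 100 / 3, rep(1, 300)))
  expect_warning(d <- deltaCutoff(a, flat), "not detected")
  expect_true(is.na(d))
})

test_that("CutoffResult show method reports Hz or the failure flag", {
  s <- c(rep(1, 100), rep(0, 200))
  ok <- detectCutoff(PowerSpectrum(seq_along(s) * 100 / 3, s))
  expect_output(show(ok), "3333")
  bad <- detectCutoff(PowerSpectrum(1:300 * 100 / 3, rep(1, 300)))
  expect_output(show(bad), "no_cutoff")
})
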