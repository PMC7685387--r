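test_that("computeFlow implements pi (d/2)^2 vmax / 2 in uL/min", {
  expect_equal(computeFlow(100, 10),
               pi * (50e-6)^2 * 10e-3 / 2 * 6e10)
  expect_equal(computeFlow(100, 10), 2.356, tolerance = 1e-3)
  # cross-section convention drops the Poiseuille 1/2
  expect_equal(computeFlow(100, 10, "cross_section"),
               2 * computeFlow(100, 10))
  # quadratic in diameter, linear in velocity
  expect_equal(computeFlow(200, 10), 4 * computeFlow(100, 10))
  expect_equal(computeFlow(100, 20), 2 * computeFlow(100, 10))
  expect_error(computeFlow(-1, 10), "diameter")
  expect_error(computeFlow(100, -1), "vmax")
})

test_that("invertFlowToVmax round-trips computeFlow in both conventions", {
  for (conv in c("poiseuille", "cross_section")) {
    f <- computeFlow(104, 11, conv)
    expect_equal(computeFlow(104, invertFlowToVmax(f, 104, conv), conv), f,
                 tolerance = 1e-12)
  }
})

test_that("frameMeasurement computes flow only for complete ok frames", {
  ok <- frameMeasurement(1L, 100, 10, "ok")
  expect_equal(ok$flowUlMin, computeFlow(100, 10))
  expect_identical(ok$qcStatus, "ok")

  imgFail <- frameMeasurement(2L, NA_real_, 10, "image_failed")
  expect_true(is.na(imgFail$flowUlMin))
  spFail <- frameMeasurement(3L, 100, NA_real_, "spectrum_failed")
  expect_true(is.na(spFail$flowUlMin))
  expect_error(frameMeasurement(4L, 100, 10, "nonsense"))
})

test_that("aggregateAcquisition averages QC-passed frames and counts exclusions", {
  frames <- rbind(frameMeasurement(1L, 100, 10, "ok"),
                  frameMeasurement(2L, 100, 12, "ok"),
                  frameMeasurement(3L, NA_real_, 10, "image_failed"),
                  frameMeasurement(4L, 100, NA_real_, "spectrum_failed"))
  est <- aggregateAcquisition(frames)
  expect_equal(meanFlowUlMin(est),
               mean(c(computeFlow(100, 10), computeFlow(100, 12))))
  expect_identical(est@nFramesTotal, 4L)
  expect_identical(est@nFramesUsed, 2L)
  expect_identical(perFrame(est), frames)
  expect_output(show(est), "2/4 frames")

  allBad <- rbind(frameMeasurement(1L, NA_real_, 10, "image_failed"))
  expect_error(aggregateAcquisition(allBad), "quality control")
})

test_that("bifurcationConservation computes deltaF = fPV - (fDV1 + fDV2)", {
  r <- bifurcationConservation(4.6, 1.4, 3.4)
  expect_equal(r@deltaF, 4.6 - 4.8, tolerance = 1e-12)
  expect_equal(deltaFRel(r), 100 * (4.6 - 4.8) / 4.6)

  exact <- bifurcationConservation(5, 2, 3)
  expect_equal(exact@deltaF, 0)
  expect_equal(deltaFRel(exact), 0)

  expect_error(bifurcationConservation(-1, 1, 1), "parent")
  expect_error(bifurcationConservation(5, 0, 1), "daughter")
  expect_output(show(r), "BifurcationResult")
})

test_that("conservation and flow summaries use sample statistics", {
  s <- conservationSummary(c(4.8, -8.3, 36.1, 19.0, -6.3, -10.7))
  expect_equal(s$mean, mean(c(4.8, -8.3, 36.1, 19.0, -6.3, -10.7)))
  expect_equal(s$sd, stats::sd(c(4.8, -8.3, 36.1, 19.0, -6.3, -10.7)))
  expect_equal(s$min, -10.7)
  expect_equal(s$max, 36.1)
  expect_error(conservationSummary(1), "at least 2")

  f <- flowTableSummary(c(4.6, 2.1, 11.3, 5.9, 12.8, 13.2))
  expect_equal(f$mean, mean(c(4.6, 2.1, 11.3, 5.9, 12.8, 13.2)))
  expect_equal(f$min, 2.1)
  expect_equal(f$max, 13.2)
  expect_error(flowTableSummary(NA), "finite")
})

test_that("the reference bifurcation table is internally consistent", {
  tab <- retinalBifurcationTable()
  expect_identical(dim(tab), c(6L, 5L))
  expect_identical(tab$subject, LETTERS[1:6])
  # all flows positive; per-row conservation residuals are computable
  expect_true(all(tab$fPV > 0 & tab$fDV1 > 0 & tab$fDV2 > 0))
  r <- bifurcationConservation(tab$fPV[2], tab$fDV1[2], tab$fDV2[2])
  expect_equal(deltaFRel(r), 100 * (2.1 - 1.9) / 2.1)
})
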