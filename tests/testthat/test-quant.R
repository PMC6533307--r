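test_that("calibration fitting recovers exact lines and flags degeneracy", {
  conc <- c(0.5, 5, 25, 50)
  cur <- fitCalibration(conc, 18817 * conc - 10155, "gallic acid", 280)
  expect_equal(cur@slope, 18817, tolerance = 1e-10)
  expect_equal(cur@intercept, -10155, tolerance = 1e-8)
  expect_equal(rSquared(cur), 1, tolerance = 1e-12)
  expect_error(fitCalibration(c(1, 2), c(5, 10)), "insufficient calibration")
  expect_error(fitCalibration(rep(5, 4), c(1, 2, 3, 4)),
               "insufficient calibration")
  expect_error(fitCalibration(conc, rep(7, 4)), "insufficient calibration")
})

test_that("noisy calibration slopes are accurate to a fraction of a percent", {
  conc <- c(0.5, 5, 25, 50)
  true_area <- 18817 * conc - 10155
  set.seed(77)
  slopes <- replicate(500, {
    area <- true_area + rnorm(4, 0, 0.01 * abs(true_area))
    fitCalibration(conc, area)@slope
  })
  expect_lt(abs(mean(slopes) / 18817 - 1), 0.005)
})

test_that("LOD and LOQ follow the signal-to-noise definitions", {
  cur <- calibrationCurve("gallic acid", 18817, -10155)
  ll <- lodLoqValues(lodLoq(87.8, cur))
  expect_equal(unname(ll["lod"]), 3 * 87.8 / 18817)
  expect_equal(unname(ll["lod"]), 0.014, tolerance = 0.001)
  expect_equal(unname(ll["loq"] / ll["lod"]), 10 / 3)
  expect_equal(unname(lodLoqValues(lodLoq(0, cur))), c(0, 0))
  neg <- calibrationCurve("x", -5, 0)
  expect_error(lodLoq(10, neg), "invalid curve")
})

test_that("curve inversion is exact and clamps blank-level areas", {
  cur <- calibrationCurve("apigenin", 29655, 6320.6, 320)
  expect_equal(concentrationFromCurve(29655 * 10 + 6320.6, cur), 10)
  expect_equal(concentrationFromCurve(cur@intercept, cur), 0)
  set.seed(3)
  conc <- runif(100, 0, 80)
  expect_equal(concentrationFromCurve(cur@slope * conc + cur@intercept, cur),
               conc, tolerance = 1e-9)
  expect_warning(lo <- concentrationFromCurve(0, cur), "clamped")
  expect_equal(lo, 0)
})

test_that("RRF and internal-standard quantification obey their identities", {
  expect_equal(relativeResponseFactor(1000, 500, 40, 20), 1)
  expect_equal(relativeResponseFactor(1000, 500, 25, 20), 1.6)
  # swapping the known and internal-standard roles inverts the RRF
  expect_equal(relativeResponseFactor(500, 1000, 20, 25),
               1 / relativeResponseFactor(1000, 500, 25, 20))
  expect_error(relativeResponseFactor(-1, 2, 3, 4), "invalid measurement")
  is20 <- internalStandard("ferulic acid", 20, 4e5)
  expect_equal(quantifyUnknown(4e5, is20, rrf = 1), 20)
  expect_equal(quantifyUnknown(4e5, is20, rrf = 1, recovery = 0.5),
               2 * quantifyUnknown(4e5, is20, rrf = 1, recovery = 1))
  expect_error(quantifyUnknown(4e5, is20, rrf = 1, recovery = 0),
               "invalid recovery")
  expect_error(quantifyUnknown(4e5, is20, rrf = 0), "rrf")
})

test_that("recovery and RSD follow their validation formulas", {
  expect_equal(recoveryRate(10, 40, 30), 100)
  expect_equal(recoveryRate(5, 5 + 30, 30), 100)
  expect_equal(recoveryRate(5, 5, 30), 0)
  expect_error(recoveryRate(1, 2, 0), "invalid spike")
  expect_equal(rsd(c(1, 2, 3)), 50)
  expect_equal(rsd(rep(4.2, 5)), 0)
  expect_equal(rsd(c(1, 2, 3) * 17), rsd(c(1, 2, 3)))
  expect_error(rsd(c(-1, 1)), "undefined RSD")
  expect_error(rsd(3), "2 values")
})

test_that("content scaling and the colorimetric TP conversion round-trip", {
  expect_equal(contentPerDw(30.67, 15, 0.5), 30.67 * 15 / 0.5 / 1000)
  expect_equal(contentPerDw(30.67, 15, 0.5), 0.92, tolerance = 0.01)
  expect_equal(contentPerDw(0, 15, 0.5), 0)
  expect_equal(contentPerDw(10, 15, 1), contentPerDw(10, 15, 0.5) / 2)
  gallic <- calibrationCurve("gallic acid abs", 0.004, 0.012)
  tp_true <- 1.27  # g GAE/100 g DW
  dil <- 20
  conc <- tp_true * 1e4 * 0.5 / (dil * 15)
  abs_meas <- 0.004 * conc + 0.012
  expect_equal(folinTp(abs_meas, gallic, dilution = dil), tp_true,
               tolerance = 1e-9)
  expect_equal(folinTp(0, calibrationCurve("g", 0.004, 0)), 0)
})

test_that("class aggregation reproduces the published content summary", {
  agg <- aggregateByClass(exampleContents())
  expect_equal(unname(agg$class_totals["flavonoid"]), 3.63)
  expect_equal(agg$phenolic_acid, 2.79)
  expect_equal(agg$total, 6.42)
  expect_equal(agg$top_compound, "luteolin")
  expect_equal(agg$top_content, 1.61)
})

test_that("aggregation is order-invariant, additive and empty-safe", {
  recs <- exampleContents()
  set.seed(12)
  agg1 <- aggregateByClass(recs)
  agg2 <- aggregateByClass(recs[sample(nrow(recs)), ])
  expect_equal(agg1, agg2)
  expect_equal(sum(agg1$class_totals[c("hydroxybenzoic_acid",
                                       "hydroxycinnamic_acid",
                                       "flavonoid")]),
               agg1$total)
  empty <- aggregateByClass(data.frame())
  expect_equal(empty$total, 0)
  expect_true(is.na(empty$top_compound))
})

test_that("content responds monotonically to area, recovery and RRF", {
  s <- syntheticQuantSetup()
  is_fa <- s$isSpecs[["ferulic acid"]]
  a <- seq(1e4, 1e6, length.out = 5)
  conc <- quantifyUnknown(a, is_fa, rrf = 1.2, recovery = 0.9)
  expect_true(all(diff(conc) > 0))
  expect_lt(quantifyUnknown(1e5, is_fa, rrf = 1.5),
            quantifyUnknown(1e5, is_fa, rrf = 1.2))
  expect_lt(quantifyUnknown(1e5, is_fa, rrf = 1.2, recovery = 1),
            quantifyUnknown(1e5, is_fa, rrf = 1.2, recovery = 0.8))
})
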