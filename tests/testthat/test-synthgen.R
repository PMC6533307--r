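test_that("all generators are reproducible under a fixed seed", {
  beta <- randomCoefficients(2)
  d <- buildCCCDesign(extractionFactors())
  r1 <- responses(genResponseSurface(beta, d, noiseSd = 0.1, seed = 42))
  r2 <- responses(genResponseSurface(beta, d, noiseSd = 0.1, seed = 42))
  expect_identical(r1, r2)
  lib <- compoundLibrary()
  t1 <- genSpectralTree(lib[[5]], mzJitter = 0.3, intensityNoise = 5,
                        seed = 42)
  t2 <- genSpectralTree(lib[[5]], mzJitter = 0.3, intensityNoise = 5,
                        seed = 42)
  expect_identical(fragments(t1), fragments(t2))
  s <- syntheticQuantSetup()
  concs <- data.frame(compound = s$map$compound,
                      concentration = seq_along(s$map$compound))
  p1 <- genPeakTable(concs, s$map, s$curves, s$isSpecs,
                     areaNoiseCv = 0.05, seed = 42)
  p2 <- genPeakTable(concs, s$map, s$curves, s$isSpecs,
                     areaNoiseCv = 0.05, seed = 42)
  expect_identical(p1, p2)
})

test_that("zero-noise surface responses are exact polynomial values", {
  beta <- randomCoefficients(3)
  d <- buildCCCDesign(extractionFactors())
  d <- genResponseSurface(beta, d, noiseSd = 0)
  m <- fitQuadratic(d)
  expect_equal(unname(coef(m)), beta, tolerance = 1e-8)
  expect_equal(rSquared(m), 1, tolerance = 1e-10)
})

test_that("generated trees satisfy reader invariants and jitter bounds", {
  lib <- compoundLibrary()
  for (entry in lib) {
    tr <- genSpectralTree(entry, mzJitter = 0.3, intensityNoise = 10,
                          seed = 7)
    expect_true(validObject(tr, test = TRUE))
    if (is.na(precursorMz(entry$tree))) next
    expect_lte(abs(precursorMz(tr) - precursorMz(entry$tree)), 0.3)
    expect_true(all(abs(fragments(tr)$mz - fragments(entry$tree)$mz) <= 0.3))
  }
})

test_that("zero-noise trees annotate back to their generating compound", {
  for (entry in compoundLibrary()) {
    tr <- genSpectralTree(entry, mzJitter = 0, intensityNoise = 0)
    expect_equal(tolower(compoundName(annotate(tr))), tolower(entry$name),
                 label = paste("peak", entry$peak_id))
  }
})

test_that("annotation survives mass-axis jitter inside the tolerance", {
  lib <- compoundLibrary()
  for (seed in 1:25) {
    for (entry in lib) {
      tr <- genSpectralTree(entry, mzJitter = 0.3, intensityNoise = 5,
                            seed = seed * 1000 + as.integer(entry$peak_id))
      expect_equal(tolower(compoundName(annotate(tr))),
                   tolower(entry$name),
                   label = paste("peak", entry$peak_id, "seed", seed))
    }
  }
})

test_that("zero-noise peak tables quantify back to the true concentrations", {
  s <- syntheticQuantSetup()
  set.seed(5)
  concs <- data.frame(compound = s$map$compound,
                      concentration = runif(nrow(s$map), 2, 60))
  peaks <- genPeakTable(concs, s$map, s$curves, s$isSpecs, areaNoiseCv = 0)
  recs <- quantifyBatch(peaks, s$map, s$curves, s$isSpecs)
  expect_equal(recs$concentration, concs$concentration, tolerance = 1e-9)
  # zero concentration: area collapses to the intercept floor
  z <- genPeakTable(data.frame(compound = "luteolin", concentration = 0),
                    s$map, s$curves, s$isSpecs)
  expect_equal(z$area, s$curves$luteolin@intercept)
})

test_that("1% area noise keeps median content error under 2%", {
  s <- syntheticQuantSetup()
  set.seed(9)
  concs <- data.frame(compound = s$map$compound,
                      concentration = runif(nrow(s$map), 5, 60))
  true_content <- contentPerDw(concs$concentration)
  rel_err <- replicate(200, {
    peaks <- genPeakTable(concs, s$map, s$curves, s$isSpecs,
                          areaNoiseCv = 0.01)
    recs <- quantifyBatch(peaks, s$map, s$curves, s$isSpecs)
    abs(recs$content / true_content - 1)
  })
  expect_lt(median(rel_err), 0.02)
})
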