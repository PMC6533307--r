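# Shared builders for the test suite; everything is generated in code.

extractionFactors <- function() {
  list(factorSpec("time", center = 30, step = 10, unit = "min"),
       factorSpec("ratio", center = 20, step = 10, unit = "mL/g"),
       factorSpec("temperature", center = 50, step = 10, unit = "degC"))
}

# Random full-quadratic coefficient vector for three coded factors.
randomCoefficients <- function(seed) {
  set.seed(seed)
  c(stats::runif(1, 0.5, 1.5),            # intercept
    stats::runif(3, -0.3, 0.3),           # linear
    stats::runif(3, -0.3, 0.1),           # quadratic
    stats::runif(3, -0.15, 0.15))         # interactions
}

fitModelFromCoefficients <- function(beta, noiseSd = 0, seed = NULL,
                                     nCenter = 6) {
  d <- buildCCCDesign(extractionFactors(), alpha = 1.68, nCenter = nCenter)
  d <- genResponseSurface(beta, d, noiseSd = noiseSd, seed = seed)
  fitQuadratic(d)
}

# Brute-force grid maximum of a fitted surface: the independent oracle
# for the optimizer.
gridMaximum <- function(model, lower = -1, upper = 1, by = 0.05) {
  g <- as.matrix(expand.grid(seq(lower, upper, by = by),
                             seq(lower, upper, by = by),
                             seq(lower, upper, by = by)))
  max(predict(model, g))
}

# Minimal synthetic quantification setup shared by quant/synthgen tests.
syntheticQuantSetup <- function() {
  curves <- list(
    luteolin = calibrationCurve("luteolin", 24041, 44178, 360),
    apigenin = calibrationCurve("apigenin", 29655, 6320.6, 320),
    acacetin = calibrationCurve("acacetin", 26463, 9248.4, 320))
  isSpecs <- list(
    "protocatechuic acid" = internalStandard("protocatechuic acid", 20, 4.2e5),
    "ferulic acid" = internalStandard("ferulic acid", 20, 6.8e5),
    "hesperidin" = internalStandard("hesperidin", 20, 3.1e5))
  map <- defaultQuantMap()
  set.seed(421)
  map$rrf[map$method == "rrf"] <- stats::runif(sum(map$method == "rrf"),
                                               0.4, 1.8)
  map$recovery[map$method == "rrf"] <- 1
  list(curves = curves, isSpecs = isSpecs, map = map)
}
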