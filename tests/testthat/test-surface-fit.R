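test_that("noise-free responses are recovered exactly by OLS", {
  for (seed in c(11, 12, 13)) {
    beta <- randomCoefficients(seed)
    m <- fitModelFromCoefficients(beta)
    expect_equal(unname(coef(m)), beta, tolerance = 1e-8)
    expect_equal(rSquared(m), 1, tolerance = 1e-8)
  }
})

test_that("coefficient estimates are unbiased under Gaussian noise", {
  beta <- randomCoefficients(7)
  nrep <- 200
  est <- matrix(NA_real_, nrep, length(beta))
  set.seed(99)
  seeds <- sample.int(1e6, nrep)
  for (r in seq_len(nrep))
    est[r, ] <- coef(fitModelFromCoefficients(beta, noiseSd = 0.05,
                                              seed = seeds[r]))
  bias <- colMeans(est) - beta
  se_mean <- apply(est, 2, stats::sd) / sqrt(nrep)
  expect_true(all(abs(bias) < 3 * se_mean))
})

test_that("fit preconditions are enforced", {
  d <- buildCCCDesign(extractionFactors())
  expect_error(fitQuadratic(d), "incomplete design")
  # duplicated-axis settings make the quadratic basis rank deficient
  f <- extractionFactors()
  cd <- codedValues(buildCCCDesign(f))
  cd[, 3] <- cd[, 2]
  d2 <- cccDesign(f, cd, designRoles(buildCCCDesign(f)), response = 1)
  responses(d2) <- rnorm(20)
  expect_error(fitQuadratic(d2), "singular design")
})

test_that("ANOVA decomposition is additive with correct pure-error df", {
  beta <- randomCoefficients(21)
  d <- buildCCCDesign(extractionFactors(), nCenter = 6)
  d <- genResponseSurface(beta, d, noiseSd = 0.05, seed = 5)
  m <- fitQuadratic(d)
  a <- anovaTable(m, d)
  ss <- function(src) a$ss[a$source == src]
  df <- function(src) a$df[a$source == src]
  expect_equal(ss("model") + ss("residual"), ss("total"))
  expect_equal(ss("lack_of_fit") + ss("pure_error"), ss("residual"))
  expect_equal(df("pure_error"), 5)
  expect_true(attr(a, "lack_of_fit_available"))
  # zero noise: residual SS collapses to zero
  d0 <- genResponseSurface(beta, d, noiseSd = 0)
  a0 <- anovaTable(fitQuadratic(d0), d0)
  expect_equal(a0$ss[a0$source == "residual"], 0, tolerance = 1e-12)
  # no center replicates: pure-error split flagged unavailable, no error
  d1 <- buildCCCDesign(extractionFactors(), nCenter = 1)
  d1 <- genResponseSurface(beta, d1, noiseSd = 0.05, seed = 6)
  a1 <- anovaTable(fitQuadratic(d1), d1)
  expect_false(attr(a1, "lack_of_fit_available"))
  expect_false("pure_error" %in% a1$source)
})

test_that("prediction evaluates the second-order polynomial", {
  f <- extractionFactors()
  m0 <- new("QuadraticSurfaceModel", coefficients = rep(0, 10), factors = f,
            rSquared = NA_real_, fStatistic = NA_real_, pValue = NA_real_,
            dfModel = 9L, dfResidual = 10L, sigma = NA_real_)
  expect_equal(predict(m0, c(0.3, -1, 2)), 0)
  m1 <- m0
  m1@coefficients[1] <- 4.2
  expect_equal(predict(m1, matrix(rnorm(9), 3)), rep(4.2, 3))
})

test_that("rescaling responses rescales the fit but not R^2", {
  beta <- randomCoefficients(31)
  d <- buildCCCDesign(extractionFactors())
  d <- genResponseSurface(beta, d, noiseSd = 0.05, seed = 8)
  m <- fitQuadratic(d)
  d2 <- d
  responses(d2) <- responses(d) * 3.7
  m2 <- fitQuadratic(d2)
  expect_equal(coef(m2), coef(m) * 3.7)
  expect_equal(rSquared(m2), rSquared(m))
  o <- optimizeSurface(m)
  o2 <- optimizeSurface(m2)
  expect_equal(o2@codedOpt, o@codedOpt, tolerance = 1e-6)
  expect_equal(o2@predictedResponse, o@predictedResponse * 3.7,
               tolerance = 1e-8)
})
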