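test_that("slope-to-steps mapping reproduces the published worked examples", {
  expect_identical(stepsFromSlope(4.8), 6L)   # ALS overall slope
  expect_identical(stepsFromSlope(4.6), 6L)   # Danish-register regression
  expect_identical(stepsFromSlope(5.0), 6L)
  expect_identical(stepsFromSlope(0.0), 1L)   # flat incidence: one step
  expect_identical(stepsFromSlope(4.49), 5L)  # half-up rounding boundary
  expect_identical(stepsFromSlope(4.5), 6L)
  expect_error(stepsFromSlope(-1), "no valid step count")
  expect_error(stepsFromSlope(-1.5), "no valid step count")
})

test_that("risk parameters follow u = exp(c), mu = u^(1/n)", {
  expect_equal(riskParameters(0, 5L), list(u = 1, mu = 1))
  expect_equal(riskParameters(log(8), 3L)$u, 8)
  expect_equal(riskParameters(log(8), 3L)$mu, 2)
  for (c_ in c(-20, -3, 0.7)) for (n in c(1L, 4L, 13L)) {
    rp <- riskParameters(c_, n)
    expect_equal(rp$mu^n, rp$u, tolerance = 1e-9)
  }
  expect_error(riskParameters(0, 0L), "nSteps")
})

test_that("age-80 truncation applies only when 4 points would remain", {
  d6 <- midpointDataset(c(62, 67, 72, 77, 82, 87), rep(10, 6))
  pts <- preparePoints(list(d6))
  expect_true(pts@truncated)
  expect_equal(10^pts@logAge, c(62, 67, 72, 77))

  d4 <- midpointDataset(c(62, 67, 82, 87), rep(10, 4))
  pts4 <- preparePoints(list(d4))
  expect_false(pts4@truncated)
  expect_equal(10^pts4@logAge, c(62, 67, 82, 87))

  # zero-incidence bins are dropped before the log transform
  dz <- midpointDataset(c(50, 55, 60, 65), c(0, 1, 2, 3))
  expect_equal(10^preparePoints(list(dz))@logAge, c(55, 60, 65))

  expect_error(preparePoints(list(midpointDataset(c(50, 55), c(0, 0)))),
               "fewer than 2 usable points")
})

test_that("points pool across studies of one stratum only", {
  a <- midpointDataset(c(50, 55), c(1, 2), study = "S1")
  b <- midpointDataset(c(52, 57), c(1.5, 2.5), study = "S2")
  pts <- preparePoints(list(a, b))
  expect_length(pts@logAge, 4L)
  expect_setequal(pts@sourceIds, c("S1", "S2"))
  other <- midpointDataset(c(50, 55), c(1, 2), code = "PD")
  expect_error(preparePoints(list(a, other)), "several strata")
})

test_that("an exact power law is recovered with r-squared 1", {
  d <- powerLawDataset(n = 6L, u = 1e-9)
  f <- fitMultistep(preparePoints(list(d)))
  expect_equal(slopeM(f), 5, tolerance = 1e-10)
  expect_equal(rSquared(f), 1, tolerance = 1e-10)
  expect_identical(nSteps(f), 6L)
  expect_equal(backgroundRisk(f), 1e-9, tolerance = 1e-6)
  expect_equal(geomMeanRisk(f)^6, backgroundRisk(f), tolerance = 1e-9)
  expect_true(passesLinearity(f))

  two <- midpointDataset(c(50, 70), c(2, 8))
  f2 <- fitMultistep(preparePoints(list(two)))
  expect_equal(rSquared(f2), 1)
  expect_equal(slopeM(f2), log10(4) / log10(70 / 50), tolerance = 1e-12)

  expect_error(fitMultistep(new("LogLogPoints", logAge = log10(c(50, 50)),
                                logIncidence = log10(c(2, 8)),
                                sourceIds = c("a", "b"), truncated = FALSE,
                                stratum = "AD")),
               "degenerate")
})

test_that("OLS agrees with brute-force normal equations to 1e-10", {
  set.seed(20240915)
  for (i in 1:100) {
    n <- sample(3:12, 1)
    x <- log10(sort(runif(n, 30, 90)))
    y <- 5 * x + rnorm(n, sd = 0.3)
    pts <- new("LogLogPoints", logAge = x, logIncidence = y,
               sourceIds = rep("S", n), truncated = FALSE, stratum = "AD")
    f <- fitMultistep(pts)
    oracle <- olsNormalEquations(x, y)
    expect_equal(slopeM(f), oracle$slope, tolerance = 1e-10)
    expect_equal(f@interceptC10, oracle$intercept, tolerance = 1e-10)
  }
})

test_that("scaling incidence changes u but not the slope or step count", {
  d <- powerLawDataset(n = 8L, u = 3e-12, ageMin = 50, ageMax = 80)
  f1 <- fitMultistep(preparePoints(list(d)))
  b <- bins(d); b$incidence <- b$incidence * 1000
  d2 <- IncidenceDataset(diseaseCode(d), sexStratum(d), studyId(d), b)
  f2 <- fitMultistep(preparePoints(list(d2)))
  expect_equal(slopeM(f2), slopeM(f1), tolerance = 1e-9)
  expect_identical(nSteps(f2), nSteps(f1))
  expect_equal(backgroundRisk(f2) / backgroundRisk(f1), 1000,
               tolerance = 1e-6)
})

test_that("noisy synthetic strata recover their true step count", {
  # study conditions: sigma 0.05, 7 five-year bins over ages 45-79
  recovered <- vapply(1:40, function(s) {
    spec <- diseaseSpec("ND", nTrue = 6L, backgroundRiskU = 1e-9,
                        ageMin = 45, ageMax = 80, binWidth = 5,
                        noiseSigma = 0.05)
    d <- generateDataset(spec, 1L, seed = s)
    nSteps(fitMultistep(preparePoints(list(d))))
  }, integer(1))
  expect_gte(mean(recovered == 6L), 0.9)
})

test_that("the nonmonotone control fails the linearity gate", {
  spec <- diseaseSpec("MS", nTrue = 1L, backgroundRiskU = 5,
                      ageMin = 15, ageMax = 80, noiseSigma = 0.05,
                      model = "nonmonotone_control")
  fails <- vapply(1:25, function(s) {
    f <- fitMultistep(preparePoints(list(generateDataset(spec, 1L, seed = s))))
    !passesLinearity(f)
  }, logical(1))
  expect_gte(mean(fails), 0.95)
})
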