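test_that("the onset interval spans the nonzero bins, truncated at 80", {
  d <- powerLawDataset(n = 6L, u = 1e-9, ageMin = 45, ageMax = 80)
  r <- incidenceAgeRange(list(d))
  expect_equal(r$ageMin, 45)
  expect_equal(r$ageMax, 80)
  expect_equal(r$rangeWidth, 35)

  # union across two studies, no truncation active
  a <- IncidenceDataset("AD", "pooled", "S1",
    data.frame(ageStart = c(50, 60), ageEnd = c(60, 70), incidence = c(1, 2)))
  b <- IncidenceDataset("AD", "pooled", "S2",
    data.frame(ageStart = c(60, 75), ageEnd = c(75, 85), incidence = c(1, 2)))
  r2 <- incidenceAgeRange(list(a, b))
  expect_equal(c(r2$ageMin, r2$ageMax), c(50, 85))

  # leading zero-incidence bins do not count toward the interval
  z <- IncidenceDataset("PD", "pooled", "S1",
    data.frame(ageStart = c(30, 40, 50), ageEnd = c(40, 50, 60),
               incidence = c(0, 1, 2)))
  expect_equal(incidenceAgeRange(list(z))$ageMin, 40)

  allz <- IncidenceDataset("PD", "pooled", "S1",
    data.frame(ageStart = c(30, 40), ageEnd = c(40, 50), incidence = c(0, 0)))
  expect_error(incidenceAgeRange(list(allz)), "all-zero")
})

test_that("years per step divides the range width by the step count", {
  expect_equal(yearsPerStep(30, 10L), 3)
  expect_equal(yearsPerStep(0, 5L), 0)
  expect_equal(yearsPerStep(65, 2L), 32.5)   # the stem-disease value
  # antitone in steps at fixed range, monotone in range at fixed steps
  expect_true(all(diff(sapply(1:13, function(n) yearsPerStep(40, n))) < 0))
  expect_true(all(diff(sapply(seq(0, 60, 10),
                              function(w) yearsPerStep(w, 6L))) > 0))
  expect_error(yearsPerStep(30, 0L), "nSteps")
  expect_error(yearsPerStep(-1, 2L), "rangeWidth")
})

test_that("steps-vs-range regression flags degenerate inputs", {
  s <- data.frame(stratum = letters[1:4], rangeWidth = c(20, 30, 40, 50),
                  nSteps = c(6L, 6L, 6L, 6L), passesLinearity = TRUE)
  fit <- fitStepsVsRange(s)
  expect_equal(fit$slope, 0, tolerance = 1e-12)

  s2 <- data.frame(stratum = letters[1:5], rangeWidth = seq(20, 60, 10),
                   nSteps = as.integer(round(14 - 0.2 * seq(20, 60, 10))),
                   passesLinearity = TRUE)
  fit2 <- fitStepsVsRange(s2)
  expect_equal(fit2$rSquared, 1, tolerance = 1e-9)
  expect_equal(fit2$slope, -0.2, tolerance = 1e-9)

  s3 <- s2; s3$rangeWidth <- 30
  expect_error(fitStepsVsRange(s3), "degenerate")
  expect_error(fitStepsVsRange(s2[1:2, ]), "at least 3")
})

test_that("shared-age-bin counts respect coverage and input order", {
  s <- data.frame(stratum = c("A", "B", "C"),
                  ageMin = c(50, 55, 60), ageMax = c(80, 75, 70))
  sh <- sharedAgeBins(s, binWidth = 2)
  expect_identical(sh$sharedInterval$count, 3L)
  expect_equal(sh$sharedInterval$ageStart, 60)
  expect_equal(sh$sharedInterval$ageEnd, 70)
  expect_true(all(sh$bins$count <= 3L))
  # permutation invariance
  sh2 <- sharedAgeBins(s[c(3, 1, 2), ], binWidth = 2)
  expect_equal(sh2$bins, sh$bins)

  disjoint <- data.frame(stratum = c("A", "B"),
                         ageMin = c(40, 60), ageMax = c(50, 70))
  expect_lte(max(sharedAgeBins(disjoint)$bins$count), 1L)
})

test_that("the default panel shares ages 60-78 across every stratum", {
  res <- defaultRun()
  sh <- res$sharedBins
  expect_identical(sh$sharedInterval$count, nrow(res$summaries))
  expect_lte(sh$sharedInterval$ageStart, 60)
  expect_gte(sh$sharedInterval$ageEnd, 78)
  full <- sh$bins[sh$bins$ageStart >= 60 & sh$bins$ageEnd <= 78, ]
  expect_true(all(full$count == nrow(res$summaries)))
})

test_that("years/step groups the default panel into its three tiers", {
  res <- defaultRun()
  s <- res$summaries[res$summaries$passesLinearity, ]
  hc <- hclust(dist(s$yearsPerStep), method = "single")
  cl <- cutree(hc, k = 3)
  design <- c(HD = 1, ALS = 2, PD = 2, FTD = 2, CJD = 2,
              PDM = 3, PDD = 3, ADm = 3, DLB = 3, ADf = 3)[s$stratum]
  # the three single-linkage clusters coincide with the designed tiers
  expect_identical(length(unique(paste(cl, design))), 3L)
})
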