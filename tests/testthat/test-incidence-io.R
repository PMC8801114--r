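test_that("stratum labels render and parse per the naming convention", {
  expect_identical(parseStratumLabel("DLBm"),
                   list(diseaseCode = "DLB", sex = "male"))
  expect_identical(parseStratumLabel("ADf"),
                   list(diseaseCode = "AD", sex = "female"))
  expect_identical(parseStratumLabel("MS"),
                   list(diseaseCode = "MS", sex = "pooled"))
  # PDM is all-uppercase: Parkinsonism pooled, not PD male
  expect_identical(parseStratumLabel("PDM")$sex, "pooled")
  expect_error(parseStratumLabel("als"), "malformed")
  expect_error(parseStratumLabel("ADx"), "malformed")
  expect_error(parseStratumLabel(""), "non-empty")

  for (lab in c("ALSm", "ADf", "MS", "PDM")) {
    parts <- parseStratumLabel(lab)
    expect_identical(renderStratumLabel(parts$diseaseCode, parts$sex), lab)
  }
})

test_that("incidence tables round-trip losslessly", {
  p <- generatePanel(defaultPanelSpecs(nStudies = 2L), seed = 9L)
  f <- withr::local_tempfile(fileext = ".csv")
  writeIncidenceTable(p, f)
  p2 <- readIncidenceTable(f)
  expect_length(p2, length(p))
  for (i in seq_along(p)) {
    j <- match(paste(stratumLabel(p[[i]]), studyId(p[[i]]), sep = "/"),
               names(p2))
    expect_equal(bins(p2[[j]]), bins(p[[i]]), tolerance = 1e-12)
  }
  # idempotence once the read-side ordering has been applied
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeIncidenceTable(p2, f2)
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeIncidenceTable(readIncidenceTable(f2), f3)
  expect_identical(readLines(f2), readLines(f3))
})

test_that("malformed tables are rejected with row diagnostics", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("disease,sex,study_id,age_start,age_end,incidence",
               "AD,pooled,S1,60,65,10",
               "AD,pooled,S1,63,68,12"), f)
  expect_error(readIncidenceTable(f), "overlapping.*rows 2, 3")

  writeLines(c("disease,sex,study_id,age_start,age_end,incidence",
               "AD,pooled,S1,60,65,-1",
               "AD,pooled,S1,65,70,2"), f)
  expect_error(readIncidenceTable(f), "negative incidence at row\\(s\\) 2")

  writeLines(c("disease,sex,age_start,age_end,incidence",
               "AD,pooled,60,65,1"), f)
  expect_error(readIncidenceTable(f), "study_id")

  # a 5-row single-study file yields one dataset with 5 bins
  writeLines(c("disease,sex,study_id,age_start,age_end,incidence",
               sprintf("AD,pooled,S1,%d,%d,%d", seq(50, 70, 5),
                       seq(55, 75, 5), 1:5)), f)
  p <- readIncidenceTable(f)
  expect_length(p, 1L)
  expect_identical(nrow(bins(p[[1]])), 5L)
})

test_that("registry filter drops pooled datasets with sexed counterparts", {
  mk <- function(code, sex, study) {
    IncidenceDataset(code, sex, study,
                     data.frame(ageStart = c(60, 65), ageEnd = c(65, 70),
                                incidence = c(1, 2)))
  }
  panel <- IncidencePanel(list(
    mk("AD", "male", "S1"), mk("AD", "female", "S1"), mk("AD", "pooled", "S1"),
    mk("PD", "pooled", "S2"),                    # no counterpart: retained
    mk("AD", "pooled", "AD-60")))                # on the exclusion list
  out <- filterRegistry(panel, verbose = FALSE)
  labs <- paste(vapply(out, stratumLabel, character(1)),
                vapply(out, studyId, character(1)), sep = "/")
  expect_setequal(labs, c("ADm/S1", "ADf/S1", "PD/S2"))
  expect_setequal(attr(out, "removed")$study_id, c("S1", "AD-60"))

  # sex-annotated datasets are never removed, whatever the configuration
  out2 <- filterRegistry(panel, counterpartRule = FALSE, verbose = FALSE)
  expect_true(all(c("ADm/S1", "ADf/S1") %in%
                  paste(vapply(out2, stratumLabel, character(1)),
                        vapply(out2, studyId, character(1)), sep = "/")))

  expect_length(filterRegistry(IncidencePanel(list()), verbose = FALSE), 0L)
})

test_that("the documented exclusion list carries the seven AD dataset IDs", {
  expect_setequal(excludedRegistryIds(),
                  c("AD-60", "AD-61", "AD-62", "AD-68", "AD-71", "AD-78",
                    "AD-82"))
})
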