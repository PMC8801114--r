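# Shared fixtures built in code.  The default-panel pipeline run is cached
# so the several tests that inspect it pay for it once per session.

.fixtureCache <- new.env(parent = emptyenv())

defaultRun <- function(seed = 101L) {
  key <- paste0("run", seed)
  if (is.null(.fixtureCache[[key]])) {
    cfg <- pipelineConfig(seed = seed, outdir = tempfile("ndsteps_fix_"))
    .fixtureCache[[key]] <- runPipeline(cfg, quiet = TRUE)
  }
  .fixtureCache[[key]]
}

# Noiseless power-law dataset: incidence u * t^(n-1) at bin midpoints.
powerLawDataset <- function(n = 6L, u = 1e-9, ageMin = 45, ageMax = 80,
                            binWidth = 5, code = "ALS", sex = "pooled",
                            study = "S1") {
  start <- seq(ageMin, ageMax - binWidth, by = binWidth)
  mid <- start + binWidth / 2
  IncidenceDataset(code, sex, study,
                   data.frame(ageStart = start, ageEnd = start + binWidth,
                              incidence = u * mid^(n - 1)))
}

# Dataset with explicit bin midpoints (unit-width bins around them).
midpointDataset <- function(mid, incidence, code = "AD", sex = "pooled",
                            study = "S1") {
  IncidenceDataset(code, sex, study,
                   data.frame(ageStart = mid - 0.5, ageEnd = mid + 0.5,
                              incidence = incidence))
}

# Independent OLS oracle: brute-force normal equations.
olsNormalEquations <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  list(intercept = beta[1L], slope = beta[2L])
}
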