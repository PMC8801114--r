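#' @include incidenceIO.R
NULL

# Run expr with a private, restored RNG state seeded from `seed`.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Stable 31-bit sub-seed from a master seed and a character/integer context,
# so every dataset gets an independent but reproducible stream.
.deriveSeed <- function(seed, label, studyIndex) {
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647
  h <- (h * 31 + as.double(studyIndex)) %% 2147483647
  as.integer(h)
}

#' Construct a synthetic disease-stratum specification
#'
#' @param diseaseCode uppercase disease code.
#' @param sex `"pooled"` (default), `"male"` or `"female"`.
#' @param nTrue true number of steps (>= 1).
#' @param backgroundRiskU product of per-step background risks, on the
#'   scale of incidence per 100,000 person-years (so that a multistep
#'   stratum has incidence \eqn{u t^{n-1}} at age t).
#' @param ageMin,ageMax designed incidence age range in years (`ageMin > 0`).
#' @param binWidth age-bin width in years.
#' @param noiseSigma sd of Gaussian noise on log incidence.
#' @param nStudies number of independent studies to simulate.
#' @param model `"multistep"` or `"nonmonotone_control"`.
#' @param peakAge,peakShape peak location (years) and sharpness of the
#'   control model's unimodal incidence curve.
#' @return a [DiseaseSpec-class].
#' @examples
#' diseaseSpec("ALS", sex = "male", nTrue = 6L, backgroundRiskU = 1e-9,
#'             ageMin = 45, ageMax = 80)
#' @export
diseaseSpec <- function(diseaseCode, sex = "pooled", nTrue = 6L,
                        backgroundRiskU = 1e-9, ageMin = 30, ageMax = 80,
                        binWidth = 5, noiseSigma = 0.05, nStudies = 1L,
                        model = c("multistep", "nonmonotone_control"),
                        peakAge = 30, peakShape = 3) {
  model <- match.arg(model)
  new("DiseaseSpec", diseaseCode = diseaseCode, sex = sex,
      nTrue = as.integer(nTrue), backgroundRiskU = backgroundRiskU,
      ageMin = ageMin, ageMax = ageMax, binWidth = binWidth,
      noiseSigma = noiseSigma, nStudies = as.integer(nStudies),
      model = model, peakAge = peakAge, peakShape = peakShape)
}

# Unimodal (rise-then-fall) incidence curve for the MS-like control:
# a Gamma-density shape normalized to peak `u` at `peakAge`, so the
# log-log trajectory is deliberately non-linear and mostly decreasing
# over adult ages.
.controlIncidence <- function(t, u, peakAge, peakShape) {
  u * (t / peakAge)^peakShape * exp(peakShape * (1 - t / peakAge))
}

#' Simulate one age-stratified incidence study
#'
#' For `model = "multistep"` the incidence at each bin midpoint t is
#' \eqn{u t^{n-1} e^{\epsilon}} with \eqn{\epsilon \sim N(0, \sigma^2)}
#' (multiplicative log-normal noise, so the log-log fit's error is additive
#' Gaussian and incidence stays positive).  For
#' `model = "nonmonotone_control"` a unimodal curve peaking near
#' `peakAge` replaces the power law.  The bin midpoint is the
#' representative age, mirroring the fitting convention.
#'
#' @param spec a [DiseaseSpec-class].
#' @param studyIndex positive integer distinguishing studies of one spec.
#' @param seed master seed; together with the stratum label and
#'   `studyIndex` it fixes all randomness.
#' @param jitter maximum uniform offset (years) added to all bin edges of
#'   this study, emulating heterogeneous bin schemes; 0 disables.
#' @return an [IncidenceDataset-class] with study ID
#'   `"<label>-S<studyIndex>"`.
#' @examples
#' spec <- diseaseSpec("ALS", nTrue = 6L, backgroundRiskU = 1e-9,
#'                     ageMin = 45, ageMax = 80, noiseSigma = 0)
#' d <- generateDataset(spec, 1L, seed = 1L)
#' all.equal(bins(d)$incidence, 1e-9 * ((bins(d)$ageStart +
#'           bins(d)$ageEnd) / 2)^5)
#' @export
generateDataset <- function(spec, studyIndex = 1L, seed = 1L, jitter = 0) {
  stopifnot(is(spec, "DiseaseSpec"))
  validObject(spec)
  if (spec@ageMin <= 0)
    stop("ageMin must be > 0: the model takes log(age)")
  if (spec@binWidth >= spec@ageMax - spec@ageMin)
    stop("binWidth must be smaller than the age range")
  label <- stratumLabel(spec)
  .withSeed(.deriveSeed(seed, label, studyIndex), {
    offset <- if (jitter > 0) stats::runif(1, 0, jitter) else 0
    edges <- seq(spec@ageMin, spec@ageMax, by = spec@binWidth)
    if (max(edges) < spec@ageMax) edges <- c(edges, spec@ageMax)
    edges <- edges + offset
    start <- edges[-length(edges)]
    end <- edges[-1L]
    mid <- (start + end) / 2
    base <- if (spec@model == "multistep") {
      spec@backgroundRiskU * mid^(spec@nTrue - 1L)
    } else {
      .controlIncidence(mid, spec@backgroundRiskU, spec@peakAge,
                        spec@peakShape)
    }
    eps <- if (spec@noiseSigma > 0)
      stats::rnorm(length(mid), 0, spec@noiseSigma) else 0
    inc <- base * exp(eps)
    stopifnot(all(inc > 0))
    IncidenceDataset(spec@diseaseCode, spec@sex,
                     sprintf("%s-S%d", label, studyIndex),
                     data.frame(ageStart = start, ageEnd = end,
                                incidence = inc))
  })
}

#' Simulate a panel of incidence studies
#'
#' Generates `nStudies` independent studies per specification, with
#' distinct study IDs and, by default, per-study jitter of the bin scheme
#' (uniform offset of all bin edges by 0--`jitter` years) so that studies
#' of one stratum genuinely differ in their age grids and exercise the
#' spline harmonization.  Output is deterministic under a fixed seed.
#'
#' @param specs list of [DiseaseSpec-class] objects; disease/sex pairs must
#'   be unique.
#' @param seed master seed fixing all randomness.
#' @param jitter maximum bin-edge offset in years (default 2; 0 disables).
#' @return an [IncidencePanel-class] with one element per (spec, study).
#' @examples
#' p <- generatePanel(defaultPanelSpecs(), seed = 7L)
#' length(p)   # 11 strata x 3 studies
#' @export
generatePanel <- function(specs, seed = 1L, jitter = 2) {
  labels <- vapply(specs, stratumLabel, character(1))
  if (anyDuplicated(labels))
    stop("duplicate disease/sex pairs in 'specs': ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  datasets <- list()
  for (spec in specs)
    for (j in seq_len(spec@nStudies))
      datasets[[length(datasets) + 1L]] <-
        generateDataset(spec, j, seed = seed, jitter = jitter)
  ids <- vapply(datasets, function(d)
    paste(diseaseCode(d), sexStratum(d), studyId(d), sep = "/"), character(1))
  if (anyDuplicated(ids))
    stop("duplicate (disease, sex, study) triples generated")
  IncidencePanel(datasets)
}

#' Default synthetic study conditions
#'
#' Ten multistep strata whose true step counts
#' \{2, 6, 6, 6, 6, 8, 9, 11, 12, 13\} follow the step counts reported for
#' the major neurodegenerative diseases (HD 2; ALS, PD, FTD, CJD 6; PDM 8;
#' PDD 9; AD 11 male and 13 female; DLB 12), plus one MS-like nonmonotone
#' control.  Designed incidence age ranges are inversely related to the
#' step count, so that years-per-step falls into three tiers (roughly
#' 30+, 7--14 and 2--4 years/step) and every stratum covers the common
#' interval 60--78 years.  Background risks are set so that incidence at
#' age 70 lies in a realistic 0.1--250 per 100,000 person-years window.
#' Three studies per stratum, log-noise sd 0.05.
#'
#' @param nStudies studies per stratum.
#' @param noiseSigma sd of the log-incidence noise.
#' @return a list of [DiseaseSpec-class] objects.
#' @export
defaultPanelSpecs <- function(nStudies = 3L, noiseSigma = 0.05) {
  design <- list(
    #        code   sex       n   i(70)  ageMin ageMax binWidth
    list("HD",  "pooled",  2L,   0.4,  15, 80, 5),
    list("ALS", "pooled",  6L,   6,    35, 80, 5),
    list("PD",  "pooled",  6L,  30,    38, 80, 6),
    list("FTD", "pooled",  6L,   3,    32, 80, 6),
    list("CJD", "pooled",  6L,   0.15, 30, 80, 5),
    list("PDM", "pooled",  8L,  20,    48, 80, 4),
    list("PDD", "pooled",  9L,  10,    42, 78, 4),
    list("AD",  "male",   11L, 200,    55, 80, 5),
    list("DLB", "pooled", 12L,  15,    52, 80, 4),
    list("AD",  "female", 13L, 250,    58, 88, 5)
  )
  specs <- lapply(design, function(d)
    diseaseSpec(d[[1]], sex = d[[2]], nTrue = d[[3]],
                backgroundRiskU = d[[4]] / 70^(d[[3]] - 1L),
                ageMin = d[[5]], ageMax = d[[6]], binWidth = d[[7]],
                noiseSigma = noiseSigma, nStudies = nStudies))
  specs[[length(specs) + 1L]] <-
    diseaseSpec("MS", sex = "pooled", nTrue = 1L, backgroundRiskU = 5,
                ageMin = 15, ageMax = 80, binWidth = 5,
                noiseSigma = noiseSigma, nStudies = nStudies,
                model = "nonmonotone_control", peakAge = 30, peakShape = 3)
  specs
}

#' Write a panel manifest
#'
#' Records the full specification list and seed as JSON for provenance.
#'
#' @param specs list of [DiseaseSpec-class] objects.
#' @param seed the seed used with [generatePanel()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writePanelManifest <- function(specs, seed, path) {
  entry <- function(s) list(
    disease = s@diseaseCode, sex = s@sex, n_true = s@nTrue,
    background_risk_u = s@backgroundRiskU, age_min = s@ageMin,
    age_max = s@ageMax, bin_width = s@binWidth, noise_sigma = s@noiseSigma,
    n_studies = s@nStudies, model = s@model)
  jsonlite::write_json(list(seed = seed, specs = lapply(specs, entry)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
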