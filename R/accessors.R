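#' @include AllGenerics.R
NULL

#' Accessors for incidence datasets and model fits
#'
#' `diseaseCode()`, `sexStratum()` and `studyId()` return the identifying
#' fields of a dataset; `bins()` its age-bin table.  `stratumLabel()`
#' renders the field's naming convention: labels ending in lowercase `f`
#' are female strata, lowercase `m` male strata, and all-uppercase labels
#' the pool of the two sexes.
#'
#' @param x an object.
#' @return the corresponding slot value.
#' @name accessors
#' @aliases diseaseCode sexStratum studyId bins stratumLabel nSteps slopeM
#'   backgroundRisk geomMeanRisk rSquared passesLinearity ageGrid incidence
#'   coverage embeddingCoords explainedVariance allocations branchPoints
#'   referenceLeaves
#' @examples
#' spec <- diseaseSpec("ALS", sex = "male", nTrue = 6L,
#'                     backgroundRiskU = 1e-9, ageMin = 45, ageMax = 80)
#' d <- generateDataset(spec, studyIndex = 1L, seed = 1L)
#' stratumLabel(d)   # "ALSm"
#' head(bins(d))
NULL

#' @rdname accessors
#' @export
setMethod("diseaseCode", "IncidenceDataset", function(x) x@diseaseCode)
#' @rdname accessors
#' @export
setMethod("diseaseCode", "DiseaseSpec", function(x) x@diseaseCode)
#' @rdname accessors
#' @export
setMethod("sexStratum", "IncidenceDataset", function(x) x@sex)
#' @rdname accessors
#' @export
setMethod("sexStratum", "DiseaseSpec", function(x) x@sex)
#' @rdname accessors
#' @export
setMethod("studyId", "IncidenceDataset", function(x) x@studyId)
#' @rdname accessors
#' @export
setMethod("bins", "IncidenceDataset", function(x) x@bins)

#' @rdname accessors
#' @export
setMethod("stratumLabel", "IncidenceDataset", function(x)
  renderStratumLabel(x@diseaseCode, x@sex))
#' @rdname accessors
#' @export
setMethod("stratumLabel", "DiseaseSpec", function(x)
  renderStratumLabel(x@diseaseCode, x@sex))
#' @rdname accessors
#' @export
setMethod("stratumLabel", "MultistepFit", function(x) x@stratum)
#' @rdname accessors
#' @export
setMethod("stratumLabel", "LogLogPoints", function(x) x@stratum)

#' @rdname accessors
#' @export
setMethod("nSteps", "MultistepFit", function(x) x@nSteps)
#' @rdname accessors
#' @export
setMethod("slopeM", "MultistepFit", function(x) x@slopeM)
#' @rdname accessors
#' @export
setMethod("backgroundRisk", "MultistepFit", function(x) x@backgroundRiskU)
#' @rdname accessors
#' @export
setMethod("geomMeanRisk", "MultistepFit", function(x) x@geomMeanRiskMu)
#' @rdname accessors
#' @export
setMethod("rSquared", "MultistepFit", function(x) x@rSquared)
#' @rdname accessors
#' @export
setMethod("passesLinearity", "MultistepFit", function(x) x@passesLinearity)

#' @rdname accessors
#' @export
setMethod("ageGrid", "IncidenceMatrix", function(x)
  SummarizedExperiment::colData(x)$age)
#' @rdname accessors
#' @export
setMethod("incidence", "IncidenceMatrix", function(x)
  SummarizedExperiment::assay(x, "incidence"))
#' @rdname accessors
#' @export
setMethod("coverage", "IncidenceMatrix", function(x)
  SummarizedExperiment::assay(x, "coverage"))

#' @rdname accessors
#' @export
setMethod("embeddingCoords", "Embedding", function(x) x@coordinates)
#' @rdname accessors
#' @export
setMethod("explainedVariance", "Embedding", function(x)
  x@explainedVariancePct)

#' @rdname accessors
#' @export
setMethod("allocations", "GenealogyTree", function(x) x@allocations)
#' @rdname accessors
#' @export
setMethod("branchPoints", "GenealogyTree", function(x) x@branchPoints)
#' @rdname accessors
#' @export
setMethod("referenceLeaves", "GenealogyTree", function(x) x@referenceLeaves)

setMethod("show", "DiseaseSpec", function(object) {
  cat(sprintf(
    "DiseaseSpec %s [%s]: n=%d, u=%.3g, ages [%g, %g), bin %g y, sigma %.3g, %d studies\n",
    stratumLabel(object), object@model, object@nTrue, object@backgroundRiskU,
    object@ageMin, object@ageMax, object@binWidth, object@noiseSigma,
    object@nStudies))
})

setMethod("show", "IncidenceDataset", function(object) {
  b <- object@bins
  cat(sprintf(
    "IncidenceDataset %s / %s: %d bins spanning [%g, %g) years\n",
    stratumLabel(object), object@studyId, nrow(b),
    min(b$ageStart), max(b$ageEnd)))
})

setMethod("show", "LogLogPoints", function(object) {
  cat(sprintf("LogLogPoints %s: %d points%s\n", object@stratum,
              length(object@logAge),
              if (object@truncated) " (ages >= 80 truncated)" else ""))
})

setMethod("show", "MultistepFit", function(object) {
  cat(sprintf(
    "MultistepFit %s: m=%.3f -> n=%d steps, u=%.3g, mu=%.3g, R2=%.3f (%d points%s)%s\n",
    object@stratum, object@slopeM, object@nSteps, object@backgroundRiskU,
    object@geomMeanRiskMu, object@rSquared, object@nPoints,
    if (object@truncated) ", truncated" else "",
    if (object@passesLinearity) "" else " [fails linearity gate]"))
})

setMethod("show", "Embedding", function(object) {
  cat(sprintf("%s embedding of %d profiles in %d dimensions\n",
              toupper(object@method), nrow(object@coordinates),
              ncol(object@coordinates)))
  if (length(object@explainedVariancePct))
    cat(sprintf("  explained variance: %s%%\n",
                paste(round(object@explainedVariancePct, 1), collapse = ", ")))
})

setMethod("show", "SharingMatrix", function(object) {
  cat(sprintf(
    "SharingMatrix: %d diseases, %d candidate sharing sets, ordinals 1..%d\n",
    length(object@diseases), length(object@subsets), nrow(object@feasible)))
})

setMethod("show", "GenealogyTree", function(object) {
  a <- object@allocations
  cat(sprintf("GenealogyTree (%s): %d diseases, trunk height %d\n",
              object@sexMode, nrow(a),
              if (nrow(object@trunk)) max(object@trunk$ordinal) else 0L))
  if (length(object@referenceLeaves))
    cat("  reference leaves:", paste(object@referenceLeaves, collapse = ", "),
        "\n")
})
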