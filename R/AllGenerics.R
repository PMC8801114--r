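#' @include AllClasses.R
NULL

#' @export
setGeneric("diseaseCode", function(x) standardGeneric("diseaseCode"))
#' @export
setGeneric("sexStratum", function(x) standardGeneric("sexStratum"))
#' @export
setGeneric("studyId", function(x) standardGeneric("studyId"))
#' @export
setGeneric("bins", function(x) standardGeneric("bins"))
#' @export
setGeneric("stratumLabel", function(x) standardGeneric("stratumLabel"))
#' @export
setGeneric("nSteps", function(x) standardGeneric("nSteps"))
#' @export
setGeneric("slopeM", function(x) standardGeneric("slopeM"))
#' @export
setGeneric("backgroundRisk", function(x) standardGeneric("backgroundRisk"))
#' @export
setGeneric("geomMeanRisk", function(x) standardGeneric("geomMeanRisk"))
#' @export
setGeneric("rSquared", function(x) standardGeneric("rSquared"))
#' @export
setGeneric("passesLinearity", function(x) standardGeneric("passesLinearity"))
#' @export
setGeneric("ageGrid", function(x) standardGeneric("ageGrid"))
#' @export
setGeneric("incidence", function(x) standardGeneric("incidence"))
#' @export
setGeneric("coverage", function(x) standardGeneric("coverage"))
#' @export
setGeneric("embeddingCoords", function(x) standardGeneric("embeddingCoords"))
#' @export
setGeneric("explainedVariance", function(x) standardGeneric("explainedVariance"))
#' @export
setGeneric("allocations", function(x) standardGeneric("allocations"))
#' @export
setGeneric("branchPoints", function(x) standardGeneric("branchPoints"))
#' @export
setGeneric("referenceLeaves", function(x) standardGeneric("referenceLeaves"))
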