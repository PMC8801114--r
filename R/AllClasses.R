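#' @import methods
#' @importFrom S4Vectors SimpleList
NULL

.SEXES <- c("male", "female", "pooled")

#' Specification of one synthetic disease stratum
#'
#' A `DiseaseSpec` fixes the ground truth used to simulate age-stratified
#' incidence for one disease/sex stratum: the true number of rate-limiting
#' steps `nTrue`, the background risk `backgroundRiskU` (the product of the
#' per-step risks, so that incidence follows \eqn{i = u t^{n-1}}), the
#' designed incidence age range, the age-bin width, the standard deviation
#' of multiplicative log-normal noise, and how many independent studies to
#' simulate.  `model = "nonmonotone_control"` instead produces a unimodal
#' rise-then-fall incidence curve (a multiple-sclerosis-like control whose
#' log-log trajectory is deliberately not linear).
#'
#' @slot diseaseCode single uppercase disease code, e.g. `"ALS"`.
#' @slot sex one of `"male"`, `"female"`, `"pooled"`.
#' @slot nTrue integer, true step count (>= 1); ignored by the control model.
#' @slot backgroundRiskU positive numeric, product of per-step risks, on the
#'   incidence scale of cases per 100,000 person-years.
#' @slot ageMin,ageMax numeric years bounding the designed incidence range.
#' @slot binWidth numeric years, width of the simulated age bins.
#' @slot noiseSigma non-negative numeric, sd of the Gaussian noise added to
#'   log incidence (multiplicative log-normal on the natural scale).
#' @slot nStudies integer number of studies to simulate for this stratum.
#' @slot model `"multistep"` or `"nonmonotone_control"`.
#' @slot peakAge,peakShape numeric, location and sharpness of the control
#'   model's incidence peak (unused by `"multistep"`).
#' @export
setClass("DiseaseSpec",
  representation(
    diseaseCode = "character",
    sex = "character",
    nTrue = "integer",
    backgroundRiskU = "numeric",
    ageMin = "numeric",
    ageMax = "numeric",
    binWidth = "numeric",
    noiseSigma = "numeric",
    nStudies = "integer",
    model = "character",
    peakAge = "numeric",
    peakShape = "numeric"
  )
)

setValidity("DiseaseSpec", function(object) {
  msg <- character()
  if (length(object@diseaseCode) != 1L || !nzchar(object@diseaseCode))
    msg <- c(msg, "'diseaseCode' must be a single non-empty string")
  if (length(object@sex) != 1L || !(object@sex %in% .SEXES))
    msg <- c(msg, "'sex' must be one of 'male', 'female', 'pooled'")
  if (length(object@nTrue) != 1L || is.na(object@nTrue) || object@nTrue < 1L)
    msg <- c(msg, "'nTrue' must be an integer >= 1")
  if (object@backgroundRiskU <= 0)
    msg <- c(msg, "'backgroundRiskU' must be > 0")
  if (!(object@ageMin < object@ageMax))
    msg <- c(msg, "'ageMin' must be < 'ageMax'")
  if (object@ageMin <= 0)
    msg <- c(msg, "'ageMin' must be > 0 (log of age is taken downstream)")
  if (object@binWidth <= 0 || object@binWidth >= object@ageMax - object@ageMin)
    msg <- c(msg, "'binWidth' must be positive and smaller than the age range")
  if (object@noiseSigma < 0)
    msg <- c(msg, "'noiseSigma' must be >= 0")
  if (object@nStudies < 1L)
    msg <- c(msg, "'nStudies' must be >= 1")
  if (!(object@model %in% c("multistep", "nonmonotone_control")))
    msg <- c(msg, "'model' must be 'multistep' or 'nonmonotone_control'")
  if (length(msg)) msg else TRUE
})

#' One study's age-stratified incidence for one disease/sex stratum
#'
#' The incidence rate is the number of new cases per population at risk in a
#' given time period, here expressed per 100,000 person-years within
#' half-open age bins `[ageStart, ageEnd)`.
#'
#' @slot diseaseCode single uppercase disease code.
#' @slot sex `"male"`, `"female"` or `"pooled"`.
#' @slot studyId study identifier string.
#' @slot bins `data.frame` with numeric columns `ageStart`, `ageEnd`,
#'   `incidence`; bins are ascending and non-overlapping.
#' @export
setClass("IncidenceDataset",
  representation(
    diseaseCode = "character",
    sex = "character",
    studyId = "character",
    bins = "data.frame"
  )
)

setValidity("IncidenceDataset", function(object) {
  msg <- character()
  if (length(object@diseaseCode) != 1L || !nzchar(object@diseaseCode))
    msg <- c(msg, "'diseaseCode' must be a single non-empty string")
  if (!(object@sex %in% .SEXES))
    msg <- c(msg, "'sex' must be one of 'male', 'female', 'pooled'")
  if (length(object@studyId) != 1L || !nzchar(object@studyId))
    msg <- c(msg, "'studyId' must be a single non-empty string")
  b <- object@bins
  need <- c("ageStart", "ageEnd", "incidence")
  if (!all(need %in% names(b))) {
    msg <- c(msg, sprintf("'bins' must have columns %s",
                          paste(need, collapse = ", ")))
    return(msg)
  }
  if (nrow(b) < 2L)
    msg <- c(msg, "'bins' must contain at least 2 age bins")
  if (any(b$ageStart >= b$ageEnd))
    msg <- c(msg, "every bin must satisfy ageStart < ageEnd")
  if (any(b$incidence < 0))
    msg <- c(msg, "incidence must be >= 0")
  if (nrow(b) >= 2L) {
    if (is.unsorted(b$ageStart, strictly = TRUE))
      msg <- c(msg, "bins must be in strictly ascending ageStart order")
    if (any(b$ageEnd[-nrow(b)] > b$ageStart[-1L] + 1e-9))
      msg <- c(msg, "bins must be non-overlapping")
  }
  if (length(msg)) msg else TRUE
})

#' A collection of incidence datasets
#'
#' A `SimpleList` of [IncidenceDataset-class] objects, usually spanning
#' several diseases, sex strata and studies.
#'
#' @export
setClass("IncidencePanel", contains = "SimpleList",
         prototype = prototype(elementType = "IncidenceDataset"))

#' Pooled log-log points for one stratum
#'
#' Log10(bin-midpoint age) and log10(incidence) pairs pooled across the
#' studies of one disease/sex stratum, after dropping zero-incidence bins
#' and (when at least 4 points remain afterwards) bins with midpoints at or
#' above 80 years.
#'
#' @slot logAge,logIncidence numeric vectors (log10 scale).
#' @slot sourceIds study identifiers contributing each point.
#' @slot truncated logical, whether the age-80 truncation was applied.
#' @slot stratum rendered stratum label (e.g. `"ALSm"`).
#' @export
setClass("LogLogPoints",
  representation(
    logAge = "numeric",
    logIncidence = "numeric",
    sourceIds = "character",
    truncated = "logical",
    stratum = "character"
  )
)

setValidity("LogLogPoints", function(object) {
  msg <- character()
  if (length(object@logAge) != length(object@logIncidence))
    msg <- c(msg, "'logAge' and 'logIncidence' must have equal length")
  if (length(object@logAge) < 2L)
    msg <- c(msg, "at least 2 points are required")
  if (any(!is.finite(object@logAge)) || any(!is.finite(object@logIncidence)))
    msg <- c(msg, "points must be finite (zero-incidence bins must be dropped)")
  if (length(msg)) msg else TRUE
})

#' Multistep model fit for one stratum
#'
#' Ordinary least-squares fit of log10 incidence on log10 age.  The slope
#' `m` estimates `n - 1`, so the step count is `n = round(m + 1)`; the
#' intercept, converted to natural-log scale, gives the background risk
#' `u = exp(c)` and its per-step geometric mean `mu = u^(1/n)`.
#'
#' @slot stratum rendered stratum label.
#' @slot slopeM regression slope (dimensionless).
#' @slot interceptC10 intercept on the log10 scale actually fitted.
#' @slot interceptC intercept converted to natural-log scale.
#' @slot nSteps estimated number of steps (>= 1).
#' @slot backgroundRiskU `exp(interceptC)`.
#' @slot geomMeanRiskMu `backgroundRiskU^(1/nSteps)`.
#' @slot rSquared coefficient of determination in [0, 1].
#' @slot nPoints number of points entering the regression.
#' @slot truncated whether the age-80 truncation was applied.
#' @slot passesLinearity whether the stratum passes the linearity gate
#'   (r-squared above the gate threshold and positive slope).
#' @slot gateThreshold the r-squared threshold used by the gate.
#' @export
setClass("MultistepFit",
  representation(
    stratum = "character",
    slopeM = "numeric",
    interceptC10 = "numeric",
    interceptC = "numeric",
    nSteps = "integer",
    backgroundRiskU = "numeric",
    geomMeanRiskMu = "numeric",
    rSquared = "numeric",
    nPoints = "integer",
    truncated = "logical",
    passesLinearity = "logical",
    gateThreshold = "numeric"
  )
)

setValidity("MultistepFit", function(object) {
  msg <- character()
  if (object@nSteps < 1L)
    msg <- c(msg, "'nSteps' must be >= 1")
  if (is.finite(object@rSquared) &&
      (object@rSquared < -1e-9 || object@rSquared > 1 + 1e-9))
    msg <- c(msg, "'rSquared' must lie in [0, 1]")
  if (object@backgroundRiskU <= 0)
    msg <- c(msg, "'backgroundRiskU' must be > 0")
  rel <- abs(object@geomMeanRiskMu^object@nSteps - object@backgroundRiskU) /
    object@backgroundRiskU
  if (rel > 1e-6)
    msg <- c(msg, "'geomMeanRiskMu'^nSteps must equal 'backgroundRiskU'")
  if (length(msg)) msg else TRUE
})

#' Harmonized diseases-by-ages incidence matrix
#'
#' A [SummarizedExperiment-class] whose `"incidence"` assay holds the
#' d x a matrix I with element I(i, j) the mean incidence of stratum i at
#' common age j across the studies covering that age; cells outside every
#' contributing study's observed range are `NA`.  The `"coverage"` assay
#' counts contributing studies per cell.  `rowData` carries the stratum
#' labels, `colData` the grid ages in years.
#'
#' @export
setClass("IncidenceMatrix", contains = "SummarizedExperiment")

#' Low-dimensional embedding of incidence profiles
#'
#' @slot method `"pca"` or `"umap"`.
#' @slot coordinates numeric matrix, one row per profile, >= 2 columns.
#' @slot explainedVariancePct per-component percentages (PCA only; in
#'   [0, 100], non-increasing).
#' @slot labels profile identifiers (row names of the input table).
#' @slot seed integer seed (UMAP; `NA` for PCA).
#' @slot params list of method parameters as used.
#' @export
setClass("Embedding",
  representation(
    method = "character",
    coordinates = "matrix",
    explainedVariancePct = "numeric",
    labels = "character",
    seed = "integer",
    params = "list"
  )
)

setValidity("Embedding", function(object) {
  msg <- character()
  if (!(object@method %in% c("pca", "umap")))
    msg <- c(msg, "'method' must be 'pca' or 'umap'")
  if (nrow(object@coordinates) != length(object@labels))
    msg <- c(msg, "'labels' must match rows of 'coordinates'")
  ev <- object@explainedVariancePct
  if (length(ev)) {
    if (any(ev < -1e-9) || any(ev > 100 + 1e-9))
      msg <- c(msg, "explained variance percentages must lie in [0, 100]")
    if (is.unsorted(-ev))
      msg <- c(msg, "explained variance percentages must be non-increasing")
    if (sum(ev) > 100 + 1e-6)
      msg <- c(msg, "explained variance percentages must sum to <= 100")
  }
  if (length(msg)) msg else TRUE
})

#' Adjacency structure of candidate shared-step combinations
#'
#' Stores, for every step ordinal k, which subsets of diseases could share
#' step k: a subset is feasible at ordinal k when every member has at least
#' k steps and all members are pairwise compatible.  Columns (candidate
#' subsets) are ordered by subset size descending, then lexicographically.
#' Promoter bookkeeping attributes each shared step once, to the first
#' disease (in label order) of the sharing set.
#'
#' @slot diseases character vector of stratum labels.
#' @slot nSteps integer step counts, parallel to `diseases`.
#' @slot compatible logical symmetric matrix of pairwise compatibility.
#' @slot subsets list of integer vectors (indices into `diseases`), the
#'   candidate sharing sets, deterministically ordered.
#' @slot feasible logical matrix, ordinals x subsets feasibility flags.
#' @export
setClass("SharingMatrix",
  representation(
    diseases = "character",
    nSteps = "integer",
    compatible = "matrix",
    subsets = "list",
    feasible = "matrix"
  )
)

setValidity("SharingMatrix", function(object) {
  msg <- character()
  d <- length(object@diseases)
  if (length(object@nSteps) != d)
    msg <- c(msg, "'nSteps' must be parallel to 'diseases'")
  if (!identical(dim(object@compatible), c(d, d)))
    msg <- c(msg, "'compatible' must be a d x d matrix")
  else if (!isSymmetric(object@compatible))
    msg <- c(msg, "'compatible' must be symmetric")
  if (ncol(object@feasible) != length(object@subsets))
    msg <- c(msg, "'feasible' must have one column per candidate subset")
  # a subset can share ordinal k only if every member has >= k steps
  for (j in seq_along(object@subsets)) {
    s <- object@subsets[[j]]
    ok <- seq_len(nrow(object@feasible)) <= min(object@nSteps[s])
    if (any(object@feasible[, j] & !ok)) {
      msg <- c(msg, "feasibility violates the ordinal-number constraint")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Extended genealogy tree of common and specific disease steps
#'
#' The trunk height counts steps shared among diseases (ordinal-preserving,
#' sharing-maximizing parsimony); branches hold each disease's specific
#' steps.  The trunk width at a branch point is the mean years-per-step of
#' the diseases branching there.  In the sex-split rendering male branches
#' are drawn on one side and female on the other.
#'
#' @slot trunk `data.frame` with columns `ordinal` and `members`
#'   (comma-separated sharing set at that trunk step).
#' @slot branchPoints `data.frame` with columns `height`, `diseases`
#'   (comma-separated), `trunkWidth` (years/step).
#' @slot allocations `data.frame` with columns `stratum`, `nSteps`,
#'   `commonSteps`, `specificSteps`, `yearsPerStep`, `tier`, `side`.
#' @slot referenceLeaves character, non-gated strata (e.g. the MS-like
#'   control) attached outside the trunk.
#' @slot sexMode `"pooled"` or `"split"`.
#' @export
setClass("GenealogyTree",
  representation(
    trunk = "data.frame",
    branchPoints = "data.frame",
    allocations = "data.frame",
    referenceLeaves = "character",
    sexMode = "character"
  )
)

setValidity("GenealogyTree", function(object) {
  msg <- character()
  a <- object@allocations
  if (nrow(a) &&
      any(a$commonSteps + a$specificSteps != a$nSteps))
    msg <- c(msg, "commonSteps + specificSteps must equal nSteps")
  if (nrow(a) && any(a$commonSteps < 0))
    msg <- c(msg, "commonSteps must be >= 0")
  bp <- object@branchPoints
  if (nrow(bp) && is.unsorted(bp$height))
    msg <- c(msg, "branch-point heights must be non-decreasing")
  if (!(object@sexMode %in% c("pooled", "split")))
    msg <- c(msg, "'sexMode' must be 'pooled' or 'split'")
  if (length(msg)) msg else TRUE
})
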