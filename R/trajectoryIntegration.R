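#' @include incidenceIO.R
NULL

#' Interpolate one study onto a common age grid
#'
#' A natural cubic spline (second derivative zero at the boundary knots)
#' is passed through the study's (bin midpoint, incidence) points and
#' evaluated at the grid ages falling inside the study's midpoint range;
#' grid ages outside that range are `NA` — the spline is never
#' extrapolated.  Negative spline excursions are clipped to 0.  Studies
#' with only 2 bins fall back to linear interpolation.
#'
#' @param dataset an [IncidenceDataset-class].
#' @param ageGrid numeric vector of strictly increasing grid ages (years).
#' @return named list: `age` (the grid), `incidence` (values with `NA`
#'   outside the study's range), `stratum`, `studyId`.
#' @examples
#' spec <- diseaseSpec("PD", nTrue = 6L, backgroundRiskU = 2e-8,
#'                     ageMin = 40, ageMax = 80, noiseSigma = 0)
#' d <- generateDataset(spec, 1L, seed = 1L)
#' tr <- splineInterpolate(d, 30:90)
#' range(which(!is.na(tr$incidence)))   # only ages inside 42.5..77.5
#' @export
splineInterpolate <- function(dataset, ageGrid) {
  stopifnot(is(dataset, "IncidenceDataset"))
  if (is.unsorted(ageGrid, strictly = TRUE))
    stop("'ageGrid' must be strictly increasing")
  b <- bins(dataset)
  mid <- (b$ageStart + b$ageEnd) / 2
  inside <- ageGrid >= min(mid) & ageGrid <= max(mid)
  values <- rep(NA_real_, length(ageGrid))
  if (!any(inside)) {
    warning("no overlap between age grid and study ", studyId(dataset),
            " (", min(mid), "-", max(mid), " years): all-missing trajectory")
  } else if (nrow(b) == 2L) {
    values[inside] <- stats::approx(mid, b$incidence,
                                    xout = ageGrid[inside])$y
  } else {
    f <- stats::splinefun(mid, b$incidence, method = "natural")
    values[inside] <- f(ageGrid[inside])
  }
  values <- pmax(values, 0)
  list(age = ageGrid, incidence = values,
       stratum = stratumLabel(dataset), studyId = studyId(dataset))
}

#' Build the harmonized diseases-by-ages incidence matrix
#'
#' Every study is spline-interpolated onto the common grid; the studies of
#' each stratum are then averaged age-by-age over those covering the age,
#' yielding the d x a matrix I whose element I(i, j) is the mean incidence
#' of stratum i at age j.  Ages covered by no study of a stratum are `NA`.
#' Rows are ordered by sorted stratum label, so the result is independent
#' of panel order.
#'
#' @param panel an [IncidencePanel-class].
#' @param ageGrid common grid ages (default integer ages 30--79).
#' @return an [IncidenceMatrix-class] with assays `"incidence"` and
#'   `"coverage"`.
#' @examples
#' p <- generatePanel(defaultPanelSpecs(), seed = 3L)
#' im <- buildIncidenceMatrix(p)
#' dim(im)
#' @export
buildIncidenceMatrix <- function(panel, ageGrid = 30:79) {
  if (!length(panel)) stop("empty panel")
  trajs <- lapply(panel, splineInterpolate, ageGrid = ageGrid)
  strata <- sort(unique(vapply(trajs, `[[`, character(1), "stratum")))
  inc <- matrix(NA_real_, length(strata), length(ageGrid),
                dimnames = list(strata, ageGrid))
  cov <- matrix(0L, length(strata), length(ageGrid),
                dimnames = list(strata, ageGrid))
  for (s in strata) {
    vals <- vapply(trajs[vapply(trajs, `[[`, character(1), "stratum") == s],
                   `[[`, numeric(length(ageGrid)), "incidence")
    vals <- matrix(vals, nrow = length(ageGrid))
    nCov <- rowSums(!is.na(vals))
    mean_ <- rowMeans(vals, na.rm = TRUE)
    mean_[nCov == 0L] <- NA_real_
    inc[s, ] <- mean_
    cov[s, ] <- nCov
  }
  parsed <- lapply(strata, parseStratumLabel)
  rd <- S4Vectors::DataFrame(
    stratum = strata,
    disease = vapply(parsed, `[[`, character(1), "diseaseCode"),
    sex = vapply(parsed, `[[`, character(1), "sex"),
    row.names = strata)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(incidence = inc, coverage = cov),
    rowData = rd,
    colData = S4Vectors::DataFrame(age = ageGrid,
                                   row.names = as.character(ageGrid)))
  new("IncidenceMatrix", se)
}

#' Per-study incidence profiles on the common grid
#'
#' Like [buildIncidenceMatrix()] but without averaging: one profile per
#' dataset, for per-dataset embeddings.
#'
#' @inheritParams buildIncidenceMatrix
#' @return numeric matrix (datasets x ages, `NA` outside coverage) with
#'   rownames `"<stratum>/<studyId>"`.
#' @export
studyProfiles <- function(panel, ageGrid = 30:79) {
  trajs <- lapply(panel, splineInterpolate, ageGrid = ageGrid)
  prof <- t(vapply(trajs, `[[`, numeric(length(ageGrid)), "incidence"))
  rownames(prof) <- vapply(trajs, function(tr)
    paste(tr$stratum, tr$studyId, sep = "/"), character(1))
  colnames(prof) <- ageGrid
  prof
}

#' Retain only grid columns covered by every profile
#'
#' @param profiles numeric matrix with possible `NA` cells (rows =
#'   profiles, columns = grid ages).
#' @return the complete-case column submatrix.
#' @export
completeColumns <- function(profiles) {
  keep <- colSums(is.na(profiles)) == 0L
  if (!any(keep))
    stop("no age-grid column is covered by every profile")
  profiles[, keep, drop = FALSE]
}

#' Write the incidence matrix with a coverage sidecar
#'
#' @param im an [IncidenceMatrix-class].
#' @param path CSV path for the incidence values (rows = strata, columns =
#'   ages); coverage counts go to `<path>.coverage.json`.
#' @return `path`, invisibly.
#' @export
writeIncidenceMatrix <- function(im, path) {
  utils::write.csv(as.data.frame(incidence(im)), path)
  jsonlite::write_json(
    list(age = ageGrid(im),
         coverage = apply(coverage(im), 1L, as.integer, simplify = FALSE)),
    paste0(path, ".coverage.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
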