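#' @include multistepModel.R
NULL

#' Onset age-range interval of one stratum
#'
#' The incidence age range spans from the start of the first bin with
#' nonzero incidence to the end of the last such bin, taking the union
#' over all the stratum's studies, after the same age-80 truncation rule
#' used by the model fit (bins with midpoints at or above 80 years are
#' dropped when at least 4 remain).  Bin edges — not midpoints — define
#' the interval, since the onset interval concerns coverage; set
#' `useMidpoints = TRUE` for the midpoint convention.
#'
#' @param datasets datasets of one stratum.
#' @param truncateAge,minPointsAfter truncation rule, as in
#'   [preparePoints()].
#' @param useMidpoints use bin midpoints instead of edges for the bounds.
#' @return list with `stratum`, `ageMin`, `ageMax`, `rangeWidth`,
#'   `truncated`.
#' @examples
#' spec <- diseaseSpec("HD", nTrue = 2L, backgroundRiskU = 6e-3,
#'                     ageMin = 15, ageMax = 80, noiseSigma = 0)
#' incidenceAgeRange(list(generateDataset(spec, 1L, seed = 1L)))
#' @export
incidenceAgeRange <- function(datasets, truncateAge = 80,
                              minPointsAfter = 4L, useMidpoints = FALSE) {
  datasets <- as.list(datasets)
  labels <- unique(vapply(datasets, stratumLabel, character(1)))
  if (length(labels) != 1L)
    stop("datasets span several strata: ", paste(labels, collapse = ", "))
  b <- do.call(rbind, lapply(datasets, bins))
  b <- b[b$incidence > 0, , drop = FALSE]
  if (!nrow(b)) stop("all-zero incidence for stratum ", labels)
  mid <- (b$ageStart + b$ageEnd) / 2
  young <- mid < truncateAge
  truncated <- FALSE
  if (any(!young) && sum(young) >= minPointsAfter) {
    b <- b[young, , drop = FALSE]
    mid <- mid[young]
    truncated <- TRUE
  }
  lo <- if (useMidpoints) min(mid) else min(b$ageStart)
  hi <- if (useMidpoints) max(mid) else max(b$ageEnd)
  list(stratum = labels, ageMin = lo, ageMax = hi, rangeWidth = hi - lo,
       truncated = truncated)
}

#' Years required per disease step
#'
#' The stratum's incidence age-range width divided by its step count: the
#' average number of years necessary for one step to occur.
#'
#' @param rangeWidth age-range width in years (>= 0).
#' @param nSteps step count (>= 1).
#' @return years per step.
#' @examples
#' yearsPerStep(65, 2L)   # 32.5 — a two-step disease spanning 65 years
#' @export
yearsPerStep <- function(rangeWidth, nSteps) {
  if (nSteps < 1L) stop("'nSteps' must be >= 1")
  if (rangeWidth < 0) stop("'rangeWidth' must be >= 0")
  rangeWidth / nSteps
}

#' Age-range and years-per-step summaries for a fitted panel
#'
#' @param panel an [IncidencePanel-class].
#' @param fits named list of [MultistepFit-class] from [fitPanel()].
#' @inheritParams incidenceAgeRange
#' @return `data.frame` with one row per stratum: `stratum`, `ageMin`,
#'   `ageMax`, `rangeWidth`, `nSteps`, `yearsPerStep`, `passesLinearity`.
#' @export
ageRangeSummaries <- function(panel, fits, truncateAge = 80,
                              minPointsAfter = 4L, useMidpoints = FALSE) {
  labels <- vapply(panel, stratumLabel, character(1))
  rows <- lapply(sort(unique(labels)), function(lab) {
    r <- incidenceAgeRange(as.list(panel)[labels == lab],
                           truncateAge = truncateAge,
                           minPointsAfter = minPointsAfter,
                           useMidpoints = useMidpoints)
    f <- fits[[lab]]
    if (is.null(f)) stop("no fit available for stratum ", lab)
    data.frame(stratum = lab, ageMin = r$ageMin, ageMax = r$ageMax,
               rangeWidth = r$rangeWidth, nSteps = nSteps(f),
               yearsPerStep = yearsPerStep(r$rangeWidth, nSteps(f)),
               passesLinearity = passesLinearity(f))
  })
  do.call(rbind, rows)
}

#' Regression of step count on incidence age range
#'
#' Ordinary least squares of the (integer) step count on the age-range
#' width, over the strata passing the linearity gate.  A negative slope
#' expresses the finding that a wider age range of incidence corresponds
#' to fewer steps required to trigger the disease.
#'
#' @param summaries `data.frame` from [ageRangeSummaries()].
#' @param gatedOnly keep only strata with `passesLinearity` (default).
#' @return list with `slope` (steps per year), `intercept` (steps),
#'   `rSquared` and `nStrata`.
#' @export
fitStepsVsRange <- function(summaries, gatedOnly = TRUE) {
  s <- summaries
  if (gatedOnly && "passesLinearity" %in% names(s))
    s <- s[s$passesLinearity, , drop = FALSE]
  if (nrow(s) < 3L)
    stop("need at least 3 gated strata for the steps-vs-range regression")
  if (stats::var(s$rangeWidth) == 0)
    stop("degenerate age-range variance")
  fit <- stats::lm(nSteps ~ rangeWidth, data = s)
  tss <- sum((s$nSteps - mean(s$nSteps))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(stats::residuals(fit)^2) / tss
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       rSquared = r2, nStrata = nrow(s))
}

#' Count diseases sharing each age bin
#'
#' The overall age axis (union of all onset intervals) is partitioned into
#' bins of `binWidth` years; a stratum counts toward a bin when its
#' interval `[ageMin, ageMax]` covers the whole bin.  The maximal-count
#' contiguous run of bins is reported as the age interval shared by the
#' most diseases.
#'
#' @param summaries `data.frame` from [ageRangeSummaries()] (or any table
#'   with `stratum`, `ageMin`, `ageMax`).
#' @param binWidth bin width in years (default 2).
#' @return list with `bins` (`data.frame`: `ageStart`, `ageEnd`, `count`)
#'   and `sharedInterval` (list `ageStart`, `ageEnd`, `count`): the
#'   maximal-count contiguous interval.
#' @examples
#' s <- data.frame(stratum = c("A", "B", "C"),
#'                 ageMin = c(50, 55, 60), ageMax = c(80, 75, 70))
#' sharedAgeBins(s)$sharedInterval   # 60-70 covered by all 3
#' @export
sharedAgeBins <- function(summaries, binWidth = 2) {
  if (binWidth <= 0) stop("'binWidth' must be > 0")
  lo <- floor(min(summaries$ageMin) / binWidth) * binWidth
  hi <- ceiling(max(summaries$ageMax) / binWidth) * binWidth
  starts <- seq(lo, hi - binWidth, by = binWidth)
  ends <- starts + binWidth
  count <- vapply(seq_along(starts), function(k)
    sum(summaries$ageMin <= starts[k] & summaries$ageMax >= ends[k]),
    integer(1))
  best <- max(count)
  inBest <- count == best
  runs <- rle(inBest)
  stopRun <- cumsum(runs$lengths)
  startRun <- stopRun - runs$lengths + 1L
  widest <- which(runs$values)[which.max(runs$lengths[runs$values])]
  shared <- list(ageStart = starts[startRun[widest]],
                 ageEnd = ends[stopRun[widest]], count = best)
  list(bins = data.frame(ageStart = starts, ageEnd = ends, count = count),
       sharedInterval = shared)
}
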