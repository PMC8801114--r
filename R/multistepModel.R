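#' @include incidenceIO.R
NULL

#' Pool a stratum's studies into log-log points
#'
#' Bins from all studies of one disease/sex stratum are pooled; the
#' representative age of each bin is its midpoint.  Zero-incidence bins
#' are dropped before the log transform.  Bins with midpoints at or above
#' `truncateAge` (80 years) are then removed, but only if at least
#' `minPointsAfter` (4) points remain afterwards; otherwise no truncation
#' is applied.
#'
#' @param datasets list (or [IncidencePanel-class]) of
#'   [IncidenceDataset-class] objects sharing one stratum label.
#' @param truncateAge ages at or above this are candidates for removal.
#' @param minPointsAfter minimum points that must survive truncation for
#'   it to be applied.
#' @return a [LogLogPoints-class] (log10 scale).
#' @examples
#' spec <- diseaseSpec("ALS", nTrue = 6L, backgroundRiskU = 1e-9,
#'                     ageMin = 45, ageMax = 80, noiseSigma = 0)
#' pts <- preparePoints(list(generateDataset(spec, 1L, seed = 1L)))
#' pts
#' @export
preparePoints <- function(datasets, truncateAge = 80, minPointsAfter = 4L) {
  datasets <- as.list(datasets)
  if (!length(datasets)) stop("no datasets supplied")
  labels <- unique(vapply(datasets, stratumLabel, character(1)))
  if (length(labels) != 1L)
    stop("datasets span several strata: ", paste(labels, collapse = ", "))
  mid <- unlist(lapply(datasets, function(d)
    (bins(d)$ageStart + bins(d)$ageEnd) / 2))
  inc <- unlist(lapply(datasets, function(d) bins(d)$incidence))
  src <- unlist(lapply(datasets, function(d)
    rep(studyId(d), nrow(bins(d)))))
  keep <- inc > 0
  mid <- mid[keep]; inc <- inc[keep]; src <- src[keep]
  if (any(mid <= 0)) stop("bin midpoints must be strictly positive")
  young <- mid < truncateAge
  truncated <- FALSE
  if (any(!young) && sum(young) >= minPointsAfter) {
    mid <- mid[young]; inc <- inc[young]; src <- src[young]
    truncated <- TRUE
  }
  if (length(mid) < 2L)
    stop("fewer than 2 usable points for stratum ", labels,
         ": multistep fit infeasible")
  ord <- order(mid)
  new("LogLogPoints", logAge = log10(mid[ord]),
      logIncidence = log10(inc[ord]), sourceIds = src[ord],
      truncated = truncated, stratum = labels)
}

#' Number of steps implied by a log-log slope
#'
#' The multistep model predicts incidence \eqn{i = u t^{n-1}}, so the
#' log-log regression slope estimates \eqn{m = n - 1} and the step count
#' is \eqn{n = m + 1}, rounded half-up to the nearest integer (slope 4.8
#' and 4.6 both map to six steps, as in the ALS literature), with a floor
#' of 1.
#'
#' @param slopeM regression slope; must exceed -1.
#' @return integer step count >= 1.
#' @examples
#' stepsFromSlope(4.8)   # 6
#' stepsFromSlope(0)     # 1 (flat incidence)
#' @export
stepsFromSlope <- function(slopeM) {
  if (!is.finite(slopeM) || slopeM <= -1)
    stop("slope must be > -1: no valid step count")
  max(1L, as.integer(floor(slopeM + 1 + 0.5)))
}

#' Background-risk parameters from the regression intercept
#'
#' With the intercept `c` on the natural-log scale, the product of the
#' per-step background risks is \eqn{u = e^c} and their geometric average
#' is \eqn{\mu(u) = u^{1/n}}.
#'
#' @param interceptC intercept on the natural-log scale.
#' @param nSteps step count (>= 1).
#' @return list with elements `u` and `mu`.
#' @examples
#' riskParameters(log(8), 3L)   # u = 8, mu = 2
#' @export
riskParameters <- function(interceptC, nSteps) {
  if (nSteps < 1L) stop("'nSteps' must be >= 1")
  u <- exp(interceptC)
  list(u = u, mu = u^(1 / nSteps))
}

#' Fit the multistep model to one stratum's points
#'
#' Ordinary least squares of log10 incidence on log10 age.  The slope is
#' base-invariant; the intercept is converted to natural-log scale before
#' computing \eqn{u = e^c}.  The linearity gate declares a stratum
#' consistent with the multistep model when the fit's r-squared reaches
#' `gateThreshold` and the slope is positive; non-monotone profiles (such
#' as MS) fail it and are excluded from step allocation downstream.
#'
#' @param points a [LogLogPoints-class].
#' @param gateThreshold r-squared threshold of the linearity gate.
#' @return a [MultistepFit-class].
#' @examples
#' t <- seq(47.5, 77.5, by = 5)
#' pts <- new("LogLogPoints", logAge = log10(t),
#'            logIncidence = log10(1e-9 * t^5),
#'            sourceIds = rep("X", length(t)), truncated = FALSE,
#'            stratum = "ALS")
#' fitMultistep(pts)   # slope 5 -> n = 6 steps
#' @export
fitMultistep <- function(points, gateThreshold = 0.8) {
  stopifnot(is(points, "LogLogPoints"))
  x <- points@logAge
  y <- points@logIncidence
  if (length(unique(x)) < 2L)
    stop("degenerate points: all ages identical, slope undefined")
  fit <- stats::lm(y ~ x)
  m <- unname(stats::coef(fit)[2L])
  c10 <- unname(stats::coef(fit)[1L])
  r2 <- if (length(x) == 2L) 1 else {
    tot <- sum((y - mean(y))^2)
    if (tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / tot
  }
  # strata with decreasing incidence (slope <= -1) have no valid step
  # count; floor at one step -- they necessarily fail the linearity gate
  n <- if (m > -1) stepsFromSlope(m) else 1L
  cNat <- c10 * log(10)
  rp <- riskParameters(cNat, n)
  new("MultistepFit", stratum = points@stratum, slopeM = m,
      interceptC10 = c10, interceptC = cNat, nSteps = n,
      backgroundRiskU = rp$u, geomMeanRiskMu = rp$mu,
      rSquared = min(max(r2, 0), 1), nPoints = length(x),
      truncated = points@truncated,
      passesLinearity = (r2 >= gateThreshold) && (m > 0),
      gateThreshold = gateThreshold)
}

#' Fit every stratum of a panel
#'
#' Groups the panel's datasets by stratum label, pools each stratum's
#' studies with [preparePoints()] and fits each with [fitMultistep()].
#'
#' @param panel an [IncidencePanel-class].
#' @inheritParams preparePoints
#' @inheritParams fitMultistep
#' @return named list of [MultistepFit-class], sorted by stratum label.
#' @export
fitPanel <- function(panel, truncateAge = 80, minPointsAfter = 4L,
                     gateThreshold = 0.8) {
  labels <- vapply(panel, stratumLabel, character(1))
  fits <- lapply(sort(unique(labels)), function(lab) {
    pts <- preparePoints(as.list(panel)[labels == lab],
                         truncateAge = truncateAge,
                         minPointsAfter = minPointsAfter)
    fitMultistep(pts, gateThreshold = gateThreshold)
  })
  names(fits) <- sort(unique(labels))
  fits
}

#' Tabulate multistep fits
#'
#' @param fits a list of [MultistepFit-class] (e.g. from [fitPanel()]).
#' @return `data.frame` with one row per stratum: label, slope m,
#'   intercept c (natural log), step count n, u, mu, r-squared, number of
#'   points, truncation flag and gate decision.
#' @export
fitTable <- function(fits) {
  do.call(rbind, lapply(fits, function(f) data.frame(
    stratum = f@stratum, slope_m = f@slopeM, intercept_c = f@interceptC,
    n_steps = f@nSteps, background_risk_u = f@backgroundRiskU,
    geom_mean_risk_mu = f@geomMeanRiskMu, r_squared = f@rSquared,
    n_points = f@nPoints, truncated = f@truncated,
    passes_linearity = f@passesLinearity, row.names = NULL)))
}
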