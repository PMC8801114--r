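#' @include ageRange.R
NULL

.asCompatMatrix <- function(compatibility, labels) {
  d <- length(labels)
  if (is.null(compatibility)) {
    m <- matrix(TRUE, d, d)
  } else if (is.matrix(compatibility)) {
    m <- compatibility
    stopifnot(identical(dim(m), c(d, d)))
  } else if (is.function(compatibility)) {
    m <- outer(labels, labels,
               Vectorize(function(a, b) isTRUE(compatibility(a, b))))
  } else stop("'compatibility' must be NULL, a matrix or a predicate")
  if (!isSymmetric(unname(m)))
    stop("compatibility must be symmetric")
  diag(m) <- TRUE
  dimnames(m) <- list(labels, labels)
  m
}

.isClique <- function(members, compat) {
  length(members) < 2L || all(compat[members, members])
}

# Chain objective: once a starting sharing set S is fixed, the optimal
# nested descent keeps every member while it has steps left and company,
# so each member's common steps are min(n_d, second-largest n in S).
.chainObjective <- function(n) {
  if (length(n) < 2L) return(0)
  sm <- sort(n, decreasing = TRUE)[2L]
  sum(pmin(n, sm))
}

#' Enumerate candidate shared-step combinations
#'
#' Builds the adjacency structure A of all combinations in which a step
#' might be shared by a set of diseases: for every step ordinal k, a
#' disease subset is feasible when every member has at least k steps
#' (preserving the ordinal number of each step) and all members are
#' pairwise compatible.  Columns are ordered by subset size descending,
#' then lexicographically by member labels.
#'
#' @param allocatable `data.frame` with columns `stratum` and `nSteps`
#'   (or a named integer vector of step counts).
#' @param compatibility `NULL` (all compatible), a symmetric logical
#'   matrix, or a symmetric predicate `function(labelA, labelB)`.
#' @return a [SharingMatrix-class].
#' @examples
#' sm <- buildSharingMatrix(c(HD = 2L, ALS = 6L, PD = 6L))
#' sm
#' @export
buildSharingMatrix <- function(allocatable, compatibility = NULL) {
  if (is.data.frame(allocatable)) {
    labels <- allocatable$stratum
    n <- as.integer(allocatable$nSteps)
  } else {
    labels <- names(allocatable)
    n <- as.integer(allocatable)
  }
  if (is.null(labels) || anyDuplicated(labels))
    stop("strata must carry unique labels")
  d <- length(labels)
  if (d > 15L)
    stop("subset enumeration is limited to 15 diseases")
  compat <- .asCompatMatrix(compatibility, labels)
  subsets <- list()
  for (size in seq(d, 1L)) {
    combos <- utils::combn(seq_len(d), size, simplify = FALSE)
    combos <- Filter(function(s) .isClique(s, compat), combos)
    key <- vapply(combos, function(s) paste(labels[s], collapse = ","),
                  character(1))
    subsets <- c(subsets, combos[order(key)])
  }
  maxOrd <- max(n)
  feasible <- vapply(subsets, function(s) seq_len(maxOrd) <= min(n[s]),
                     logical(maxOrd))
  feasible <- matrix(feasible, nrow = maxOrd)
  new("SharingMatrix", diseases = labels, nSteps = n, compatible = compat,
      subsets = subsets, feasible = feasible)
}

# Deterministic preference between candidate starting sets with equal
# objective: larger subset first, then the one holding the larger step
# counts, then lexicographic by member labels.
.preferSubset <- function(a, b, n, labels) {
  if (length(a) != length(b)) return(length(a) > length(b))
  na <- sort(n[a], decreasing = TRUE)
  nb <- sort(n[b], decreasing = TRUE)
  if (!identical(na, nb)) {
    i <- which(na != nb)[1L]
    return(na[i] > nb[i])
  }
  ka <- paste(sort(labels[a]), collapse = ",")
  kb <- paste(sort(labels[b]), collapse = ",")
  ka < kb
}

#' Allocate common and disease-specific steps
#'
#' Selects the nested chain of sharing sets that maximizes the total
#' number of shared steps under the two parsimony criteria: the ordinal
#' number of each step is preserved (a subset can share step k only when
#' every member has at least k steps) and the number of shared steps
#' between diseases is maximized.  Because any subset of a pairwise-
#' compatible set is itself compatible, fixing the starting set S forces
#' the rest of the chain (each member stays until its steps run out), so
#' the selection scores every maximal compatible clique with the
#' closed-form chain objective and keeps the best; this is exact, and
#' identical to taking the largest feasible subset per ordinal when all
#' diseases are mutually compatible.  A disease's common steps are the
#' largest ordinal at which it still shares with at least one other
#' disease; the remaining steps are specific.
#'
#' @param sharing a [SharingMatrix-class].
#' @return `data.frame` with columns `stratum`, `nSteps`, `commonSteps`,
#'   `specificSteps`, in input stratum order, carrying attributes
#'   `objective` (total shared steps) and `promoters` (`data.frame` of
#'   trunk ordinals with their sharing sets and the promoter disease each
#'   shared step is attributed to).
#' @examples
#' sm <- buildSharingMatrix(c(HD = 2L, ALS = 6L, PD = 6L))
#' allocateSteps(sm)   # HD shares 2, ALS and PD share all 6
#' @export
allocateSteps <- function(sharing) {
  stopifnot(is(sharing, "SharingMatrix"))
  labels <- sharing@diseases
  n <- sharing@nSteps
  compat <- sharing@compatible
  d <- length(labels)
  best <- integer(0)
  bestObj <- 0
  if (d >= 2L) {
    g <- igraph::graph_from_adjacency_matrix(
      compat & !diag(d), mode = "undirected")
    cliques <- igraph::max_cliques(g, min = 2L)
    for (cl in cliques) {
      s <- as.integer(cl)
      obj <- .chainObjective(n[s])
      if (obj > bestObj ||
          (obj == bestObj && length(best) &&
           .preferSubset(s, best, n, labels)) ||
          (obj == bestObj && obj > 0 && !length(best))) {
        best <- s
        bestObj <- obj
      }
    }
  }
  common <- integer(d)
  if (length(best) >= 2L) {
    sm <- sort(n[best], decreasing = TRUE)[2L]
    common[best] <- pmin(n[best], sm)
  }
  out <- data.frame(stratum = labels, nSteps = n, commonSteps = common,
                    specificSteps = n - common)
  trunkHeight <- if (length(best)) max(common) else 0L
  promoters <- if (trunkHeight > 0) {
    do.call(rbind, lapply(seq_len(trunkHeight), function(k) {
      members <- sort(labels[common >= k])
      data.frame(ordinal = k, members = paste(members, collapse = ","),
                 promoter = members[1L])
    }))
  } else data.frame(ordinal = integer(0), members = character(0),
                    promoter = character(0))
  attr(out, "objective") <- sum(common)
  attr(out, "promoters") <- promoters
  out
}

#' Exhaustive oracle for the step allocation
#'
#' Enumerates every nested sharing selection on a small instance (at most
#' 5 diseases, at most 13 steps each): each disease is assigned a chain
#' membership depth between 0 and its step count; the induced sharing
#' sets are automatically nested, and the selection is feasible when the
#' depth-positive diseases are pairwise compatible.  Returns an
#' allocation maximizing the total number of shared steps.  Intended as
#' an independent test oracle for [allocateSteps()].
#'
#' @inheritParams buildSharingMatrix
#' @return as [allocateSteps()], with attribute `objective`.
#' @export
bruteForceAllocate <- function(allocatable, compatibility = NULL) {
  if (is.data.frame(allocatable)) {
    labels <- allocatable$stratum
    n <- as.integer(allocatable$nSteps)
  } else {
    labels <- names(allocatable)
    n <- as.integer(allocatable)
  }
  d <- length(labels)
  if (d > 5L || any(n > 13L))
    stop("brute force is limited to <= 5 diseases with <= 13 steps")
  compat <- .asCompatMatrix(compatibility, labels)
  if (d == 1L) {
    out <- data.frame(stratum = labels, nSteps = n, commonSteps = 0L,
                      specificSteps = n)
    attr(out, "objective") <- 0
    return(out)
  }
  grid <- as.matrix(expand.grid(lapply(n, function(k) 0:k),
                                KEEP.OUT.ATTRS = FALSE))
  colnames(grid) <- labels
  # feasibility: the depth-positive set must be pairwise compatible
  keep <- rep(TRUE, nrow(grid))
  if (d >= 2L) {
    for (a in seq_len(d - 1L)) for (b in seq(a + 1L, d)) {
      if (!compat[a, b])
        keep <- keep & !(grid[, a] >= 1L & grid[, b] >= 1L)
    }
  }
  grid <- grid[keep, , drop = FALSE]
  cols <- lapply(seq_len(d), function(j) grid[, j])
  m1 <- do.call(pmax, cols)
  firstMax <- max.col(grid, ties.method = "first")
  masked <- grid
  masked[cbind(seq_len(nrow(grid)), firstMax)] <- -1L
  m2 <- do.call(pmax, lapply(seq_len(d), function(j) masked[, j]))
  common <- grid
  for (j in seq_len(d)) {
    other <- ifelse(firstMax == j, m2, m1)
    common[, j] <- pmin(grid[, j], other)
  }
  obj <- rowSums(common)
  bestRow <- which.max(obj)
  out <- data.frame(stratum = labels, nSteps = n,
                    commonSteps = as.integer(common[bestRow, ]),
                    specificSteps = n - as.integer(common[bestRow, ]))
  attr(out, "objective") <- unname(obj[bestRow])
  out
}

#' Tier of a disease by its step count
#'
#' Stem diseases have fewer than 3 steps, trunk-level diseases 5--7 steps
#' and crown diseases more than 7; counts of 3 or 4 fall between the bands
#' and are labelled `"unclassified"`.
#'
#' @param nSteps integer vector of step counts.
#' @return character vector of tiers.
#' @examples
#' classifyTiers(c(2, 6, 11))   # stem, trunk_level, crown
#' @export
classifyTiers <- function(nSteps) {
  ifelse(nSteps < 3, "stem",
         ifelse(nSteps >= 5 & nSteps <= 7, "trunk_level",
                ifelse(nSteps > 7, "crown", "unclassified")))
}

#' Assemble the extended genealogy tree
#'
#' Branch points are placed at each distinct common-step count; the trunk
#' width at a branch point is the mean years-per-step of all diseases
#' branching there (the width of a single-disease branch point is that
#' disease's own years/step).  Strata present in `summaries` but not in
#' `allocations` (those failing the linearity gate, such as the MS-like
#' control) are attached as reference leaves outside the trunk.  In
#' `sexMode = "split"` male branches render on the left side and female on
#' the right; pooled strata sit in the middle.
#'
#' @param allocations `data.frame` from [allocateSteps()].
#' @param summaries `data.frame` from [ageRangeSummaries()]; every
#'   allocated stratum must have a `yearsPerStep` entry.
#' @param sexMode `"pooled"` or `"split"`.
#' @return a [GenealogyTree-class].
#' @export
buildTree <- function(allocations, summaries, sexMode = c("pooled", "split")) {
  sexMode <- match.arg(sexMode)
  idx <- match(allocations$stratum, summaries$stratum)
  if (anyNA(idx))
    stop("missing years-per-step summary for: ",
         paste(allocations$stratum[is.na(idx)], collapse = ", "))
  yps <- summaries$yearsPerStep[idx]
  side <- if (sexMode == "split") {
    sex <- vapply(allocations$stratum,
                  function(l) parseStratumLabel(l)$sex, character(1))
    c(male = "left", female = "right", pooled = "center")[sex]
  } else rep("center", nrow(allocations))
  alloc <- data.frame(allocations[c("stratum", "nSteps", "commonSteps",
                                    "specificSteps")],
                      yearsPerStep = yps,
                      tier = classifyTiers(allocations$nSteps),
                      side = unname(side))
  heights <- sort(unique(alloc$commonSteps))
  bp <- do.call(rbind, lapply(heights, function(h) {
    who <- alloc$stratum[alloc$commonSteps == h]
    data.frame(height = h, diseases = paste(sort(who), collapse = ","),
               trunkWidth = mean(alloc$yearsPerStep[alloc$commonSteps == h]))
  }))
  if (is.null(bp))
    bp <- data.frame(height = integer(0), diseases = character(0),
                     trunkWidth = numeric(0))
  trunkHeight <- max(c(alloc$commonSteps, 0L))
  trunk <- if (trunkHeight > 0) {
    do.call(rbind, lapply(seq_len(trunkHeight), function(k)
      data.frame(ordinal = k,
                 members = paste(sort(alloc$stratum[alloc$commonSteps >= k]),
                                 collapse = ","))))
  } else data.frame(ordinal = integer(0), members = character(0))
  refs <- setdiff(summaries$stratum, alloc$stratum)
  new("GenealogyTree", trunk = trunk, branchPoints = bp,
      allocations = alloc, referenceLeaves = refs, sexMode = sexMode)
}

#' Serialize a genealogy tree to JSON
#'
#' @param tree a [GenealogyTree-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTreeJSON <- function(tree, path) {
  bp <- branchPoints(tree)
  obj <- list(
    sex_mode = tree@sexMode,
    trunk = lapply(seq_len(nrow(tree@trunk)), function(i) list(
      ordinal = tree@trunk$ordinal[i],
      members = strsplit(tree@trunk$members[i], ",")[[1]])),
    branch_points = lapply(seq_len(nrow(bp)), function(i) list(
      height = bp$height[i],
      diseases = strsplit(bp$diseases[i], ",")[[1]],
      trunk_width_years_per_step = bp$trunkWidth[i])),
    allocations = allocations(tree),
    reference_leaves = referenceLeaves(tree))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}

#' Draw the extended genealogy tree
#'
#' Schematic rendering: the trunk rises along the step ordinate with its
#' width proportional to the years/step at each branch point; branches
#' carry each disease's specific steps, split left/right by sex when the
#' tree was built in split mode; reference leaves are drawn apart from
#' the trunk.
#'
#' @param x a [GenealogyTree-class].
#' @param y ignored.
#' @param ... passed to [graphics::plot()].
#' @export
setMethod("plot", signature(x = "GenealogyTree", y = "missing"),
  function(x, y, ...) {
    a <- allocations(x)
    bp <- branchPoints(x)
    maxH <- max(c(a$nSteps, 1L))
    wScale <- if (nrow(bp) && max(bp$trunkWidth) > 0)
      4 / max(bp$trunkWidth) else 1
    graphics::plot(NA, xlim = c(-8, 8 + 3 * length(referenceLeaves(x))),
                   ylim = c(0, maxH + 1), xlab = "years/step (trunk width)",
                   ylab = "steps", main = "Extended genealogy tree", ...)
    prev <- 0
    for (i in seq_len(nrow(bp))) {
      w <- bp$trunkWidth[i] * wScale / 2
      graphics::rect(-w, prev, w, bp$height[i], col = "tan", border = "tan4")
      prev <- bp$height[i]
    }
    for (i in seq_len(nrow(a))) {
      dir <- switch(a$side[i], left = -1, right = 1, 0)
      if (dir == 0) dir <- if (i %% 2) -1 else 1
      x0 <- 0; y0 <- a$commonSteps[i]
      x1 <- dir * (2 + 4 * (i %% 3)); y1 <- a$nSteps[i]
      graphics::segments(x0, y0, x1, y1, col = "forestgreen", lwd = 2)
      graphics::text(x1, y1, a$stratum[i], pos = 3, cex = 0.7)
    }
    for (j in seq_along(referenceLeaves(x))) {
      xr <- 8 + 3 * j - 1.5
      graphics::segments(xr, 0, xr, 1, col = "grey50", lwd = 2, lty = 2)
      graphics::text(xr, 1, referenceLeaves(x)[j], pos = 3, cex = 0.7,
                     col = "grey30")
    }
    invisible(x)
  })
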