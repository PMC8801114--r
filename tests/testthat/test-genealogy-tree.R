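test_that("the sharing matrix enforces the ordinal-number constraint", {
  sm <- buildSharingMatrix(c(HD = 2L, ALS = 6L))
  expect_s4_class(sm, "SharingMatrix")
  pair <- which(vapply(sm@subsets, length, integer(1)) == 2L)
  expect_length(pair, 1L)
  expect_true(all(sm@feasible[1:2, pair]))
  expect_false(any(sm@feasible[3:6, pair]))
  # singletons: each feasible up to its own step count
  for (j in which(vapply(sm@subsets, length, integer(1)) == 1L)) {
    n <- sm@nSteps[sm@subsets[[j]]]
    expect_equal(sum(sm@feasible[, j]), n)
  }
})

test_that("feasibility flags agree with direct enumeration", {
  n <- c(A = 2L, B = 6L, C = 6L)
  compat <- matrix(TRUE, 3, 3); compat[1, 3] <- compat[3, 1] <- FALSE
  sm <- buildSharingMatrix(n, compat)
  # enumerate independently: all subsets, all ordinals
  labels <- names(n)
  for (ord in 1:6) {
    for (j in seq_along(sm@subsets)) {
      s <- sm@subsets[[j]]
      ok <- all(n[s] >= ord)
      expect_identical(sm@feasible[ord, j], ok)
    }
    # incompatible pairs never appear in any candidate subset
    expect_false(any(vapply(sm@subsets, function(s)
      all(c(1L, 3L) %in% s), logical(1))))
  }
  # columns ordered by size descending, then lexicographically
  sizes <- vapply(sm@subsets, length, integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("allocation shares the whole chain where ordinals permit", {
  sm <- buildSharingMatrix(c(HD = 2L, ALS = 6L, PD = 6L))
  alloc <- allocateSteps(sm)
  expect_equal(alloc$commonSteps, c(2L, 6L, 6L))
  expect_equal(alloc$specificSteps, c(0L, 0L, 0L))
  expect_equal(attr(alloc, "objective"), 14)
  # conservation
  expect_true(all(alloc$commonSteps + alloc$specificSteps == alloc$nSteps))
  # promoter bookkeeping: one promoter per trunk ordinal, first in order
  pr <- attr(alloc, "promoters")
  expect_identical(nrow(pr), 6L)
  expect_identical(pr$promoter[1L], "ALS")

  single <- allocateSteps(buildSharingMatrix(c(AD = 11L)))
  expect_equal(single$commonSteps, 0L)
  expect_equal(single$specificSteps, 11L)
})

test_that("nestedness: sharing sets form a decreasing chain", {
  set.seed(99)
  for (rep in 1:10) {
    d <- sample(2:6, 1)
    n <- setNames(sample(1:13, d, replace = TRUE), LETTERS[1:d])
    compat <- matrix(TRUE, d, d)
    if (d > 2 && runif(1) < 0.5) {
      ij <- sample(d, 2)
      compat[ij[1], ij[2]] <- compat[ij[2], ij[1]] <- FALSE
    }
    alloc <- allocateSteps(buildSharingMatrix(n, compat))
    pr <- attr(alloc, "promoters")
    if (nrow(pr) > 1L) {
      memberSets <- lapply(strsplit(pr$members, ","), sort)
      for (k in 2:nrow(pr))
        expect_true(all(memberSets[[k]] %in% memberSets[[k - 1]]))
    }
    expect_true(all(alloc$commonSteps + alloc$specificSteps == alloc$nSteps))
  }
})

test_that("allocation matches the exhaustive oracle", {
  # deterministic spot checks
  a1 <- allocateSteps(buildSharingMatrix(c(A = 2L, B = 6L, C = 6L)))
  b1 <- bruteForceAllocate(c(A = 2L, B = 6L, C = 6L))
  expect_equal(attr(a1, "objective"), attr(b1, "objective"))

  compat <- matrix(TRUE, 4, 4); compat[2, 4] <- compat[4, 2] <- FALSE
  n4 <- c(A = 3L, B = 7L, C = 5L, D = 5L)
  a2 <- allocateSteps(buildSharingMatrix(n4, compat))
  b2 <- bruteForceAllocate(n4, compat)
  expect_equal(attr(a2, "objective"), attr(b2, "objective"))

  # the greedy-by-size trap: a large low-step clique must not beat a
  # smaller high-step pair
  compat5 <- matrix(FALSE, 5, 5); diag(compat5) <- TRUE
  compat5[1:3, 1:3] <- TRUE
  compat5[4, 5] <- compat5[5, 4] <- TRUE
  n5 <- c(A = 2L, B = 2L, C = 2L, D = 13L, E = 13L)
  a3 <- allocateSteps(buildSharingMatrix(n5, compat5))
  b3 <- bruteForceAllocate(n5, compat5)
  expect_equal(attr(a3, "objective"), attr(b3, "objective"))
  expect_equal(attr(a3, "objective"), 26)

  expect_equal(attr(bruteForceAllocate(c(A = 5L)), "objective"), 0)
  expect_error(bruteForceAllocate(setNames(rep(2L, 6), LETTERS[1:6])),
               "limited")
})

test_that("random instances agree with the oracle (50 draws)", {
  set.seed(7041)
  for (rep in 1:50) {
    d <- sample(2:5, 1)
    n <- setNames(sample(1:13, d, replace = TRUE), LETTERS[1:d])
    compat <- matrix(TRUE, d, d)
    for (a in seq_len(d - 1)) for (b in seq(a + 1, d))
      if (runif(1) < 0.25) compat[a, b] <- compat[b, a] <- FALSE
    alloc <- allocateSteps(buildSharingMatrix(n, compat))
    oracle <- bruteForceAllocate(n, compat)
    expect_equal(attr(alloc, "objective"), attr(oracle, "objective"))
    expect_true(all(alloc$commonSteps + alloc$specificSteps == alloc$nSteps))
  }
})

test_that("tiers follow the published step-count bands", {
  expect_identical(classifyTiers(2L), "stem")
  expect_identical(classifyTiers(6L), "trunk_level")
  expect_identical(classifyTiers(11L), "crown")
  expect_identical(classifyTiers(c(1, 2, 3, 4, 5, 7, 8)),
                   c("stem", "stem", "unclassified", "unclassified",
                     "trunk_level", "trunk_level", "crown"))
})

test_that("trunk widths average the years/step of co-branching diseases", {
  alloc <- data.frame(stratum = c("A", "B", "C"),
                      nSteps = c(6L, 6L, 9L),
                      commonSteps = c(6L, 6L, 9L),
                      specificSteps = c(0L, 0L, 0L))
  summ <- data.frame(stratum = c("A", "B", "C", "MS"),
                     yearsPerStep = c(2, 4, 7, 60))
  tree <- buildTree(alloc, summ)
  bp <- branchPoints(tree)
  expect_equal(bp$trunkWidth[bp$height == 6], 3, tolerance = 1e-12)
  expect_identical(referenceLeaves(tree), "MS")
  # single-disease branch point keeps that disease's own width
  tree2 <- buildTree(alloc[3, ], summ)
  expect_equal(branchPoints(tree2)$trunkWidth, 7, tolerance = 1e-12)

  expect_error(buildTree(alloc, summ[1:2, ]), "missing years-per-step")

  split <- buildTree(data.frame(stratum = c("ADm", "ADf"),
                                nSteps = c(11L, 13L),
                                commonSteps = c(11L, 11L),
                                specificSteps = c(0L, 2L)),
                     data.frame(stratum = c("ADm", "ADf"),
                                yearsPerStep = c(2.3, 1.5)),
                     sexMode = "split")
  expect_identical(allocations(split)$side, c("left", "right"))
})

test_that("the default panel's tree matches its designed sharing", {
  res <- defaultRun()
  tree <- res$tree
  a <- allocations(tree)
  # all gated diseases share fully up to the second-largest step count
  expect_identical(referenceLeaves(tree), "MS")
  secondMax <- sort(a$nSteps, decreasing = TRUE)[2L]
  expect_equal(a$commonSteps, pmin(a$nSteps, secondMax))
  expect_true(all(a$commonSteps + a$specificSteps == a$nSteps))
  bp <- branchPoints(tree)
  for (i in seq_len(nrow(bp))) {
    who <- strsplit(bp$diseases[i], ",")[[1]]
    expect_equal(bp$trunkWidth[i],
                 mean(a$yearsPerStep[a$stratum %in% who]),
                 tolerance = 1e-12)
  }
})
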