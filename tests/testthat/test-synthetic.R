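test_that("block correlation construction handles trivial specs exactly", {
  # zero correlation everywhere -> identity
  spec0 <- list(list(within = rep(0, 2), between = matrix(0, 2, 2),
                     description = "null"))
  a <- buildStateCovariances(c(3L, 2L), spec0)
  expect_equal(archetypeCovariance(a[[1]]), diag(5))

  # a single correlated block of size 2 embedded in identity
  spec1 <- list(list(within = c(0.5, 0), between = matrix(0, 2, 2),
                     description = "one block"))
  S <- archetypeCovariance(buildStateCovariances(c(2L, 3L), spec1)[[1]])
  expect_equal(S[1:2, 1:2], matrix(c(1, 0.5, 0.5, 1), 2))
  expect_equal(S[3:5, 3:5], diag(3))
  expect_equal(S[1:2, 3:5], matrix(0, 2, 3))
})

test_that("default archetypes are positive definite with the expected density ordering", {
  arch <- buildStateCovariances()
  expect_length(arch, 4)
  for (a in arch) {
    S <- archetypeCovariance(a)
    expect_equal(dim(S), c(37, 37))
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
    expect_equal(diag(S), rep(1, 37))
  }
  offMean <- vapply(arch, function(a) {
    S <- archetypeCovariance(a)
    mean(abs(S[upper.tri(S)]))
  }, numeric(1))
  # the highly connected state II is denser than the sparse state III
  expect_gt(offMean[2], offMean[3])
})

test_that("correlation levels outside (-1, 1) and bad partitions are rejected", {
  bad <- list(list(within = rep(1.2, 2), between = matrix(0, 2, 2)))
  expect_error(buildStateCovariances(c(2L, 2L), bad), "correlation levels")
  spec <- list(list(within = rep(0, 2), between = matrix(0, 2, 2)))
  # block sizes not summing to the component count of the spec caller
  expect_error(
    makeCohort(cohortConfig(nSubjectsPerGroup = c(2, 2), nComponents = 5L,
                            networkBlockSizes = c(2L, 2L))),
    "sum")
})

test_that("lazy transition construction hits the requested stationary law", {
  occ <- c(0.1345, 0.1903, 0.4870, 0.1882)
  P <- transitionMatrixFromOccupancy(occ, q = c(0.1, 0.1, 0.07, 0.1))
  expect_equal(rowSums(P), rep(1, 4))
  expect_equal(stationaryDistribution(P), occ / sum(occ), tolerance = 1e-10)
})

test_that("an absorbing chain freezes the state sequence", {
  arch <- buildStateCovariances(c(1L, 1L), list(
    list(within = c(0, 0), between = matrix(0, 2, 2)),
    list(within = c(0, 0), between = matrix(0.3, 2, 2))))
  s <- simulateSubject(diag(2), arch, 50, noiseSd = 0, seed = 3)
  expect_length(unique(s$states), 1L)
})

test_that("chain occupancy converges to the stationary distribution", {
  # analytic stationary law of [[.9,.1],[.2,.8]] is (2/3, 1/3)
  P <- matrix(c(0.9, 0.2, 0.1, 0.8), 2, 2)
  expect_equal(stationaryDistribution(P), c(2 / 3, 1 / 3), tolerance = 1e-12)
  arch <- buildStateCovariances(c(1L, 1L), list(
    list(within = c(0, 0), between = matrix(0, 2, 2)),
    list(within = c(0, 0), between = matrix(0.3, 2, 2))))
  s <- simulateSubject(P, arch, 20000, noiseSd = 0, seed = 11)
  expect_lt(abs(mean(s$states == 1) - 2 / 3), 0.02)
})

test_that("occupancy of the planted four-state chain converges at long horizons", {
  P <- defaultTransitionMatrices()$AD
  s <- chainSequences(P, 1, 1e5, seed = 7)
  emp <- tabulate(s[1, ], 4) / ncol(s)
  expect_lt(max(abs(emp - stationaryDistribution(P))), 0.02)
})

test_that("single-state emissions reproduce the archetype correlation", {
  spec <- list(list(within = rep(0, 4),
                    between = matrix(0.4, 4, 4), description = "x"))
  arch <- buildStateCovariances(rep(1L, 4), spec)
  s <- simulateSubject(matrix(1), arch, 20000, noiseSd = 0, seed = 5)
  emp <- cor(s$timecourse)
  expect_lt(max(abs(emp - archetypeCovariance(arch[[1]]))), 0.05)
})

test_that("within-state correlation error shrinks with sample size", {
  spec <- list(list(within = rep(0, 4),
                    between = matrix(0.4, 4, 4), description = "x"))
  arch <- buildStateCovariances(rep(1L, 4), spec)
  S0 <- archetypeCovariance(arch[[1]])
  err <- vapply(c(500, 5000, 50000), function(T) {
    s <- simulateSubject(matrix(1), arch, T, noiseSd = 0, seed = 9)
    norm(cor(s$timecourse) - S0, "F")
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("subject simulation validates its inputs", {
  arch <- buildStateCovariances(c(1L, 1L), list(
    list(within = c(0, 0), between = matrix(0, 2, 2))))
  expect_error(simulateSubject(matrix(1), list(), 100), "archetype")
  expect_error(simulateSubject(matrix(1), arch, 1), "nTimepoints")
})

test_that("cohort generation is deterministic and correctly sized", {
  c1 <- tinyCohort(c(3, 2), seed = 21)
  c2 <- tinyCohort(c(3, 2), seed = 21)
  expect_identical(c1$timecourses@timecourses, c2$timecourses@timecourses)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(stateSequences(c1$truth), stateSequences(c2$truth))

  expect_equal(nrow(c1$manifest), 5)
  expect_length(timecourses(c1$timecourses), 5)
  expect_equal(c1$manifest$group, c(rep("HC", 3), rep("AD", 2)))

  c3 <- tinyCohort(c(3, 2), seed = 22)
  expect_false(identical(c1$timecourses@timecourses,
                         c3$timecourses@timecourses))
})

test_that("planted group chains differ in the documented directions", {
  tm <- defaultTransitionMatrices()
  piHC <- stationaryDistribution(tm$HC)
  piAD <- stationaryDistribution(tm$AD)
  # AD-like chain over-occupies the sparse state III ...
  expect_gt(piAD[3], piHC[3])
  # ... and under-occupies the strongly connected state IV
  expect_lt(piAD[4], piHC[4])
  # persistence (self-transition) follows the same ordering
  expect_gt(tm$AD[3, 3], tm$HC[3, 3])
  expect_lt(tm$AD[4, 4], tm$HC[4, 4])
})

test_that("clinical scores follow the planted linear model", {
  co <- tinyCohort(c(4, 4), seed = 31)
  # zero weights, zero noise -> intercept everywhere
  s0 <- attachClinicalScores(co$truth, coefficients = rep(0, 4),
                             noiseSd = 0, intercept = 2.5, seed = 1)
  expect_equal(unname(s0$scores), rep(2.5, 8))
  # pure weight on state III, zero noise -> exact linear dependence
  s1 <- attachClinicalScores(co$truth, coefficients = c(0, 0, -10, 0),
                             noiseSd = 0, seed = 1)
  occ3 <- trueOccupancy(co$truth)[, 3]
  expect_equal(cor(s1$scores, occ3), -1)
  expect_equal(s1$truth@scoreModel$weights, c(0, 0, -10, 0))
})

test_that("true occupancy rows are proper distributions", {
  co <- tinyCohort(c(3, 3), seed = 41)
  occ <- trueOccupancy(co$truth)
  expect_equal(unname(rowSums(occ)), rep(1, 6), tolerance = 1e-12)
  expect_true(all(occ >= 0))
})

test_that("cohort round-trips through the on-disk layout", {
  co <- tinyCohort(c(2, 2), seed = 51)
  dir <- tempfile("cohort")
  writeCohort(co, dir)
  back <- readCohort(dir)
  expect_equal(back$timecourses@timecourses, co$timecourses@timecourses,
               tolerance = 1e-12)
  expect_equal(back$manifest$subject_id, co$manifest$subject_id)
  expect_equal(stateSequences(back$truth), stateSequences(co$truth))
  expect_equal(trSeconds(back$timecourses), trSeconds(co$timecourses))
  # a manifest subject without a file is reported by name
  file.remove(file.path(dir, "HC002.tsv"))
  expect_error(readCohort(dir), "HC002")
})
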