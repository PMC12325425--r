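test_that("Mann-Whitney z handles symmetric and extreme cases", {
  x <- c(1, 2, 3, 4)
  res <- mannWhitneyZ(x, x)
  expect_equal(res$z, 0)
  expect_equal(res$p, 1)
  # complete separation on tiny samples: U = 0, exact p = 1/3
  res2 <- mannWhitneyZ(c(1, 2), c(3, 4))
  expect_equal(res2$U, 0)
  expect_equal(res2$pExact, 1 / 3)
  expect_lt(res2$p, 1)   # normal approximation reported alongside
  # fully tied data degenerates to z = 0, p = 1
  res3 <- mannWhitneyZ(rep(1, 5), rep(1, 7))
  expect_equal(res3$z, 0)
  expect_equal(res3$p, 1)
})

test_that("Mann-Whitney agrees with the exact enumeration for all small sizes", {
  set.seed(33)
  for (n1 in 1:4) for (n2 in 1:4) {
    if (n1 + n2 < 3) next
    x <- rnorm(n1)
    y <- rnorm(n2)
    res <- mannWhitneyZ(x, y)
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = TRUE,
                                              correct = FALSE))
    expect_equal(res$U, unname(wt$statistic))
    expect_equal(res$pExact, wt$p.value, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney type-I error is calibrated at moderate n", {
  set.seed(34)
  rejections <- replicate(2000, {
    mannWhitneyZ(rnorm(30), rnorm(30), exactMax = 0)$p < 0.05
  })
  expect_gte(mean(rejections), 0.035)
  expect_lte(mean(rejections), 0.065)
})

test_that("chi-square on counts matches hand computations", {
  # demographic sex table: 48/52 vs 28/41
  res <- chiSquareCounts(matrix(c(48, 28, 52, 41), 2, 2, byrow = FALSE))
  expect_equal(round(res$chisq, 2), 0.91)
  expect_equal(res$df, 1)
  expect_equal(chiSquareCounts(matrix(10, 2, 2))$chisq, 0)
  # all expected counts 15 -> chi-square = 4 * 25/15 = 20/3
  res3 <- chiSquareCounts(matrix(c(10, 20, 20, 10), 2, 2))
  expect_equal(res3$chisq, 20 / 3, tolerance = 1e-12)
  expect_error(chiSquareCounts(matrix(c(0, 0, 5, 5), 2, 2)), "margin")
})

test_that("summary t-tests reproduce the demographic-table values", {
  # age row: 65.37 +/- 9.56 (n=100) vs 63.45 +/- 7.33 (n=69), Welch
  res <- tTestFromSummary(65.37, 9.56, 100, 63.45, 7.33, 69)
  expect_equal(round(res$t, 2), 1.48)
  expect_gt(res$p, 0.05)
  expect_equal(tTestFromSummary(5, 2, 30, 5, 2, 30)$t, 0)
  # pooled closed form: se = sqrt(2/10), t = 1/se
  resP <- tTestFromSummary(1, 1, 10, 0, 1, 10, variant = "pooled")
  expect_equal(resP$t, 1 / sqrt(2 / 10), tolerance = 1e-10)
  expect_equal(resP$df, 18)
  # degenerate zero-variance identical groups
  expect_equal(tTestFromSummary(3, 0, 10, 3, 0, 10)$t, 0)
})

test_that("subject state connectivity averages only the state's windows", {
  idx <- edgeIndex(4)
  Z <- matrix(rnorm(10 * 6), 10, 6)
  wfc <- new("WindowedFC", subjectId = "a", zEdges = Z, edgeIndex = idx)
  labs <- c(rep(1L, 7), 2L, 1L, 1L)
  expect_equal(subjectStateFc(wfc, rep(1L, 10), 1), colMeans(Z))
  expect_null(subjectStateFc(wfc, rep(1L, 10), 2))
  expect_equal(subjectStateFc(wfc, labs, 2), Z[8, ])
})

test_that("per-state subject matrices sit closest to their own archetype", {
  co <- makeCohort(validationCohortConfig(c(4, 4), seed = 55),
                   archetypeSpec = validationArchetypeSpec())
  wfc <- computeCohortDfnc(co$timecourses)
  archZ <- archetypeZ(truthArchetypes(co$truth))
  hits <- 0; total <- 0
  for (id in subjectIds(co$timecourses)) {
    tru <- stateSequences(co$truth)[[id]]
    # window-level truth = majority latent state inside the window
    wl <- vapply(seq_len(185), function(p)
      which.max(tabulate(tru[p:(p + 21)], 4)), integer(1))
    for (s in unique(wl)) {
      if (sum(wl == s) < 10) next
      v <- subjectStateFc(wfc[[id]], wl, s)
      d <- colSums((archZ - v)^2)
      # compare on centred patterns: shrinkage biases the magnitude
      dc <- apply(archZ, 2, function(a) -cor(a, v))
      hits <- hits + (which.min(dc) == s)
      total <- total + 1
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("edgewise tests control errors and find planted shifts", {
  set.seed(35)
  # identical groups: no significant edges
  X <- matrix(rnorm(20 * 100, sd = 0.5), 20, 100)
  same <- edgewiseStateTtests(rbind(X, X), rep(c("HC", "AD"), each = 20))
  expect_equal(sum(same$significant), 0)
  expect_equal(nrow(same), 100)
  expect_true(all(same$q >= same$p))

  # planted +0.5 z shift on 10 designated edges, n = 40/40
  planted <- 1:10
  recovered <- c(); falsePos <- c()
  for (r in 1:30) {
    A <- matrix(rnorm(40 * 100, sd = 0.5), 40, 100)
    B <- matrix(rnorm(40 * 100, sd = 0.5), 40, 100)
    B[, planted] <- B[, planted] + 0.5
    res <- edgewiseStateTtests(rbind(A, B), rep(c("HC", "AD"), each = 40))
    recovered <- c(recovered, sum(res$significant[planted]))
    falsePos <- c(falsePos, sum(res$significant[-planted]))
  }
  expect_gte(mean(recovered), 8)
  expect_lte(mean(falsePos), 2)
})

test_that("edgewise tests on exchangeable groups control the FDR", {
  set.seed(36)
  fdrHat <- replicate(200, {
    X <- matrix(rnorm(30 * 80), 30, 80)
    res <- edgewiseStateTtests(X, rep(c("HC", "AD"), 15))
    nd <- sum(res$significant)
    if (nd == 0) 0 else 1  # all discoveries on a null are false
  })
  # P(any false discovery) <= nominal FDR level on a global null
  expect_lte(mean(fdrHat), 0.075)
})

test_that("BH step-up matches hand-worked examples and dominates Bonferroni", {
  res <- bhFdr(c(0.01, 0.02, 0.04), 0.05)
  expect_true(all(res$rejected))             # p(3) = 0.04 <= 3/3 * 0.05
  expect_equal(res$qvalues, c(0.03, 0.03, 0.04))
  expect_true(bhFdr(0.04, 0.05)$rejected)
  resNull <- bhFdr(rep(1, 5), 0.05)
  expect_false(any(resNull$rejected))
  expect_equal(resNull$qvalues, rep(1, 5))

  set.seed(37)
  for (i in 1:20) {
    p <- runif(50)^2
    bh <- bhFdr(p, 0.05)
    bonf <- p <= 0.05 / length(p)
    expect_true(all(bh$rejected[bonf]))      # BH rejects a superset
    ord <- order(p)
    expect_true(all(diff(bh$qvalues[ord]) >= -1e-12))  # monotone in rank
  }
})

test_that("partial correlation residualises correctly", {
  set.seed(38)
  x <- rnorm(50)
  y <- 2 * x
  expect_equal(partialCorrelation(x, y)$r, 1)
  # no covariates equals plain Pearson
  y2 <- x + rnorm(50)
  expect_equal(partialCorrelation(x, y2)$r, cor(x, y2))
  # conditioning on the common driver removes the association
  z <- rnorm(50)
  a <- z + rnorm(50, sd = 0.1)
  b <- z + rnorm(50, sd = 0.1)
  raw <- partialCorrelation(a, b)$r
  adj <- partialCorrelation(a, b, cbind(z))$r
  expect_gt(raw, 0.9)
  expect_lt(abs(adj), 0.4)
  # covariates identical to x leave zero residual variance
  expect_error(partialCorrelation(x, y2, cbind(x)), "residual variance")
  # duplicated covariate columns are rank deficient
  expect_error(partialCorrelation(x, y2, cbind(z, z)), "rank")
})

test_that("planted score-occupancy association is recovered reliably", {
  # 200 cohort replicates: the planted negative weight on state-III
  # occupancy must surface as a significant negative partial r at n=100
  hits <- 0
  for (r in 1:200) {
    co <- tinyCohort(c(2, 100), seed = 4000 + r)
    ad <- co$manifest[co$manifest$group == "AD", ]
    occ3 <- trueOccupancy(co$truth)[ad$subject_id, 3]
    covars <- cbind(ad$age, as.numeric(factor(ad$sex, c("F", "M"))),
                    ad$education)
    res <- partialCorrelation(occ3, ad$score_memory, covars)
    hits <- hits + (res$r < 0 && res$p < 0.05)
  }
  expect_gte(hits / 200, 0.9)
})

test_that("state occupancy chi-square behaves on pooled window counts", {
  labsEqual <- list(a = rep(1:4, 25), b = rep(1:4, 25))
  m <- modelFromLabels(labsEqual, 4)
  res <- stateOccupancyChisq(m, c(a = "HC", b = "AD"))
  expect_equal(res$chisq, 0)
  expect_equal(res$df, 3)

  # proportional tables also give zero
  labsProp <- list(a = rep(1:4, times = c(100, 100, 100, 100)),
                   b = rep(1:4, times = c(50, 50, 50, 50)))
  m2 <- modelFromLabels(labsProp, 4)
  expect_equal(stateOccupancyChisq(m2, c(a = "HC", b = "AD"))$chisq, 0)

  # planted differing chains separate reliably
  tm <- defaultTransitionMatrices()
  hits <- 0
  for (r in 1:40) {
    sHC <- chainSequences(tm$HC, 40, 185, seed = 6000 + r)
    sAD <- chainSequences(tm$AD, 40, 185, seed = 7000 + r)
    labs <- c(lapply(seq_len(40), function(i) sHC[i, ]),
              lapply(seq_len(40), function(i) sAD[i, ]))
    names(labs) <- c(sprintf("h%02d", 1:40), sprintf("a%02d", 1:40))
    groups <- stats::setNames(rep(c("HC", "AD"), each = 40), names(labs))
    m3 <- modelFromLabels(labs, 4)
    hits <- hits + (stateOccupancyChisq(m3, groups)$p < 0.05)
  }
  expect_gte(hits / 40, 0.9)
})
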