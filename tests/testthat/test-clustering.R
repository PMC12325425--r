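test_that("single-cluster k-means reduces to the column mean", {
  set.seed(18)
  X <- matrix(rnorm(200), 40, 5)
  m <- kmeansFit(X, 1, nRestarts = 3, seed = 1)
  expect_equal(as.numeric(stateCentroids(m)), colMeans(X))
  expect_equal(stateInertia(m), sum(sweep(X, 2, colMeans(X))^2))
})

test_that("well-separated planted clouds are recovered exactly", {
  set.seed(19)
  X <- rbind(matrix(rnorm(300, sd = 0.1), 60, 5),
             sweep(matrix(rnorm(300, sd = 0.1), 60, 5), 2, rep(10, 5), "+"))
  planted <- rep(1:2, each = 60)
  m <- kmeansFit(X, 2, nRestarts = 10, seed = 2)
  lab <- stateLabels(m)$state
  agreement <- max(mean(lab == planted), mean(lab == 3 - planted))
  expect_equal(agreement, 1)
})

test_that("best-of-restarts inertia is monotone in k", {
  set.seed(20)
  X <- matrix(rnorm(600), 100, 6)
  i2 <- stateInertia(kmeansFit(X, 2, nRestarts = 10, seed = 3))
  i3 <- stateInertia(kmeansFit(X, 3, nRestarts = 10, seed = 3))
  expect_lte(i3, i2)
})

test_that("k-means is deterministic given the seed and validates k", {
  set.seed(21)
  X <- matrix(rnorm(300), 50, 6)
  m1 <- kmeansFit(X, 3, nRestarts = 5, seed = 9)
  m2 <- kmeansFit(X, 3, nRestarts = 5, seed = 9)
  expect_identical(stateCentroids(m1), stateCentroids(m2))
  expect_identical(stateLabels(m1), stateLabels(m2))
  Xdeg <- matrix(rep(c(0, 1), each = 6), 4, 3, byrow = TRUE)
  expect_error(kmeansFit(Xdeg, 3), "distinct")
})

test_that("inertia is recomputable from labels and centroids", {
  set.seed(22)
  X <- matrix(rnorm(400), 80, 5)
  m <- kmeansFit(X, 3, nRestarts = 5, seed = 4)
  d2 <- rowSums((X - stateCentroids(m)[stateLabels(m)$state, ])^2)
  expect_equal(sum(d2), stateInertia(m), tolerance = 1e-8)
})

test_that("elbow criterion recovers planted cluster counts", {
  set.seed(23)
  p <- 40
  mkBlobs <- function(k, nPer, sep) {
    centers <- matrix(0, k, p)
    for (s in seq_len(k))
      centers[s, ((s - 1) * 8 + 1):(s * 8)] <- sep / sqrt(8)
    do.call(rbind, lapply(seq_len(k), function(s)
      sweep(matrix(rnorm(nPer * p, sd = 0.3), nPer, p), 2, centers[s, ], "+")))
  }
  X4 <- mkBlobs(4, 150, 6)
  expect_equal(elbowSelectK(X4, 2:8, nRestarts = 4, seed = 5)$selectedK, 4)
  # with the true k at the range minimum the interior curve is flat and
  # the warning fallback lands on the correct k
  X2 <- mkBlobs(2, 200, 6)
  expect_warning(
    eb2 <- elbowSelectK(X2, 2:8, nRestarts = 4, seed = 5), "elbow")
  expect_equal(eb2$selectedK, 2)
})

test_that("elbow warns and falls back to the smallest k on a single blob", {
  set.seed(24)
  X <- matrix(rnorm(200 * 30), 200, 30)  # one Gaussian cloud
  expect_warning(eb <- elbowSelectK(X, 2:6, nRestarts = 4, seed = 6),
                 "elbow")
  expect_equal(eb$selectedK, 2L)
  expect_true(all(diff(eb$withinss) <= 1e-6))
})

test_that("states relabel by occupancy with norm tie-breaks, idempotently", {
  labs <- rep(1:4, times = c(15, 18, 55, 13))
  m <- modelFromLabels(list(all = labs), 4,
                       centroids = matrix(c(1, 2, 3, 4, 1, 2, 3, 4), 4, 2))
  s <- sortAndLabelStates(m)
  # the 55%-occupancy state becomes label 1
  expect_equal(which.max(tabulate(stateLabels(s)$state, 4)), 1L)
  expect_equal(stateCentroids(s)[1, ], c(3, 3))
  # ties on occupancy break by descending centroid norm
  m2 <- modelFromLabels(list(all = rep(1:2, each = 10)), 2,
                        centroids = matrix(c(1, 5, 1, 5), 2, 2))
  s2 <- sortAndLabelStates(m2)
  expect_equal(stateCentroids(s2)[1, ], c(5, 5))
  # idempotence
  expect_identical(sortAndLabelStates(s)@labels, s@labels)
  expect_identical(sortAndLabelStates(s)@centroids, s@centroids)
})

test_that("group centroids average the right windows and flag empty cells", {
  idx <- edgeIndex(4)
  z1 <- matrix(rnorm(30 * 6), 30, 6)
  wfc <- list(
    a = new("WindowedFC", subjectId = "a", zEdges = z1, edgeIndex = idx),
    b = new("WindowedFC", subjectId = "b", zEdges = z1 + 1, edgeIndex = idx))
  labs <- list(a = rep(1L, 30), b = rep(2L, 30))
  m <- modelFromLabels(labs, 2, centroids = matrix(0, 2, 6))
  gc <- groupCentroids(wfc, m, c(a = "HC", b = "AD"))
  expect_equal(matrixToEdgeVector(gc$HC[[1]]), colMeans(z1))
  # group HC never visits state 2 -> missing, not zero-filled
  expect_null(gc$HC[[2]])
  expect_equal(matrixToEdgeVector(gc$AD[[2]]), colMeans(z1 + 1))
  expect_true(all(is.na(diag(gc$HC[[1]]))))
})

test_that("top edges rank by absolute strength with index tie-breaks", {
  v <- rep(0, 666)
  te0 <- topEdges(v, 0.05)
  expect_equal(nrow(te0), 33)               # floor(0.05 * 666)
  expect_equal(te0$edge, 1:33)              # tie-break by edge index
  v[400] <- -5
  v[10] <- 2
  te <- topEdges(v, 0.05)
  expect_equal(te$edge[1:2], c(400L, 10L))  # ranked by |z|
  expect_equal(nrow(topEdges(rnorm(666), 1)), 666)
})

test_that("state matching solves the assignment exactly", {
  set.seed(25)
  cent <- matrix(rnorm(4 * 50), 4, 50)
  mkModel <- function(centroids) {
    new("StateModel", k = nrow(centroids), centroids = centroids,
        labels = data.frame(subject = "a",
                            window = seq_len(nrow(centroids)),
                            state = seq_len(nrow(centroids))),
        inertia = 0, seed = 1L, nRestarts = 1L)
  }
  a <- mkModel(cent)
  # self-match is the identity
  expect_equal(matchStates(a, a)$permutation, 1:4)
  # a label shuffle is inverted
  shuf <- c(3, 1, 4, 2)
  b <- mkModel(cent[shuf, ])
  mt <- matchStates(a, b)
  expect_equal(mt$permutation, order(shuf))
  expect_equal(mt$correlations, rep(1, 4))
  # exhaustive enumeration agrees with the assignment solver
  set.seed(26)
  a5 <- mkModel(matrix(rnorm(5 * 30), 5, 30))
  b5 <- mkModel(matrix(rnorm(5 * 30), 5, 30))
  C <- cor(t(a5@centroids), t(b5@centroids))
  perms <- as.matrix(expand.grid(rep(list(1:5), 5)))
  perms <- perms[apply(perms, 1, function(p) !anyDuplicated(p)), ]
  bestBrute <- max(apply(perms, 1, function(p) sum(C[cbind(1:5, p)])))
  expect_equal(matchStates(a5, b5)$total, bestBrute, tolerance = 1e-12)
  expect_error(matchStates(a, a5), "equal k")
})

test_that("clustering is invariant to subject ordering", {
  set.seed(27)
  idx <- edgeIndex(4)
  wfc <- lapply(1:4, function(i)
    new("WindowedFC", subjectId = paste0("s", i),
        zEdges = matrix(rnorm(20 * 6, mean = i %% 2 * 3), 20, 6),
        edgeIndex = idx))
  names(wfc) <- paste0("s", 1:4)
  st1 <- stackWindowedFC(wfc)
  st2 <- stackWindowedFC(wfc[c(3, 1, 4, 2)])
  m1 <- kmeansFit(st1$X, 2, nRestarts = 5, seed = 11,
                  subjects = st1$subjects, windows = st1$windows)
  m2 <- kmeansFit(st2$X, 2, nRestarts = 5, seed = 11,
                  subjects = st2$subjects, windows = st2$windows)
  l1 <- stateLabels(sortAndLabelStates(m1))
  l2 <- stateLabels(sortAndLabelStates(m2))
  l2 <- l2[order(match(l2$subject, l1$subject), l2$window), ]
  expect_equal(l1$state, l2$state)
})
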