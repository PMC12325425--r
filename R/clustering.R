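# k-means++ seeding: first centre uniform, later centres with
# probability proportional to squared distance to the nearest chosen one.
kmeansPlusPlusInit <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  first <- sample.int(n, 1L)
  centers[1, ] <- X[first, ]
  if (k > 1) {
    d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
    for (c in 2:k) {
      if (all(d2 == 0)) {
        pick <- sample.int(n, 1L)
      } else {
        pick <- sample.int(n, 1L, prob = d2)
      }
      centers[c, ] <- X[pick, ]
      d2 <- pmin(d2, rowSums(sweep(X, 2, centers[c, ])^2))
    }
  }
  centers
}

#' Best-of-restarts k-means state clustering
#'
#' Lloyd k-means with Euclidean distance and k-means++ initialisation,
#' restarted `nRestarts` times (default 100, to wash out the random
#' initial cluster selection); the solution with the lowest total
#' within-cluster sum of squares is kept. Deterministic given `seed`.
#'
#' @param X windows x edges matrix of Fisher-z vectors.
#' @param k number of states (>= 1, at most the number of distinct rows).
#' @param nRestarts restarts (default 100).
#' @param seed integer seed.
#' @param subjects optional subject id per row of `X`.
#' @param windows optional window index per row of `X`.
#' @param iterMax Lloyd iteration cap per restart (default 300).
#' @return a [StateModel-class].
#' @export
kmeansFit <- function(X, k, nRestarts = 100L, seed = 1L,
                      subjects = NULL, windows = NULL, iterMax = 300L) {
  X <- as.matrix(X)
  stopifnot(k >= 1, nrow(X) >= k)
  if (nrow(unique(X)) < k) stop("k exceeds the number of distinct rows")
  if (is.null(subjects)) subjects <- rep("all", nrow(X))
  if (is.null(windows)) {
    windows <- stats::ave(seq_along(subjects), subjects, FUN = seq_along)
  }
  best <- NULL
  for (r in seq_len(nRestarts)) {
    set.seed(childSeed(seed, r))
    km <- tryCatch({
      centers <- kmeansPlusPlusInit(X, k)
      suppressWarnings(stats::kmeans(X, centers = centers,
                                     iter.max = iterMax,
                                     algorithm = "Lloyd"))
    }, error = function(e) NULL)
    if (is.null(km)) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (is.null(best)) stop("all k-means restarts failed")
  new("StateModel",
      k = as.integer(k),
      centroids = unname(best$centers),
      labels = data.frame(subject = as.character(subjects),
                          window = as.integer(windows),
                          state = as.integer(best$cluster),
                          stringsAsFactors = FALSE),
      inertia = best$tot.withinss,
      seed = as.integer(seed),
      nRestarts = as.integer(nRestarts))
}

#' Stack per-subject windowed connectivity for clustering
#'
#' @param wfcList named list of [WindowedFC-class].
#' @return list with `X` (pooled windows x edges matrix), `subjects` and
#'   `windows` row annotations.
#' @export
stackWindowedFC <- function(wfcList) {
  stopifnot(length(wfcList) > 0)
  X <- do.call(rbind, lapply(wfcList, zEdges))
  subjects <- rep(vapply(wfcList, function(w) w@subjectId, character(1)),
                  vapply(wfcList, function(w) nrow(w@zEdges), integer(1)))
  windows <- unlist(lapply(wfcList, function(w) seq_len(nrow(w@zEdges))),
                    use.names = FALSE)
  list(X = unname(X), subjects = subjects, windows = as.integer(windows))
}

#' Elbow-criterion selection of the number of states
#'
#' For every k in `kRange`, fits best-of-restarts k-means and records
#' the dispersion ratio (within-cluster sum of squares divided by
#' between-cluster sum of squares). The selected k is the interior point
#' of maximum curvature of the log dispersion ratio: the argmax of
#' `log ratio[k-1] - 2 log ratio[k] + log ratio[k+1]`. The ratio decays
#' roughly geometrically while real cluster structure is being resolved
#' and flattens beyond the true k, so the log-scale second difference
#' peaks exactly at the flattening point (the raw-scale second
#' difference of a geometrically decaying curve peaks one k too early,
#' even for perfectly separated equidistant clusters).
#'
#' Degenerate input (a single cloud with no cluster structure) is
#' detected from the within-cluster curve: without real structure the
#' log within-cluster dispersion decays smoothly and its curvature
#' stays near zero everywhere, whereas a true elbow leaves a large kink.
#' When no curvature exceeds `minCurvature` the function warns and
#' falls back to the smallest k in the range. A data set whose cluster
#' structure is fully resolved at the smallest candidate k is also flat
#' over the interior and takes the same fallback, which is then the
#' correct selection.
#'
#' @param X windows x edges matrix.
#' @param kRange candidate k values (default 2:10).
#' @param nRestarts k-means restarts per k (default 10; model selection
#'   tolerates a lighter restart schedule than the final fit).
#' @param seed integer seed.
#' @param minCurvature smallest log-within-dispersion curvature counted
#'   as a real elbow (default 0.05).
#' @return list with `kValues`, `dispersionRatio`, `withinss`,
#'   `selectedK`.
#' @export
elbowSelectK <- function(X, kRange = 2:10, nRestarts = 10L, seed = 1L,
                         minCurvature = 0.05) {
  X <- as.matrix(X)
  stopifnot(length(kRange) >= 3, max(kRange) <= nrow(X))
  kRange <- sort(as.integer(kRange))
  totss <- sum(sweep(X, 2, colMeans(X))^2)
  within <- numeric(length(kRange))
  for (i in seq_along(kRange)) {
    m <- kmeansFit(X, kRange[i], nRestarts = nRestarts,
                   seed = childSeed(seed, 7000L + kRange[i]))
    within[i] <- m@inertia
  }
  between <- pmax(totss - within, .Machine$double.eps)
  ratio <- within / between
  interior <- 2:(length(kRange) - 1L)
  lw <- log(pmax(within, .Machine$double.eps))
  curvW <- lw[interior - 1L] - 2 * lw[interior] + lw[interior + 1L]
  if (max(curvW) < minCurvature) {
    warning("no pronounced elbow in the dispersion curve; ",
            "selecting the smallest k")
    selected <- kRange[1]
  } else {
    lr <- log(ratio)
    curv <- lr[interior - 1L] - 2 * lr[interior] + lr[interior + 1L]
    selected <- kRange[interior[which.max(curv)]]
  }
  list(kValues = kRange, dispersionRatio = ratio, withinss = within,
       selectedK = selected)
}

#' Relabel states by descending occupancy
#'
#' States are renumbered 1..k by descending pooled occupancy (fraction
#' of all windows assigned), ties broken by descending centroid norm, so
#' that reports are stable across runs. Idempotent.
#'
#' @param model a [StateModel-class].
#' @return relabelled [StateModel-class].
#' @export
sortAndLabelStates <- function(model) {
  stopifnot(is(model, "StateModel"))
  occ <- tabulate(model@labels$state, model@k)
  norms <- sqrt(rowSums(model@centroids^2))
  ord <- order(-occ, -norms)
  remap <- integer(model@k)
  remap[ord] <- seq_len(model@k)
  model@labels$state <- remap[model@labels$state]
  model@centroids <- model@centroids[ord, , drop = FALSE]
  model
}

#' Per-group state centroid matrices
#'
#' For every group and state, the mean Fisher-z edge vector over that
#' group's windows assigned to the state, reshaped to a symmetric matrix
#' with an empty (NA) diagonal. A group-state cell with no windows is
#' returned as `NULL` (flagged missing, never zero-filled).
#'
#' @param wfcList named list of [WindowedFC-class].
#' @param model fitted [StateModel-class] on the stacked windows.
#' @param groups named character vector: group per subject id.
#' @return nested list `result[[group]][[state]]`.
#' @export
groupCentroids <- function(wfcList, model, groups) {
  stopifnot(is(model, "StateModel"))
  labs <- model@labels
  nComp <- (1 + sqrt(1 + 8 * ncol(model@centroids))) / 2
  out <- list()
  for (g in unique(groups)) {
    subjectsInG <- names(groups)[groups == g]
    out[[g]] <- vector("list", model@k)
    for (s in seq_len(model@k)) {
      rows <- labs[labs$subject %in% subjectsInG & labs$state == s, ]
      if (nrow(rows) == 0L) next   # cell stays NULL: flagged missing
      acc <- 0
      for (id in unique(rows$subject)) {
        w <- rows$window[rows$subject == id]
        acc <- acc + colSums(zEdges(wfcList[[id]])[w, , drop = FALSE])
      }
      out[[g]][[s]] <- edgeVectorToMatrix(acc / nrow(rows), nComp)
    }
  }
  out
}

#' Strongest connections of a state centroid
#'
#' Edges ranked by absolute Fisher-z value, descending, ties broken by
#' edge index; the top `floor(fraction * nEdges)` are returned (33 of
#' 666 edges at the default 5%).
#'
#' @param centroid symmetric centroid matrix or edge vector.
#' @param fraction fraction of edges to keep (default 0.05).
#' @return data.frame with columns `edge`, `i`, `j`, `z`.
#' @export
topEdges <- function(centroid, fraction = 0.05) {
  stopifnot(fraction > 0, fraction <= 1)
  v <- if (is.matrix(centroid)) matrixToEdgeVector(centroid) else centroid
  nEdges <- length(v)
  nComp <- (1 + sqrt(1 + 8 * nEdges)) / 2
  idx <- edgeIndex(nComp)
  nKeep <- max(1L, floor(fraction * nEdges))
  ord <- order(-abs(v), seq_len(nEdges))[seq_len(nKeep)]
  data.frame(edge = ord, i = idx[ord, 1], j = idx[ord, 2], z = v[ord])
}

#' Match states between two fitted models
#'
#' Finds the permutation of model `b`'s states that maximises the total
#' Pearson correlation between matched centroids, by exact assignment
#' (dynamic programming over subsets).
#'
#' @param a,b [StateModel-class] objects with equal k.
#' @return list with `permutation` (state of `b` matched to each state
#'   of `a`), `correlations` (per matched pair) and `total`.
#' @export
matchStates <- function(a, b) {
  stopifnot(is(a, "StateModel"), is(b, "StateModel"))
  if (a@k != b@k) stop("models must have equal k")
  k <- a@k
  C <- matrix(0, k, k)
  for (i in seq_len(k))
    for (j in seq_len(k))
      C[i, j] <- stats::cor(a@centroids[i, ], b@centroids[j, ])
  perm <- solveAssignment(C)
  list(permutation = perm,
       correlations = C[cbind(seq_len(k), perm)],
       total = sum(C[cbind(seq_len(k), perm)]))
}

# Exact linear assignment maximising sum(C[i, perm[i]]) by dynamic
# programming over subsets of columns (fine for the small k used here).
solveAssignment <- function(C) {
  k <- nrow(C)
  nMask <- bitwShiftL(1L, k)
  f <- rep(-Inf, nMask)
  choice <- matrix(0L, nMask, 1L)
  f[1] <- 0
  popcount <- vapply(0:(nMask - 1L), function(m)
    sum(bitwAnd(m, bitwShiftL(1L, 0:(k - 1L))) != 0L), integer(1))
  for (mask in 0:(nMask - 2L)) {
    if (!is.finite(f[mask + 1L])) next
    i <- popcount[mask + 1L] + 1L  # next row of a to assign
    for (j in seq_len(k)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(mask, bit) != 0L) next
      nm <- bitwOr(mask, bit)
      val <- f[mask + 1L] + C[i, j]
      if (val > f[nm + 1L]) {
        f[nm + 1L] <- val
        choice[nm + 1L, 1L] <- j
      }
    }
  }
  perm <- integer(k)
  mask <- nMask - 1L
  for (i in k:1) {
    j <- choice[mask + 1L, 1L]
    perm[i] <- j
    mask <- bitwAnd(mask, bitwNot(bitwShiftL(1L, j - 1L)))
  }
  perm
}
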