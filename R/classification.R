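# Vectorised Welch t per column; zero standard error yields t = 0 so
# constant features sort last among ties.
welchTPerColumn <- function(X, y) {
  lev <- unique(y)
  A <- X[y == lev[1], , drop = FALSE]
  B <- X[y == lev[2], , drop = FALSE]
  v1 <- apply(A, 2, stats::var) / nrow(A)
  v2 <- apply(B, 2, stats::var) / nrow(B)
  se <- sqrt(v1 + v2)
  t <- (colMeans(A) - colMeans(B)) / se
  t[se == 0] <- 0
  t
}

#' Rank connectivity features by group separation
#'
#' Orders edges by descending absolute Welch t between the two classes;
#' ties (including constant features, which get t = 0) break by edge
#' index. Label flips leave the ordering unchanged.
#'
#' @param X subjects x edges matrix.
#' @param y binary class labels (one per row).
#' @return integer vector of edge indices, most discriminative first.
#' @export
rankEdgesByT <- function(X, y) {
  if (length(unique(y)) != 2) stop("both classes must be present")
  t <- welchTPerColumn(X, y)
  order(-abs(t), seq_along(t))
}

#' Rank-based ROC area under the curve
#'
#' AUC as the normalised Mann-Whitney statistic of the decision values,
#' with tied pairs counted 1/2: the probability that a random positive
#' scores above a random negative.
#'
#' @param scores numeric decision values (higher = more positive-like).
#' @param y class labels.
#' @param positiveClass label of the positive class (default: second
#'   sorted level).
#' @return AUC in `[0, 1]`.
#' @export
rocAuc <- function(scores, y, positiveClass = NULL) {
  lev <- sort(unique(as.character(y)))
  if (length(lev) != 2) stop("both classes must be present")
  if (is.null(positiveClass)) positiveClass <- lev[2]
  pos <- y == positiveClass
  r <- rank(scores)
  n1 <- sum(pos); n2 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Linear SVM with leave-one-out cross-validation
#'
#' For each left-out subject the features are standardised by the
#' training fold's mean and SD, edges are ranked by absolute Welch t on
#' the training fold only, and a linear SVM (penalty `C`) is trained on
#' the top `nFeatures` edges; the held-out prediction and signed
#' decision value are recorded. No statistic of the left-out subject
#' ever enters its own fold's ranking or scaling.
#'
#' @param X subjects x edges matrix.
#' @param y binary class labels.
#' @param nFeatures number of top-ranked edges per fold.
#' @param C SVM cost parameter (default 1).
#' @param seed integer seed (kept for interface stability; the LOOCV
#'   procedure itself is deterministic).
#' @param positiveClass label treated as "patient" for sensitivity
#'   (default `"AD"` when present, otherwise the second sorted level).
#' @return list with `accuracy`, `sensitivity`, `specificity`, `auc`,
#'   `predictions`, `decisionValues`, `foldFeatures` (per-fold selected
#'   edge sets), `consensusFeatures`, `nFeatures`, `positiveClass`.
#' @export
svmLoocv <- function(X, y, nFeatures, C = 1, seed = 1L,
                     positiveClass = NULL) {
  X <- as.matrix(X)
  y <- as.character(y)
  n <- nrow(X)
  lev <- sort(unique(y))
  if (n < 4 || length(lev) != 2 || min(table(y)) < 2)
    stop("need n >= 4 with both classes at least twice")
  if (is.null(positiveClass))
    positiveClass <- if ("AD" %in% lev) "AD" else lev[2]
  negativeClass <- setdiff(lev, positiveClass)
  nFeatures <- min(nFeatures, ncol(X))

  pred <- character(n)
  dv <- numeric(n)
  foldFeatures <- vector("list", n)
  for (i in seq_len(n)) {
    trX <- X[-i, , drop = FALSE]
    trY <- y[-i]
    if (length(unique(trY)) != 2)
      stop("a training fold is missing a class")
    mu <- colMeans(trX)
    sdv <- apply(trX, 2, sd)
    sdv[sdv == 0] <- 1
    trXs <- sweep(sweep(trX, 2, mu), 2, sdv, "/")
    teXs <- (X[i, ] - mu) / sdv
    sel <- rankEdgesByT(trXs, trY)[seq_len(nFeatures)]
    foldFeatures[[i]] <- sort(sel)
    fit <- e1071::svm(trXs[, sel, drop = FALSE],
                      factor(trY, levels = c(negativeClass, positiveClass)),
                      kernel = "linear", cost = C, scale = FALSE)
    p <- stats::predict(fit, matrix(teXs[sel], nrow = 1),
                        decision.values = TRUE)
    d <- as.numeric(attr(p, "decision.values"))
    # libsvm signs the decision value towards the first class of the
    # reported pair; orient it so positive = patient class
    pair <- colnames(attr(p, "decision.values"))[1]
    firstOfPair <- strsplit(pair, "/", fixed = TRUE)[[1]][1]
    dv[i] <- if (firstOfPair == positiveClass) d else -d
    pred[i] <- as.character(p[1])
  }
  tp <- sum(pred == positiveClass & y == positiveClass)
  tn <- sum(pred == negativeClass & y == negativeClass)
  fp <- sum(pred == positiveClass & y == negativeClass)
  fn <- sum(pred == negativeClass & y == positiveClass)
  list(
    accuracy = (tp + tn) / n,
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    auc = rocAuc(dv, y, positiveClass),
    predictions = pred,
    decisionValues = dv,
    foldFeatures = foldFeatures,
    consensusFeatures = consensusFeatures(foldFeatures),
    nFeatures = nFeatures,
    positiveClass = positiveClass
  )
}

#' Consensus features across cross-validation folds
#'
#' Intersection of the per-fold selected feature sets: the connections
#' every fold agreed on.
#'
#' @param foldSets list of integer feature-index vectors.
#' @return sorted integer vector (possibly empty).
#' @export
consensusFeatures <- function(foldSets) {
  stopifnot(length(foldSets) >= 1)
  sort(Reduce(intersect, foldSets))
}

#' Permutation p-value of the LOOCV accuracy
#'
#' Repeats the full LOOCV (including per-fold feature re-ranking) on
#' label permutations; `p = (1 + #{permuted accuracy >= observed}) /
#' (nPerm + 1)`.
#'
#' @inheritParams svmLoocv
#' @param nPerm number of permutations (default 1000).
#' @param observed optional precomputed observed report from
#'   [svmLoocv()] on the same data.
#' @return list with `p`, `observedAccuracy`, `permutedAccuracies`.
#' @export
permutationPvalue <- function(X, y, nFeatures, C = 1, nPerm = 1000L,
                              seed = 1L, positiveClass = NULL,
                              observed = NULL) {
  stopifnot(nPerm >= 1)
  if (is.null(observed))
    observed <- svmLoocv(X, y, nFeatures, C, seed, positiveClass)
  acc <- numeric(nPerm)
  for (b in seq_len(nPerm)) {
    set.seed(childSeed(seed, 50000L + b))
    yp <- sample(y)
    acc[b] <- tryCatch(
      svmLoocv(X, yp, nFeatures, C, seed, positiveClass)$accuracy,
      error = function(e) NA_real_)
  }
  acc <- acc[!is.na(acc)]
  p <- (1 + sum(acc >= observed$accuracy - 1e-12)) / (length(acc) + 1)
  list(p = p, observedAccuracy = observed$accuracy,
       permutedAccuracies = acc)
}

#' Sweep the number of SVM features
#'
#' Runs [svmLoocv()] for every feature count in `grid`; values above
#' the edge count are clipped with a warning. The best row is flagged
#' by accuracy, ties broken toward fewer features.
#'
#' @inheritParams svmLoocv
#' @param grid integer vector of feature counts.
#' @return list with `table` (data.frame: nFeatures, accuracy,
#'   sensitivity, specificity, auc, best) and `reports` (full per-value
#'   reports).
#' @export
sweepFeatureCounts <- function(X, y, grid, C = 1, seed = 1L,
                               positiveClass = NULL) {
  stopifnot(length(grid) >= 1)
  grid <- as.integer(grid)
  if (any(grid > ncol(X))) {
    warning("feature counts above the edge count clipped to ", ncol(X))
    grid <- pmin(grid, ncol(X))
  }
  grid <- unique(grid)
  reports <- lapply(grid, function(m)
    svmLoocv(X, y, m, C, seed, positiveClass))
  tab <- data.frame(
    nFeatures = grid,
    accuracy = vapply(reports, `[[`, numeric(1), "accuracy"),
    sensitivity = vapply(reports, `[[`, numeric(1), "sensitivity"),
    specificity = vapply(reports, `[[`, numeric(1), "specificity"),
    auc = vapply(reports, `[[`, numeric(1), "auc")
  )
  bestIdx <- order(-tab$accuracy, tab$nFeatures)[1]
  tab$best <- seq_len(nrow(tab)) == bestIdx
  list(table = tab, reports = reports)
}
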