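#' Tapered sliding windows
#'
#' Builds the Gaussian-tapered sliding windows used for dynamic
#' connectivity: the base taper is a discrete rectangle of
#' `windowLength` samples convolved with a unit-area Gaussian kernel of
#' width `sigma` (support truncated at +/- 4 sigma). Position p covers
#' samples `[p, p + windowLength - 1]`; taper mass falling outside the
#' time axis is clipped and each weight vector renormalised to sum 1.
#' With the step fixed at 1 TR there are `nTimepoints - windowLength`
#' positions (185 for 207 timepoints and a 22-TR window).
#'
#' @param nTimepoints number of samples on the time axis.
#' @param windowLength window length in TRs (default 22).
#' @param sigma Gaussian taper width in TRs (default 3).
#' @return list with `weights` (positions x nTimepoints matrix, rows
#'   summing to 1), `windowLength` and `sigma`.
#' @export
makeTapers <- function(nTimepoints, windowLength = 22L, sigma = 3) {
  if (windowLength >= nTimepoints)
    stop("windowLength must be smaller than nTimepoints")
  stopifnot(sigma > 0, windowLength >= 2)
  h <- max(1L, ceiling(4 * sigma))
  off <- (-h):h
  kern <- exp(-off^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  # rectangle over offsets 0..windowLength-1 convolved with the kernel
  base <- rep(0, windowLength + 2L * h)
  for (a in seq_len(windowLength))
    base[a + off + h] <- base[a + off + h] + kern
  baseOffsets <- (1L - h):(windowLength + h)  # offsets relative to p
  nPositions <- nTimepoints - windowLength
  weights <- matrix(0, nPositions, nTimepoints)
  for (p in seq_len(nPositions)) {
    idx <- p - 1L + baseOffsets
    keep <- idx >= 1L & idx <= nTimepoints
    weights[p, idx[keep]] <- base[keep]
    weights[p, ] <- weights[p, ] / sum(weights[p, ])
  }
  list(weights = weights, windowLength = as.integer(windowLength),
       sigma = sigma)
}

#' Weighted sample covariance
#'
#' Covariance under a probability-weight vector with the unbiased
#' normalisation 1 / (1 - sum(w^2)).
#'
#' @param X timepoints x components matrix.
#' @param w nonnegative weights summing to 1, one per row of `X`.
#' @return symmetric components x components covariance matrix.
#' @export
weightedCovariance <- function(X, w) {
  stopifnot(nrow(X) == length(w), all(w >= 0))
  w <- w / sum(w)
  denom <- 1 - sum(w^2)
  if (denom <= 0) stop("at least 2 effective samples required")
  mu <- as.numeric(crossprod(w, X))
  Xc <- sweep(X, 2, mu)
  S <- crossprod(Xc * w, Xc) / denom
  (S + t(S)) / 2
}

#' Graphical LASSO
#'
#' L1-penalised Gaussian precision estimation: minimises
#' `-log det(Theta) + tr(S Theta) + lambda * sum_{i != j} |Theta_ij|`
#' (penalty on off-diagonal entries only) by block coordinate descent.
#' With `lambda = 0` the solution is the unpenalised MLE `solve(S)`.
#' Non-convergence within `maxIter` sweeps is reported via the
#' `converged` flag, not an error (the sweep cap is a fixed pipeline
#' parameter).
#'
#' @param S symmetric covariance matrix with positive diagonal.
#' @param lambda penalty (>= 0).
#' @param maxIter coordinate-descent sweep cap (default 100).
#' @param tol convergence tolerance on the average absolute change of
#'   the working covariance, relative to the mean absolute off-diagonal
#'   of `S` (default 1e-4).
#' @return list with `precision` (Theta), `covariance` (W = inverse of
#'   Theta at the solution), `converged`, `iterations`.
#' @export
graphicalLasso <- function(S, lambda, maxIter = 100L, tol = 1e-4) {
  if (!isSymmetric(unname(S), tol = 1e-8)) stop("S must be symmetric")
  if (any(diag(S) <= 0)) stop("S must have positive diagonal")
  stopifnot(lambda >= 0)
  S <- (S + t(S)) / 2
  if (lambda == 0) {
    Theta <- solve(S)
    return(list(precision = (Theta + t(Theta)) / 2, covariance = S,
                converged = TRUE, iterations = 0L))
  }
  .glassoCd(S, lambda, as.integer(maxIter), tol)
}

#' Graphical-LASSO objective
#'
#' `-log det(Theta) + tr(S Theta) + lambda * sum_{i != j} |Theta_ij|`.
#'
#' @param Theta precision matrix.
#' @param S covariance matrix.
#' @param lambda penalty.
#' @return objective value.
#' @export
glassoObjective <- function(Theta, S, lambda) {
  -determinant(Theta, logarithm = TRUE)$modulus[1] +
    sum(S * Theta) + lambda * (sum(abs(Theta)) - sum(abs(diag(Theta))))
}

#' Fisher z-transformed edge vector of a covariance matrix
#'
#' Converts a (regularised) covariance to correlations, clamps them to
#' `|r| <= 1 - clampEps`, and applies the variance-stabilising Fisher
#' transform `z = atanh(r)`. Edges are ordered row-major over the strict
#' upper triangle.
#'
#' @param W covariance matrix with positive diagonal.
#' @param edgeIdx edge index as from [edgeIndex()]; defaults to the full
#'   upper triangle of `W`.
#' @param clampEps clamping margin (default 1e-7).
#' @return numeric z vector, one entry per edge.
#' @export
covarianceToFisherZ <- function(W, edgeIdx = edgeIndex(nrow(W)),
                                clampEps = 1e-7) {
  d <- diag(W)
  if (any(d <= 0)) stop("covariance diagonal must be positive")
  r <- W[edgeIdx] / sqrt(d[edgeIdx[, 1]] * d[edgeIdx[, 2]])
  r <- pmin(pmax(r, -1 + clampEps), 1 - clampEps)
  atanh(r)
}

#' Dynamic functional connectivity of one subject
#'
#' Full subject-level sliding-window pipeline: for every taper position,
#' the tapered weighted covariance of the component time courses is
#' regularised by the graphical LASSO and converted to a Fisher-z edge
#' vector; vectors are stacked into a windows x edges matrix.
#'
#' @param X timepoints x components matrix (cleaned time courses).
#' @param subjectId subject identifier.
#' @param windowLength window length in TRs (default 22).
#' @param sigma Gaussian taper width in TRs (default 3).
#' @param lambda graphical-LASSO penalty (default 0.1).
#' @param maxIter graphical-LASSO sweep cap (default 100).
#' @param tol graphical-LASSO tolerance (default 1e-4).
#' @return a [WindowedFC-class]; the number of non-converged windows (if
#'   any) is attached as attribute `nNotConverged`.
#' @export
computeSubjectDfnc <- function(X, subjectId = "subject",
                               windowLength = 22L, sigma = 3,
                               lambda = 0.1, maxIter = 100L, tol = 1e-4) {
  taps <- makeTapers(nrow(X), windowLength, sigma)
  idx <- edgeIndex(ncol(X))
  nPos <- nrow(taps$weights)
  Z <- matrix(0, nPos, nrow(idx))
  notConv <- 0L
  for (p in seq_len(nPos)) {
    S <- weightedCovariance(X, taps$weights[p, ])
    gl <- graphicalLasso(S, lambda, maxIter, tol)
    if (!gl$converged) notConv <- notConv + 1L
    Z[p, ] <- covarianceToFisherZ(gl$covariance, idx)
  }
  wfc <- new("WindowedFC", subjectId = as.character(subjectId),
             zEdges = Z, edgeIndex = idx)
  attr(wfc, "nNotConverged") <- notConv
  wfc
}

#' Dynamic functional connectivity of a cohort
#'
#' Applies [computeSubjectDfnc()] to every subject of a
#' [TimecourseSet-class].
#'
#' @inheritParams computeSubjectDfnc
#' @param tcs a [TimecourseSet-class].
#' @return named list of [WindowedFC-class], one per subject.
#' @export
computeCohortDfnc <- function(tcs, windowLength = 22L, sigma = 3,
                              lambda = 0.1, maxIter = 100L, tol = 1e-4) {
  stopifnot(is(tcs, "TimecourseSet"))
  out <- lapply(tcs@subjectIds, function(id)
    computeSubjectDfnc(tcs@timecourses[[id]], id, windowLength, sigma,
                       lambda, maxIter, tol))
  names(out) <- tcs@subjectIds
  out
}
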