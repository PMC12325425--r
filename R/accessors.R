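#' Accessors for pipeline containers
#'
#' Small read-only accessors so user code never touches slots directly.
#'
#' @param x a pipeline object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
subjectIds <- function(x) {
  if (is(x, "TimecourseSet")) return(x@subjectIds)
  if (is(x, "SyntheticTruth")) return(names(x@stateSequences))
  stop("no subject ids for class ", class(x))
}

#' @rdname accessors
#' @export
timecourses <- function(x) {
  stopifnot(is(x, "TimecourseSet"))
  x@timecourses
}

#' @rdname accessors
#' @export
trSeconds <- function(x) {
  stopifnot(is(x, "TimecourseSet"))
  x@trSeconds
}

#' @rdname accessors
#' @export
nStates <- function(x) {
  if (is(x, "StateModel")) return(x@k)
  if (is(x, "SyntheticTruth")) return(length(x@archetypes))
  stop("no state count for class ", class(x))
}

#' @rdname accessors
#' @export
stateCentroids <- function(x) {
  stopifnot(is(x, "StateModel"))
  x@centroids
}

#' @rdname accessors
#' @export
stateLabels <- function(x) {
  stopifnot(is(x, "StateModel"))
  x@labels
}

#' @rdname accessors
#' @export
stateInertia <- function(x) {
  stopifnot(is(x, "StateModel"))
  x@inertia
}

#' @rdname accessors
#' @export
zEdges <- function(x) {
  stopifnot(is(x, "WindowedFC"))
  x@zEdges
}

#' @rdname accessors
#' @export
archetypeCovariance <- function(x) {
  stopifnot(is(x, "StateArchetype"))
  x@covariance
}

#' @rdname accessors
#' @export
stateSequences <- function(x) {
  stopifnot(is(x, "SyntheticTruth"))
  x@stateSequences
}

#' @rdname accessors
#' @export
truthArchetypes <- function(x) {
  stopifnot(is(x, "SyntheticTruth"))
  x@archetypes
}

#' Edge index of the strict upper triangle
#'
#' Row-major ordering of the unique component pairs (i, j), i < j: edge 1
#' is (1,2), edge 2 is (1,3), ..., the convention used for every edge
#' vector in the package. For 37 components this yields 666 edges.
#'
#' @param nComponents number of components.
#' @return integer matrix with columns `i` and `j`.
#' @export
edgeIndex <- function(nComponents) {
  stopifnot(nComponents >= 2)
  i <- rep(seq_len(nComponents - 1L), times = (nComponents - 1L):1L)
  j <- unlist(lapply(seq_len(nComponents - 1L), function(a) (a + 1L):nComponents),
              use.names = FALSE)
  cbind(i = as.integer(i), j = as.integer(j))
}

#' Reshape an edge vector into a symmetric matrix
#'
#' Inverse of the upper-triangle vectorisation; the diagonal is left at
#' `diagValue` (states are defined on off-diagonal connectivity only).
#'
#' @param v numeric edge vector.
#' @param nComponents number of components.
#' @param diagValue value placed on the diagonal (default `NA`).
#' @return symmetric nComponents x nComponents matrix.
#' @export
edgeVectorToMatrix <- function(v, nComponents, diagValue = NA_real_) {
  idx <- edgeIndex(nComponents)
  stopifnot(length(v) == nrow(idx))
  M <- matrix(diagValue, nComponents, nComponents)
  M[idx] <- v
  M[idx[, c(2, 1), drop = FALSE]] <- v
  M
}

#' Vectorise the strict upper triangle of a symmetric matrix
#'
#' @param M symmetric matrix.
#' @return numeric vector in row-major upper-triangle order.
#' @export
matrixToEdgeVector <- function(M) {
  idx <- edgeIndex(nrow(M))
  M[idx]
}

# Derive a stream of child seeds from one root seed, staying within the
# 32-bit integer range expected by set.seed().
childSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 9973) %% 2147483563) + 1L
}
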