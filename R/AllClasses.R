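#' @import methods
#' @importFrom stats sd cor median rnorm runif rbinom quantile pnorm pt pchisq
#' @importFrom utils head combn write.csv read.csv
#' @useDynLib dfnc, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Cohort of per-subject component time courses
#'
#' Container for the raw input of the dynamic-connectivity pipeline: one
#' numeric matrix per subject with rows = timepoints (TRs) and columns =
#' independent components, plus the repetition time used for any
#' frequency-domain operation.
#'
#' @slot timecourses named list of numeric matrices, one per subject,
#'   all with identical dimensions (timepoints x components).
#' @slot subjectIds character vector of unique subject identifiers,
#'   parallel to `timecourses`.
#' @slot trSeconds sampling interval (repetition time) in seconds.
#' @export
setClass("TimecourseSet",
  representation(
    timecourses = "list",
    subjectIds = "character",
    trSeconds = "numeric"
  )
)

setValidity("TimecourseSet", function(object) {
  msgs <- character()
  if (length(object@timecourses) != length(object@subjectIds))
    msgs <- c(msgs, "one time-course matrix per subject id required")
  if (anyDuplicated(object@subjectIds))
    msgs <- c(msgs, "subject ids must be unique")
  if (length(object@trSeconds) != 1L || object@trSeconds <= 0)
    msgs <- c(msgs, "trSeconds must be a single positive number")
  dims <- unique(lapply(object@timecourses, dim))
  if (length(dims) > 1L)
    msgs <- c(msgs, "all subjects must share the same matrix dimensions")
  if (length(object@timecourses) > 0L) {
    if (!all(vapply(object@timecourses, function(m)
      is.matrix(m) && is.numeric(m) && all(is.finite(m)), logical(1))))
      msgs <- c(msgs, "time courses must be finite numeric matrices")
  }
  if (length(msgs)) msgs else TRUE
})

#' Planted connectivity-state archetype
#'
#' One latent functional-connectivity state of the synthetic generator: a
#' component-by-component correlation matrix used as the emission
#' covariance while the hidden Markov chain occupies this state.
#'
#' @slot stateId integer state label (1-based).
#' @slot covariance symmetric positive-definite matrix with unit diagonal.
#' @slot description free-text characterisation of the state.
#' @export
setClass("StateArchetype",
  representation(
    stateId = "integer",
    covariance = "matrix",
    description = "character"
  )
)

setValidity("StateArchetype", function(object) {
  S <- object@covariance
  msgs <- character()
  if (!isSymmetric(unname(S), tol = 1e-8))
    msgs <- c(msgs, "covariance must be symmetric")
  else {
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      msgs <- c(msgs, "covariance must be positive definite")
  }
  if (max(abs(diag(S) - 1)) > 1e-8)
    msgs <- c(msgs, "covariance must have unit diagonal (correlation scale)")
  if (length(msgs)) msgs else TRUE
})

#' Synthetic-cohort configuration
#'
#' Describes a two-group cohort of component time courses whose
#' correlation structure switches among K latent states via group-specific
#' Markov chains.
#'
#' @slot nSubjectsPerGroup integer vector of length 2 (reference group,
#'   patient-like group).
#' @slot nComponents number of independent components per subject.
#' @slot nTimepoints number of TRs per subject.
#' @slot trSeconds repetition time in seconds.
#' @slot networkBlockSizes partition of components into functional
#'   networks; must sum to `nComponents`.
#' @slot transitionMatrices list of two row-stochastic K x K matrices,
#'   one per group.
#' @slot observationNoiseSd isotropic observation noise standard deviation.
#' @slot ar AR(1) coefficient of the within-state emission process
#'   (0 = temporally independent observations).
#' @slot seed integer root seed for the cohort.
#' @export
setClass("CohortConfig",
  representation(
    nSubjectsPerGroup = "integer",
    nComponents = "integer",
    nTimepoints = "integer",
    trSeconds = "numeric",
    networkBlockSizes = "integer",
    transitionMatrices = "list",
    observationNoiseSd = "numeric",
    ar = "numeric",
    seed = "integer"
  )
)

setValidity("CohortConfig", function(object) {
  msgs <- character()
  if (length(object@nSubjectsPerGroup) != 2L || any(object@nSubjectsPerGroup < 1L))
    msgs <- c(msgs, "nSubjectsPerGroup must be two positive counts")
  if (sum(object@networkBlockSizes) != object@nComponents)
    msgs <- c(msgs, "network block sizes must sum to nComponents")
  if (length(object@transitionMatrices) != 2L)
    msgs <- c(msgs, "one transition matrix per group required")
  for (P in object@transitionMatrices) {
    if (!is.matrix(P) || nrow(P) != ncol(P))
      msgs <- c(msgs, "transition matrices must be square")
    else {
      if (any(P < 0) || any(P > 1))
        msgs <- c(msgs, "transition probabilities must lie in [0, 1]")
      if (max(abs(rowSums(P) - 1)) > 1e-12)
        msgs <- c(msgs, "transition-matrix rows must sum to 1 within 1e-12")
    }
  }
  if (object@observationNoiseSd < 0)
    msgs <- c(msgs, "observationNoiseSd must be nonnegative")
  if (abs(object@ar) >= 1)
    msgs <- c(msgs, "ar coefficient must lie in (-1, 1)")
  if (length(msgs)) msgs else TRUE
})

#' Ground truth of a synthetic cohort
#'
#' Everything the generator knows and the pipeline must recover: the
#' per-timepoint latent state sequences, the planted archetypes, the
#' group transition matrices, and the linear model tying clinical scores
#' to true state occupancy.
#'
#' @slot stateSequences named list (by subject) of integer state
#'   sequences, one label per timepoint.
#' @slot archetypes list of [StateArchetype-class] objects.
#' @slot transitionMatrices list of two K x K matrices (one per group).
#' @slot scoreModel list with elements `intercept`, `weights` (per state)
#'   and `noiseSd`, or empty before scores are attached.
#' @export
setClass("SyntheticTruth",
  representation(
    stateSequences = "list",
    archetypes = "list",
    transitionMatrices = "list",
    scoreModel = "list"
  )
)

setValidity("SyntheticTruth", function(object) {
  k <- length(object@archetypes)
  msgs <- character()
  lens <- unique(vapply(object@stateSequences, length, integer(1)))
  if (length(lens) > 1L)
    msgs <- c(msgs, "all state sequences must have equal length")
  bad <- vapply(object@stateSequences, function(s)
    any(s < 1L | s > k), logical(1))
  if (any(bad))
    msgs <- c(msgs, "state labels must lie in 1..K")
  if (length(msgs)) msgs else TRUE
})

#' Windowed functional connectivity of one subject
#'
#' The subject-level output of the sliding-window stage: one Fisher-z
#' edge vector per taper position.
#'
#' @slot subjectId subject identifier.
#' @slot zEdges numeric matrix, windows x edges, of Fisher z-transformed
#'   correlations.
#' @slot edgeIndex integer matrix with two columns (i, j), i < j, giving
#'   the component pair behind each edge column (row-major upper
#'   triangle order).
#' @export
setClass("WindowedFC",
  representation(
    subjectId = "character",
    zEdges = "matrix",
    edgeIndex = "matrix"
  )
)

setValidity("WindowedFC", function(object) {
  msgs <- character()
  if (ncol(object@zEdges) != nrow(object@edgeIndex))
    msgs <- c(msgs, "one edge-index row per z column required")
  if (!all(is.finite(object@zEdges)))
    msgs <- c(msgs, "all z values must be finite")
  if (nrow(object@edgeIndex) > 0 &&
      any(object@edgeIndex[, 1] >= object@edgeIndex[, 2]))
    msgs <- c(msgs, "edge index must satisfy i < j")
  if (length(msgs)) msgs else TRUE
})

#' Fitted connectivity-state model
#'
#' Result of k-means clustering of all subjects' windowed Fisher-z edge
#' vectors: the state centroids and the per-window state assignment.
#'
#' @slot k number of states.
#' @slot centroids k x edges matrix of state centroids (Fisher-z scale).
#' @slot labels data.frame with columns `subject`, `window`, `state`.
#' @slot inertia total within-cluster sum of squared Euclidean distances.
#' @slot seed integer seed used for the restarts.
#' @slot nRestarts number of k-means restarts performed.
#' @export
setClass("StateModel",
  representation(
    k = "integer",
    centroids = "matrix",
    labels = "data.frame",
    inertia = "numeric",
    seed = "integer",
    nRestarts = "integer"
  )
)

setValidity("StateModel", function(object) {
  msgs <- character()
  if (nrow(object@centroids) != object@k)
    msgs <- c(msgs, "one centroid row per state required")
  if (!all(c("subject", "window", "state") %in% names(object@labels)))
    msgs <- c(msgs, "labels must have subject, window and state columns")
  else if (nrow(object@labels) > 0 &&
           (any(object@labels$state < 1L) || any(object@labels$state > object@k)))
    msgs <- c(msgs, "state labels must lie in 1..k")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "TimecourseSet", function(object) {
  d <- if (length(object@timecourses)) dim(object@timecourses[[1]]) else c(0, 0)
  cat(sprintf("TimecourseSet: %d subjects, %d timepoints x %d components, TR = %.3g s\n",
              length(object@subjectIds), d[1], d[2], object@trSeconds))
})

setMethod("show", "StateArchetype", function(object) {
  cat(sprintf("StateArchetype %d (%d components): %s\n",
              object@stateId, nrow(object@covariance), object@description))
})

setMethod("show", "WindowedFC", function(object) {
  cat(sprintf("WindowedFC [%s]: %d windows x %d edges\n",
              object@subjectId, nrow(object@zEdges), ncol(object@zEdges)))
})

setMethod("show", "StateModel", function(object) {
  occ <- if (nrow(object@labels))
    paste(sprintf("%.2f", tabulate(object@labels$state, object@k) /
                    nrow(object@labels)), collapse = " ")
  else "none"
  cat(sprintf("StateModel: k = %d, %d windows, inertia = %.4g\n  occupancy: %s\n",
              object@k, nrow(object@labels), object@inertia, occ))
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth: %d subjects, %d states, scores %s\n",
              length(object@stateSequences), length(object@archetypes),
              if (length(object@scoreModel)) "attached" else "not attached"))
})

setMethod("show", "CohortConfig", function(object) {
  cat(sprintf("CohortConfig: %d + %d subjects, %d components, %d timepoints, K = %d states\n",
              object@nSubjectsPerGroup[1], object@nSubjectsPerGroup[2],
              object@nComponents, object@nTimepoints,
              nrow(object@transitionMatrices[[1]])))
})
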