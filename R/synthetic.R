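#' Block-structured state archetype specification
#'
#' The four default connectivity states are defined on seven functional
#' network blocks (visual, sensorimotor, auditory, default-mode,
#' cognitive-executive, cerebellar, basal ganglia). Each state is given
#' by a per-block within-network correlation and a block-by-block
#' between-network correlation matrix:
#'
#' * State I: moderate within-network coupling with moderately negative
#'   sensory-to-associative between-network correlations.
#' * State II: globally strong positive coupling (the "highly connected"
#'   state).
#' * State III: near-diagonal, sparse connectivity (the baseline state).
#' * State IV: strong visual/sensorimotor blocks with negative basal
#'   ganglia coupling to both.
#'
#' @param nBlocks number of network blocks (7 for the default parcellation).
#' @return list of per-state specs, each with elements `within`
#'   (length-`nBlocks` vector), `between` (`nBlocks` x `nBlocks`
#'   symmetric matrix, diagonal ignored) and `description`.
#' @export
defaultArchetypeSpec <- function(nBlocks = 7L) {
  stopifnot(nBlocks == 7L)
  sensory <- 1:3   # VN, SMN, AUD
  assoc <- 4:7     # DMN, CEN, CB, BG
  zeroB <- matrix(0, nBlocks, nBlocks)

  b1 <- zeroB
  b1[sensory, assoc] <- -0.25
  b1[assoc, sensory] <- -0.25

  b2 <- matrix(0.4, nBlocks, nBlocks)

  b3 <- matrix(0.02, nBlocks, nBlocks)

  b4 <- zeroB
  b4[1, 2] <- b4[2, 1] <- 0.45   # VN-SMN coupling
  b4[7, 1] <- b4[1, 7] <- -0.40  # BG-VN
  b4[7, 2] <- b4[2, 7] <- -0.40  # BG-SMN
  w4 <- c(0.60, 0.60, 0.15, 0.15, 0.15, 0.15, 0.15)

  list(
    list(within = rep(0.45, nBlocks), between = b1,
         description = "moderate within-network, negative sensory-associative"),
    list(within = rep(0.60, nBlocks), between = b2,
         description = "highly connected: strong intra- and inter-network coupling"),
    list(within = rep(0.15, nBlocks), between = b3,
         description = "sparse, near-diagonal baseline connectivity"),
    list(within = w4, between = b4,
         description = "strong sensory blocks with negative basal-ganglia coupling")
  )
}

#' Default network partition of the 37 components
#'
#' Sizes of the seven network blocks (VN, SMN, AUD, DMN, CEN, CB, BG).
#'
#' @return integer vector summing to 37.
#' @export
defaultNetworkBlockSizes <- function() {
  c(VN = 9L, SMN = 5L, AUD = 2L, DMN = 8L, CEN = 8L, CB = 3L, BG = 2L)
}

#' Build planted state covariance matrices
#'
#' Expands block-level correlation specifications into full
#' component-level correlation matrices, one per state. Matrices that are
#' not positive definite are repaired by flooring eigenvalues at 1e-6 and
#' rescaling to unit diagonal; a spec that is still indefinite after
#' repair is an error.
#'
#' @param networkBlockSizes integer partition of the components.
#' @param archetypeSpec per-state spec as from [defaultArchetypeSpec()].
#' @return list of [StateArchetype-class] objects.
#' @export
buildStateCovariances <- function(networkBlockSizes = defaultNetworkBlockSizes(),
                                  archetypeSpec = defaultArchetypeSpec()) {
  networkBlockSizes <- as.integer(networkBlockSizes)
  nBlocks <- length(networkBlockSizes)
  p <- sum(networkBlockSizes)
  blockOf <- rep(seq_len(nBlocks), times = networkBlockSizes)

  lapply(seq_along(archetypeSpec), function(s) {
    spec <- archetypeSpec[[s]]
    stopifnot(length(spec$within) == nBlocks,
              all(dim(spec$between) == c(nBlocks, nBlocks)))
    if (any(abs(spec$within) >= 1) || any(abs(spec$between) >= 1))
      stop("correlation levels must lie in (-1, 1)")
    S <- spec$between[blockOf, blockOf]
    for (b in seq_len(nBlocks)) {
      idx <- which(blockOf == b)
      S[idx, idx] <- spec$within[b]
    }
    diag(S) <- 1
    S <- repairCorrelation(S)
    new("StateArchetype", stateId = as.integer(s), covariance = S,
        description = if (is.null(spec$description)) "" else spec$description)
  })
}

# Floor eigenvalues at 1e-6 and rescale to unit diagonal; error if the
# result is still not positive definite.
repairCorrelation <- function(S) {
  ed <- eigen(S, symmetric = TRUE)
  if (min(ed$values) < 1e-6) {
    vals <- pmax(ed$values, 1e-6)
    S <- ed$vectors %*% (vals * t(ed$vectors))
    d <- sqrt(diag(S))
    S <- S / outer(d, d)
    S <- (S + t(S)) / 2
    diag(S) <- 1
  }
  if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("correlation spec not positive definite after repair")
  S
}

#' Amplified archetypes for planted-recovery validation
#'
#' Same four-state structure as [defaultArchetypeSpec()] but with
#' amplified contrasts, chosen so that all six pairwise distances
#' between the states' Fisher-z edge patterns are large and comparable.
#' This is the regime for validating state recovery (label agreement,
#' elbow selection of k): windowed covariance estimates carry
#' substantial sampling noise at a 22-TR window, so recovery guarantees
#' only hold when planted states are strongly separated.
#'
#' @inheritParams defaultArchetypeSpec
#' @return list of per-state specs (see [defaultArchetypeSpec()]).
#' @export
validationArchetypeSpec <- function(nBlocks = 7L) {
  stopifnot(nBlocks == 7L)
  sensory <- 1:3
  assoc <- 4:7
  zeroB <- matrix(0, nBlocks, nBlocks)

  b1 <- zeroB
  b1[sensory, assoc] <- -0.40
  b1[assoc, sensory] <- -0.40

  # heterogeneous between-network levels keep the four z patterns
  # mutually distinguishable (a uniform level would make this state's
  # pattern collinear with the sparse state's block indicator)
  b2 <- matrix(0.45, nBlocks, nBlocks)
  b2[4, 5] <- b2[5, 4] <- 0.65   # DMN-CEN
  b2[1, 2] <- b2[2, 1] <- 0.60   # VN-SMN
  b2[sensory, 6:7] <- 0.30
  b2[6:7, sensory] <- 0.30

  b3 <- matrix(0.04, nBlocks, nBlocks)

  b4 <- zeroB
  b4[1, 2] <- b4[2, 1] <- 0.65
  b4[7, 1] <- b4[1, 7] <- -0.60
  b4[7, 2] <- b4[2, 7] <- -0.60
  w4 <- c(0.80, 0.80, 0.30, 0.05, 0.05, 0.05, 0.05)
  w3 <- c(0.18, 0.18, 0.18, 0.30, 0.18, 0.18, 0.18)  # faint DMN emphasis

  list(
    list(within = rep(0.55, nBlocks), between = b1,
         description = "moderate within-network, negative sensory-associative"),
    list(within = rep(0.75, nBlocks), between = b2,
         description = "highly connected: strong intra- and inter-network coupling"),
    list(within = w3, between = b3,
         description = "sparse, near-diagonal baseline connectivity"),
    list(within = w4, between = b4,
         description = "strong sensory blocks with negative basal-ganglia coupling")
  )
}

#' Well-separated validation cohort configuration
#'
#' The study conditions for planted-recovery validation: the amplified
#' archetypes of [validationArchetypeSpec()], persistent state chains
#' (mean dwell around 40-90 TRs, so most 22-TR windows fall inside a
#' single state run), low observation noise, and a mild version of the
#' planted group contrast (patient-like group over-occupies the sparse
#' state III and under-occupies state IV). Occupancies are kept
#' near-balanced: a state that drifts below ~15% of the pooled windows
#' at this cohort size no longer forms a recoverable cluster, which
#' would break the well-separated premise the recovery guarantees are
#' conditioned on. Pass the result to [makeCohort()] together with
#' [validationArchetypeSpec()].
#'
#' @param nSubjectsPerGroup counts per group (default `c(15, 15)`).
#' @param seed root seed.
#' @return a [CohortConfig-class].
#' @export
validationCohortConfig <- function(nSubjectsPerGroup = c(15L, 15L),
                                   seed = 1L) {
  cohortConfig(
    nSubjectsPerGroup = nSubjectsPerGroup,
    transitionMatrices = list(
      HC = transitionMatrixFromOccupancy(c(0.25, 0.25, 0.28, 0.22),
                                         q = c(0.02, 0.02, 0.018, 0.022)),
      AD = transitionMatrixFromOccupancy(c(0.22, 0.22, 0.36, 0.20),
                                         q = c(0.02, 0.02, 0.015, 0.028))
    ),
    observationNoiseSd = 0.02,
    seed = seed
  )
}

#' Stationary distribution of a Markov chain
#'
#' For a reducible chain (e.g. the identity matrix) the stationary law
#' is not unique; the uniform distribution is returned as the starting
#' convention.
#'
#' @param P row-stochastic transition matrix.
#' @return probability vector pi with pi %*% P = pi.
#' @export
stationaryDistribution <- function(P) {
  k <- nrow(P)
  A <- rbind(t(P) - diag(k), rep(1, k))
  b <- c(rep(0, k), 1)
  pi <- tryCatch(qr.solve(A, b), error = function(e) rep(1 / k, k))
  pi <- pmax(pi, 0)
  pi / sum(pi)
}

#' Transition matrix with prescribed stationary occupancy
#'
#' Constructs a "lazy" chain P = diag(1 - q) + q r' whose stationary
#' distribution is exactly proportional to r/q: choosing the laziness
#' vector q sets per-state persistence (mean dwell roughly
#' 1 / (q_s (1 - r_s)) timepoints) while the jump distribution r is
#' solved so that the stationary law equals `occupancy`.
#'
#' @param occupancy target stationary probabilities (length K, positive).
#' @param q per-state jump propensity in (0, 1].
#' @return K x K row-stochastic matrix.
#' @export
transitionMatrixFromOccupancy <- function(occupancy, q) {
  stopifnot(length(occupancy) == length(q),
            all(occupancy > 0), all(q > 0), all(q <= 1))
  occupancy <- occupancy / sum(occupancy)
  r <- occupancy * q
  r <- r / sum(r)
  P <- diag(1 - q) + q %o% r
  P / rowSums(P)
}

#' Default group transition matrices
#'
#' Two four-state chains whose stationary occupancies match the planted
#' group profiles: the patient-like (AD-like) group dwells longer in the
#' sparse state III and shorter in the strongly connected state IV than
#' the control-like group.
#'
#' @return named list with elements `HC` and `AD`.
#' @export
defaultTransitionMatrices <- function() {
  piHC <- c(0.1345, 0.1903, 0.4870, 0.1882)
  piAD <- c(0.1621, 0.1675, 0.5916, 0.0788)
  list(
    HC = transitionMatrixFromOccupancy(piHC, q = c(0.10, 0.10, 0.07, 0.10)),
    AD = transitionMatrixFromOccupancy(piAD, q = c(0.10, 0.10, 0.05, 0.16))
  )
}

#' Simulate one subject's component time courses
#'
#' Draws a latent state sequence from the Markov chain (initialised at
#' its stationary distribution) and, at each timepoint, a zero-mean
#' multivariate Gaussian observation with the current state's covariance
#' plus isotropic noise of variance `noiseSd^2`. An optional AR(1)
#' coefficient smooths the state-conditional signal; innovations are
#' scaled by sqrt(1 - ar^2) so the stationary marginal covariance remains
#' the archetype.
#'
#' @param transitionMatrix row-stochastic K x K matrix.
#' @param archetypes list of [StateArchetype-class] (length K).
#' @param nTimepoints number of TRs (>= 2).
#' @param noiseSd isotropic observation noise sd.
#' @param seed integer seed; seeded runs are bit-reproducible.
#' @param ar AR(1) coefficient in (-1, 1); 0 gives temporally
#'   independent observations.
#' @return list with `timecourse` (nTimepoints x components matrix) and
#'   `states` (integer vector of latent labels).
#' @export
simulateSubject <- function(transitionMatrix, archetypes, nTimepoints,
                            noiseSd = 0.1, seed = 1L, ar = 0) {
  K <- length(archetypes)
  if (K == 0L) stop("at least one archetype required")
  if (nTimepoints < 2L) stop("nTimepoints must be at least 2")
  stopifnot(nrow(transitionMatrix) == K, abs(ar) < 1)
  p <- nrow(archetypes[[1]]@covariance)
  chols <- lapply(archetypes, function(a) chol(a@covariance))

  set.seed(as.integer(seed))
  pi0 <- stationaryDistribution(transitionMatrix)
  states <- integer(nTimepoints)
  states[1] <- sample.int(K, 1L, prob = pi0)
  for (t in 2:nTimepoints)
    states[t] <- sample.int(K, 1L, prob = transitionMatrix[states[t - 1L], ])

  Z <- matrix(rnorm(nTimepoints * p), nTimepoints, p)
  X <- matrix(0, nTimepoints, p)
  if (ar == 0) {
    for (s in unique(states)) {
      idx <- which(states == s)
      X[idx, ] <- Z[idx, , drop = FALSE] %*% chols[[s]]
    }
  } else {
    innovScale <- sqrt(1 - ar^2)
    prev <- Z[1, ] %*% chols[[states[1]]]
    X[1, ] <- prev
    for (t in 2:nTimepoints) {
      e <- Z[t, ] %*% chols[[states[t]]]
      prev <- ar * prev + innovScale * e
      X[t, ] <- prev
    }
  }
  if (noiseSd > 0)
    X <- X + matrix(rnorm(nTimepoints * p, sd = noiseSd), nTimepoints, p)
  list(timecourse = unname(X), states = states)
}

#' Cohort configuration constructor
#'
#' @param nSubjectsPerGroup counts for the control-like and patient-like
#'   groups; the full-scale study design is `c(69, 100)` (HC, AD).
#' @param nComponents number of independent components (default 37).
#' @param nTimepoints number of TRs (default 207).
#' @param trSeconds repetition time in seconds; 2.24 s makes 207 TRs
#'   roughly an 8-minute acquisition.
#' @param networkBlockSizes component partition (default 9/5/2/8/8/3/2).
#' @param transitionMatrices list of two chains (control, patient).
#' @param observationNoiseSd isotropic observation noise sd.
#' @param ar AR(1) smoothing coefficient (default 0, independent
#'   observations; 0.3 is a reasonable value when temporal smoothness is
#'   wanted).
#' @param seed root seed.
#' @return a [CohortConfig-class] object.
#' @export
cohortConfig <- function(nSubjectsPerGroup = c(69L, 100L),
                         nComponents = 37L,
                         nTimepoints = 207L,
                         trSeconds = 2.24,
                         networkBlockSizes = defaultNetworkBlockSizes(),
                         transitionMatrices = defaultTransitionMatrices(),
                         observationNoiseSd = 0.1,
                         ar = 0,
                         seed = 1L) {
  new("CohortConfig",
      nSubjectsPerGroup = as.integer(nSubjectsPerGroup),
      nComponents = as.integer(nComponents),
      nTimepoints = as.integer(nTimepoints),
      trSeconds = trSeconds,
      networkBlockSizes = as.integer(networkBlockSizes),
      transitionMatrices = transitionMatrices,
      observationNoiseSd = observationNoiseSd,
      ar = ar,
      seed = as.integer(seed))
}

#' Generate a two-group synthetic cohort
#'
#' Simulates every subject from its group's Markov chain and the shared
#' state archetypes, draws demographic covariates (age, sex, education),
#' and attaches a planted memory-like clinical score negatively weighted
#' on state-III occupancy. Identical config (including seed) yields
#' byte-identical output.
#'
#' @param config a [CohortConfig-class].
#' @param archetypeSpec per-state block spec (default
#'   [defaultArchetypeSpec()]).
#' @param scoreWeights per-state weights of the planted clinical score
#'   (default -10 on state III only).
#' @param scoreNoiseSd score noise sd; the default targets a population
#'   score-occupancy correlation around -0.33 under the default chains.
#' @return list with `timecourses` ([TimecourseSet-class]), `manifest`
#'   (data.frame: subject_id, group, age, sex, education, score_memory)
#'   and `truth` ([SyntheticTruth-class]).
#' @export
makeCohort <- function(config = cohortConfig(),
                       archetypeSpec = defaultArchetypeSpec(),
                       scoreWeights = NULL,
                       scoreNoiseSd = NULL) {
  validObject(config)
  archetypes <- buildStateCovariances(config@networkBlockSizes, archetypeSpec)
  K <- length(archetypes)
  if (any(vapply(config@transitionMatrices, nrow, integer(1)) != K))
    stop("transition matrices must be K x K with K = number of archetypes")
  if (is.null(scoreWeights)) {
    scoreWeights <- rep(0, K)
    if (K >= 3) scoreWeights[3] <- -10
  }
  if (is.null(scoreNoiseSd)) scoreNoiseSd <- defaultScoreNoiseSd()

  groups <- c("HC", "AD")
  nPer <- config@nSubjectsPerGroup
  ids <- c(sprintf("HC%03d", seq_len(nPer[1])), sprintf("AD%03d", seq_len(nPer[2])))
  if (anyDuplicated(ids)) stop("duplicate subject ids")
  groupOf <- rep(groups, nPer)

  tcs <- vector("list", length(ids))
  seqs <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    g <- match(groupOf[i], groups)
    sim <- simulateSubject(config@transitionMatrices[[g]], archetypes,
                           config@nTimepoints, config@observationNoiseSd,
                           seed = childSeed(config@seed, i), ar = config@ar)
    tcs[[i]] <- sim$timecourse
    seqs[[i]] <- sim$states
  }
  names(tcs) <- names(seqs) <- ids

  set.seed(childSeed(config@seed, 1000003L))
  n <- length(ids)
  manifest <- data.frame(
    subject_id = ids,
    group = groupOf,
    age = round(rnorm(n, 65, 9), 1),
    sex = ifelse(runif(n) < 0.45, "M", "F"),
    education = pmax(0, round(rnorm(n, 8, 4.6))),
    stringsAsFactors = FALSE
  )

  truth <- new("SyntheticTruth",
               stateSequences = seqs,
               archetypes = archetypes,
               transitionMatrices = config@transitionMatrices,
               scoreModel = list())
  sc <- attachClinicalScores(truth, coefficients = scoreWeights,
                             noiseSd = scoreNoiseSd,
                             seed = childSeed(config@seed, 2000003L))
  manifest$score_memory <- sc$scores[manifest$subject_id]
  truth <- sc$truth

  tcset <- new("TimecourseSet", timecourses = tcs, subjectIds = ids,
               trSeconds = config@trSeconds)
  list(timecourses = tcset, manifest = manifest, truth = truth)
}

# Score noise calibrated so that, under the default AD-like chain over a
# 207-TR acquisition and a weight of -10 on state-III occupancy, the
# population score-occupancy correlation is about -0.35 (the sd of true
# state-III occupancy is about 0.168 at that length). At that strength a
# two-sided test at n = 100 recovers the association with ~95% power,
# while the effect stays in the weak-to-moderate range.
defaultScoreNoiseSd <- function() 4.5

#' True per-subject fractional occupancy
#'
#' Occupancy fractions of the latent state sequences (per timepoint, not
#' per window) recorded by the generator.
#'
#' @param truth a [SyntheticTruth-class].
#' @return subjects x K matrix of fractions, rows summing to 1.
#' @export
trueOccupancy <- function(truth) {
  K <- length(truth@archetypes)
  out <- t(vapply(truth@stateSequences,
                  function(s) tabulate(s, K) / length(s), numeric(K)))
  colnames(out) <- paste0("state", seq_len(K))
  out
}

#' Attach planted clinical scores to a cohort truth
#'
#' score_i = intercept + sum_s weight_s * (true fractional occupancy of
#' state s for subject i) + Gaussian noise.
#'
#' @param truth a [SyntheticTruth-class].
#' @param coefficients per-state weights (length K, finite).
#' @param noiseSd Gaussian noise sd (>= 0).
#' @param intercept score intercept.
#' @param seed integer seed.
#' @return list with `scores` (named numeric vector, one per subject)
#'   and `truth` (the input with `scoreModel` filled in).
#' @export
attachClinicalScores <- function(truth, coefficients, noiseSd = 0,
                                 intercept = 5, seed = 1L) {
  K <- length(truth@archetypes)
  stopifnot(length(coefficients) == K, all(is.finite(coefficients)),
            noiseSd >= 0)
  occ <- trueOccupancy(truth)
  set.seed(as.integer(seed))
  scores <- intercept + as.numeric(occ %*% coefficients) +
    rnorm(nrow(occ), sd = noiseSd)
  names(scores) <- rownames(occ)
  truth@scoreModel <- list(intercept = intercept, weights = coefficients,
                           noiseSd = noiseSd)
  list(scores = scores, truth = truth)
}
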