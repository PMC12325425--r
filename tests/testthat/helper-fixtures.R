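# Shared fixtures: tiny archetype specs and cheap cohort builders.

# Four-state spec over four single-component blocks: emissions are
# 4-dimensional, so chains-plus-scores simulations are cheap.
tinyArchetypeSpec <- function() {
  base <- function(level) {
    b <- matrix(level, 4, 4)
    list(within = rep(0, 4), between = b, description = "tiny")
  }
  list(base(0.5), base(0.3), base(0.05), base(-0.15))
}

tinyCohort <- function(nPerGroup = c(5, 5), seed = 1, ...) {
  makeCohort(cohortConfig(nSubjectsPerGroup = nPerGroup,
                          nComponents = 4L,
                          networkBlockSizes = c(1L, 1L, 1L, 1L),
                          seed = seed, ...),
             archetypeSpec = tinyArchetypeSpec())
}

# Fisher-z edge vectors of a list of archetypes (the planted targets on
# the scale the pipeline estimates).
archetypeZ <- function(archetypes) {
  sapply(archetypes, function(a) {
    r <- matrixToEdgeVector(archetypeCovariance(a))
    atanh(pmin(pmax(r, -0.999), 0.999))
  })
}

# Random symmetric positive-definite matrix.
randomSpd <- function(p, seed = 1, jitter = 1) {
  set.seed(seed)
  A <- matrix(rnorm(p * p), p, p)
  crossprod(A) / p + diag(jitter, p)
}

# Latent state sequences only (no emissions): one integer matrix
# subjects x timepoints drawn from the chain started at stationarity.
chainSequences <- function(P, nSubjects, nTimepoints, seed = 1) {
  set.seed(seed)
  K <- nrow(P)
  pi0 <- stationaryDistribution(P)
  out <- matrix(0L, nSubjects, nTimepoints)
  cum <- t(apply(P, 1, cumsum))
  out[, 1] <- sample.int(K, nSubjects, replace = TRUE, prob = pi0)
  for (t in 2:nTimepoints) {
    u <- runif(nSubjects)
    out[, t] <- max.col(cum[out[, t - 1L], , drop = FALSE] >= u,
                        ties.method = "first")
  }
  out
}

# Construct a minimal valid StateModel around a set of label sequences.
modelFromLabels <- function(labelList, k, centroids = NULL) {
  if (is.null(centroids)) centroids <- matrix(0, k, 2)
  labs <- do.call(rbind, lapply(names(labelList), function(id)
    data.frame(subject = id, window = seq_along(labelList[[id]]),
               state = as.integer(labelList[[id]]))))
  new("StateModel", k = as.integer(k), centroids = centroids,
      labels = labs, inertia = 0, seed = 1L, nRestarts = 1L)
}
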