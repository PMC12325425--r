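#' Run the full dynamic-connectivity pipeline
#'
#' Orchestrates post-processing, tapered sliding-window connectivity,
#' state clustering (fixed k or elbow selection), temporal metrics,
#' group statistics and (optionally) state-wise SVM classification on a
#' cohort of component time courses. All randomness flows from the one
#' root `seed`; identical inputs and seed give identical outputs.
#'
#' @param cohort list with `timecourses` ([TimecourseSet-class]),
#'   `manifest`, optional `truth`; or `NULL` to read from `inputDir`.
#' @param inputDir directory in [writeCohort()] layout (used when
#'   `cohort` is `NULL`).
#' @param outDir output directory; `NULL` disables file output.
#' @param windowLength sliding-window length in TRs (default 22).
#' @param sigma Gaussian taper width in TRs (default 3).
#' @param lambda graphical-LASSO penalty (default 0.1).
#' @param k number of states; `NULL` selects k by the elbow criterion
#'   over `kRange`.
#' @param kRange candidate k values for the elbow (default 2:10).
#' @param nRestarts k-means restarts for the final fit (default 100).
#' @param elbowRestarts restarts per k during elbow selection (default 10).
#' @param fdrQ FDR level for edgewise tests (default 0.05).
#' @param postprocess apply the cleaning cascade first (default TRUE).
#' @param classify run state-wise LOOCV-SVM classification (default
#'   FALSE; slow for large cohorts).
#' @param nFeaturesClassify features per fold when classifying (default 15).
#' @param nPerm label permutations for classifier significance (default
#'   99; 0 skips the permutation test).
#' @param writeDfnc also write per-subject `.dfnc.tsv` files (default
#'   FALSE; they are large).
#' @param seed root seed.
#' @return a run report: list with `config`, `model`
#'   ([StateModel-class]), `wfc`, `temporal`, `stats`, `classification`,
#'   `elbow`, `timings` (seconds per stage), `warnings`, `outputs`
#'   (files with md5 digests).
#' @export
runPipeline <- function(cohort = NULL, inputDir = NULL, outDir = NULL,
                        windowLength = 22L, sigma = 3, lambda = 0.1,
                        k = NULL, kRange = 2:10, nRestarts = 100L,
                        elbowRestarts = 10L, fdrQ = 0.05,
                        postprocess = TRUE, classify = FALSE,
                        nFeaturesClassify = 15L, nPerm = 99L,
                        writeDfnc = FALSE, seed = 1L) {
  timings <- c()
  warningsLog <- character()
  tic <- function() proc.time()[["elapsed"]]
  if (is.null(cohort)) {
    if (is.null(inputDir)) stop("either cohort or inputDir required")
    cohort <- readCohort(inputDir)
  }
  tcs <- cohort$timecourses
  manifest <- cohort$manifest
  if (!all(manifest$subject_id %in% tcs@subjectIds))
    stop("manifest subjects missing from the time-course set: ",
         paste(setdiff(manifest$subject_id, tcs@subjectIds), collapse = ", "))
  nT <- nrow(tcs@timecourses[[1]])
  if (windowLength >= nT) stop("windowLength must be below nTimepoints")

  t0 <- tic()
  if (postprocess) tcs <- postprocessTimecourses(tcs)
  timings["postprocess"] <- tic() - t0

  t0 <- tic()
  wfc <- computeCohortDfnc(tcs, windowLength, sigma, lambda)
  nc <- sum(vapply(wfc, function(w) attr(w, "nNotConverged"), integer(1)))
  if (nc > 0)
    warningsLog <- c(warningsLog,
                     sprintf("%d windows hit the graphical-lasso sweep cap", nc))
  timings["connectivity"] <- tic() - t0

  t0 <- tic()
  stacked <- stackWindowedFC(wfc)
  elbow <- NULL
  if (is.null(k)) {
    elbow <- elbowSelectK(stacked$X, kRange, elbowRestarts,
                          seed = childSeed(seed, 11L))
    k <- elbow$selectedK
  }
  model <- kmeansFit(stacked$X, k, nRestarts, seed = childSeed(seed, 13L),
                     subjects = stacked$subjects, windows = stacked$windows)
  model <- sortAndLabelStates(model)
  timings["clustering"] <- tic() - t0

  t0 <- tic()
  sequences <- stateSequencesFromModel(model)
  temporal <- temporalTable(sequences, manifest, model@k)
  timings["temporal"] <- tic() - t0

  t0 <- tic()
  groups <- stats::setNames(manifest$group, manifest$subject_id)
  statsOut <- groupStatistics(wfc, model, temporal, manifest, fdrQ)
  warningsLog <- c(warningsLog, statsOut$warnings)
  timings["stats"] <- tic() - t0

  classification <- NULL
  if (classify) {
    t0 <- tic()
    classification <- classifyStates(wfc, model, manifest,
                                     nFeaturesClassify, nPerm,
                                     seed = childSeed(seed, 17L))
    timings["classification"] <- tic() - t0
  }

  config <- list(windowLength = windowLength, sigma = sigma,
                 lambda = lambda, k = model@k, kRange = kRange,
                 nRestarts = nRestarts, elbowRestarts = elbowRestarts,
                 fdrQ = fdrQ, postprocess = postprocess, seed = seed,
                 nSubjects = nrow(manifest),
                 nWindows = nrow(zEdges(wfc[[1]])),
                 nEdges = ncol(zEdges(wfc[[1]])))

  outputs <- data.frame(file = character(), md5 = character())
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    paths <- character()
    sj <- file.path(outDir, "states.json")
    jsonlite::write_json(list(
      k = model@k, centroids = model@centroids, inertia = model@inertia,
      occupancy = as.numeric(tabulate(model@labels$state, model@k) /
                               nrow(model@labels)),
      seed = model@seed, nRestarts = model@nRestarts,
      config = config), sj, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, sj)
    lf <- file.path(outDir, "labels.tsv")
    utils::write.table(model@labels, lf, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    paths <- c(paths, lf)
    tf <- file.path(outDir, "temporal_properties.tsv")
    utils::write.table(temporal, tf, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    paths <- c(paths, tf)
    gf <- file.path(outDir, "group_stats.json")
    jsonlite::write_json(statsOut$summary, gf, auto_unbox = TRUE,
                         digits = NA, na = "null")
    paths <- c(paths, gf)
    for (s in seq_along(statsOut$edgeTests)) {
      if (is.null(statsOut$edgeTests[[s]])) next
      ef <- file.path(outDir, sprintf("edge_tests_state%d.tsv", s))
      utils::write.table(statsOut$edgeTests[[s]], ef, sep = "\t",
                         row.names = FALSE, quote = FALSE)
      paths <- c(paths, ef)
    }
    if (!is.null(elbow)) {
      bf <- file.path(outDir, "elbow.tsv")
      utils::write.table(
        data.frame(k = elbow$kValues, withinss = elbow$withinss,
                   dispersion_ratio = elbow$dispersionRatio),
        bf, sep = "\t", row.names = FALSE, quote = FALSE)
      paths <- c(paths, bf)
    }
    if (writeDfnc)
      paths <- c(paths, writeWindowedFC(wfc, file.path(outDir, "dfnc")))
    if (!is.null(classification)) {
      cf <- file.path(outDir, "classification.json")
      jsonlite::write_json(
        lapply(classification, function(r) r[c("state", "accuracy",
                                               "sensitivity", "specificity",
                                               "auc", "p",
                                               "consensusFeatures")]),
        cf, auto_unbox = TRUE, digits = NA, na = "null")
      paths <- c(paths, cf)
    }
    outputs <- data.frame(file = paths,
                          md5 = as.character(tools::md5sum(paths)),
                          row.names = NULL)
  }

  list(config = config, model = model, wfc = wfc, temporal = temporal,
       stats = statsOut$summary, edgeTests = statsOut$edgeTests,
       classification = classification, elbow = elbow,
       timings = timings, warnings = warningsLog, outputs = outputs)
}

# Group-level statistics of a fitted run: Mann-Whitney on temporal
# metrics, occupancy chi-square, edgewise Welch tests per state,
# score-temporal partial correlations within the patient group.
groupStatistics <- function(wfc, model, temporal, manifest, fdrQ = 0.05) {
  warningsLog <- character()
  groups <- stats::setNames(manifest$group, manifest$subject_id)
  lev <- unique(manifest$group)
  k <- model@k

  mw <- list()
  for (metric in c("fractional_windows", "mean_dwell_time")) {
    for (s in seq_len(k)) {
      sub <- temporal[temporal$state == s, ]
      res <- mannWhitneyZ(sub[[metric]][sub$group == lev[1]],
                          sub[[metric]][sub$group == lev[2]])
      mw[[sprintf("%s_state%d", metric, s)]] <-
        list(z = res$z, p = res$p)
    }
  }
  tc <- temporal[!duplicated(temporal$subject), ]
  resT <- mannWhitneyZ(tc$n_transitions[tc$group == lev[1]],
                       tc$n_transitions[tc$group == lev[2]])
  mw[["n_transitions"]] <- list(z = resT$z, p = resT$p)

  occ <- tryCatch(stateOccupancyChisq(model, groups),
                  warning = function(w) {
                    warningsLog <<- c(warningsLog, conditionMessage(w))
                    suppressWarnings(stateOccupancyChisq(model, groups))
                  })

  sequences <- stateSequencesFromModel(model)
  edgeTests <- vector("list", k)
  for (s in seq_len(k)) {
    fcRows <- list(); fcGroups <- character()
    for (id in manifest$subject_id) {
      v <- subjectStateFc(wfc[[id]], sequences[[id]], s)
      if (is.null(v)) next
      fcRows[[id]] <- v
      fcGroups <- c(fcGroups, groups[[id]])
    }
    if (length(unique(fcGroups)) < 2 ||
        min(table(fcGroups)) < 2) {
      warningsLog <- c(warningsLog,
                       sprintf("state %d lacks subjects in one group; edgewise tests skipped", s))
      next
    }
    edgeTests[[s]] <- edgewiseStateTtests(do.call(rbind, fcRows),
                                          fcGroups, fdrQ)
  }

  correlations <- list()
  scoreCols <- grep("^score_", names(manifest), value = TRUE)
  patientGroup <- if ("AD" %in% lev) "AD" else lev[2]
  pm <- manifest[manifest$group == patientGroup, ]
  if (length(scoreCols) && nrow(pm) > 6) {
    covars <- cbind(pm$age,
                    as.numeric(factor(pm$sex)),
                    pm$education)
    for (sc in scoreCols) {
      for (metric in c("fractional_windows", "mean_dwell_time")) {
        for (s in seq_len(k)) {
          sub <- temporal[temporal$state == s &
                            temporal$subject %in% pm$subject_id, ]
          sub <- sub[match(pm$subject_id, sub$subject), ]
          x <- sub[[metric]]
          # treat never-visited states as missing for correlations to
          # avoid zero-inflation
          keep <- !(metric == "mean_dwell_time" & x == 0)
          if (sum(keep) < 10) next
          res <- tryCatch(
            partialCorrelation(x[keep], pm[[sc]][keep],
                               covars[keep, , drop = FALSE]),
            error = function(e) NULL)
          if (!is.null(res))
            correlations[[sprintf("%s_vs_%s_state%d", sc, metric, s)]] <-
              list(r = res$r, p = res$p, n = res$n)
        }
      }
    }
  }

  list(summary = list(mannWhitney = mw,
                      occupancyChisq = occ[c("chisq", "df", "p")],
                      partialCorrelations = correlations),
       edgeTests = edgeTests,
       warnings = warningsLog)
}

# State-wise LOOCV-SVM classification on subject-level state FC.
classifyStates <- function(wfc, model, manifest, nFeatures = 15L,
                           nPerm = 99L, seed = 1L) {
  sequences <- stateSequencesFromModel(model)
  groups <- stats::setNames(manifest$group, manifest$subject_id)
  out <- list()
  for (s in seq_len(model@k)) {
    fcRows <- list(); y <- character()
    for (id in manifest$subject_id) {
      v <- subjectStateFc(wfc[[id]], sequences[[id]], s)
      if (is.null(v)) next
      fcRows[[id]] <- v
      y <- c(y, groups[[id]])
    }
    if (length(unique(y)) < 2 || min(table(y)) < 2) next
    X <- do.call(rbind, fcRows)
    rep <- svmLoocv(X, y, nFeatures, seed = childSeed(seed, s))
    rep$state <- s
    rep$p <- if (nPerm > 0)
      permutationPvalue(X, y, nFeatures, nPerm = nPerm,
                        seed = childSeed(seed, 100L + s),
                        observed = rep)$p
    else NA_real_
    out[[s]] <- rep
  }
  out
}

#' Validate state structure across window lengths
#'
#' Recomputes the windowed connectivity and the k-state clustering at
#' each alternative window length, matches the resulting states to a
#' reference model, and reports matched-centroid correlations plus the
#' Spearman correlation of per-subject fractional windows between each
#' rerun and the reference.
#'
#' @param tcs cleaned [TimecourseSet-class].
#' @param referenceModel fitted [StateModel-class] of the reference run.
#' @param lengths window lengths to test (default `c(15, 20, 25, 30)`).
#' @param sigma,lambda connectivity parameters (as in the reference run).
#' @param nRestarts k-means restarts per rerun (default 20).
#' @param seed integer seed.
#' @return data.frame with one row per (length, state): `windowLength`,
#'   `nWindows`, `state`, `matchedState`, `centroidCorrelation`,
#'   `fwSpearman`.
#' @export
validateWindowLengths <- function(tcs, referenceModel,
                                  lengths = c(15L, 20L, 25L, 30L),
                                  sigma = 3, lambda = 0.1,
                                  nRestarts = 20L, seed = 1L) {
  stopifnot(is(referenceModel, "StateModel"))
  nT <- nrow(tcs@timecourses[[1]])
  if (any(lengths >= nT)) stop("window lengths must be below nTimepoints")
  k <- referenceModel@k
  refSeq <- stateSequencesFromModel(referenceModel)
  refFW <- t(vapply(refSeq, fractionalWindows, numeric(k), k = k))
  rows <- list()
  for (w in lengths) {
    wfc <- computeCohortDfnc(tcs, w, sigma, lambda)
    stacked <- stackWindowedFC(wfc)
    m <- kmeansFit(stacked$X, k, nRestarts,
                   seed = childSeed(seed, 900L + w),
                   subjects = stacked$subjects, windows = stacked$windows)
    mt <- matchStates(referenceModel, m)
    seqs <- stateSequencesFromModel(m)
    fw <- t(vapply(seqs, fractionalWindows, numeric(k), k = k))
    fw <- fw[rownames(refFW), mt$permutation, drop = FALSE]
    for (s in seq_len(k)) {
      rows[[length(rows) + 1L]] <- data.frame(
        windowLength = w,
        nWindows = nT - w,
        state = s,
        matchedState = mt$permutation[s],
        centroidCorrelation = mt$correlations[s],
        fwSpearman = suppressWarnings(
          stats::cor(refFW[, s], fw[, s], method = "spearman"))
      )
    }
  }
  do.call(rbind, rows)
}
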