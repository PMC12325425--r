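#' Write a synthetic cohort to disk
#'
#' One TSV per subject (timepoints x components, header `IC_1..IC_p`),
#' a `manifest.csv`, and a `truth.json` carrying archetype covariances,
#' transition matrices, per-subject latent state sequences and the
#' clinical score model.
#'
#' @param cohort list as returned by [makeCohort()].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tcs <- cohort$timecourses
  paths <- character()
  for (id in tcs@subjectIds) {
    M <- tcs@timecourses[[id]]
    colnames(M) <- paste0("IC_", seq_len(ncol(M)))
    f <- file.path(dir, paste0(id, ".tsv"))
    utils::write.table(M, f, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <- c(paths, f)
  }
  mf <- file.path(dir, "manifest.csv")
  write.csv(cohort$manifest, mf, row.names = FALSE)
  paths <- c(paths, mf)
  if (!is.null(cohort$truth)) {
    truth <- cohort$truth
    tj <- file.path(dir, "truth.json")
    jsonlite::write_json(list(
      archetypes = lapply(truth@archetypes, function(a)
        list(stateId = a@stateId, description = a@description,
             covariance = a@covariance)),
      transitionMatrices = truth@transitionMatrices,
      stateSequences = truth@stateSequences,
      scoreModel = truth@scoreModel,
      trSeconds = tcs@trSeconds
    ), tj, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, tj)
  }
  invisible(paths)
}

#' Read a cohort of time courses from disk
#'
#' Counterpart of [writeCohort()]: reads `manifest.csv` and one TSV per
#' manifest subject. A subject listed in the manifest without a
#' time-course file is an error naming the subject. `truth.json` is
#' reloaded when present.
#'
#' @param dir directory written by [writeCohort()] (or hand-assembled in
#'   the same layout).
#' @param trSeconds repetition time; taken from `truth.json` when
#'   available, otherwise required.
#' @return list with `timecourses`, `manifest` and (possibly `NULL`)
#'   `truth`.
#' @export
readCohort <- function(dir, trSeconds = NULL) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop("manifest.csv not found in ", dir)
  manifest <- read.csv(mf, stringsAsFactors = FALSE)
  truth <- NULL
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) {
    raw <- jsonlite::read_json(tj, simplifyVector = FALSE)
    if (is.null(trSeconds)) trSeconds <- as.numeric(raw$trSeconds)
    asMatrix <- function(rows)
      do.call(rbind, lapply(rows, function(r) as.numeric(unlist(r))))
    archetypes <- lapply(raw$archetypes, function(a)
      new("StateArchetype",
          stateId = as.integer(a$stateId),
          covariance = asMatrix(a$covariance),
          description = as.character(a$description)))
    scoreModel <- if (length(raw$scoreModel))
      lapply(raw$scoreModel, function(x) as.numeric(unlist(x)))
    else list()
    truth <- new("SyntheticTruth",
                 stateSequences = lapply(raw$stateSequences,
                                         function(s) as.integer(unlist(s))),
                 archetypes = archetypes,
                 transitionMatrices = lapply(raw$transitionMatrices,
                                             asMatrix),
                 scoreModel = scoreModel)
  }
  if (is.null(trSeconds))
    stop("trSeconds must be given when truth.json is absent")
  tcs <- list()
  for (id in manifest$subject_id) {
    f <- file.path(dir, paste0(id, ".tsv"))
    if (!file.exists(f)) stop("missing time-course file for subject ", id)
    tcs[[id]] <- as.matrix(utils::read.table(f, header = TRUE, sep = "\t"))
  }
  tcset <- new("TimecourseSet",
               timecourses = lapply(tcs, unname),
               subjectIds = manifest$subject_id,
               trSeconds = trSeconds)
  list(timecourses = tcset, manifest = manifest, truth = truth)
}

#' Write per-subject windowed connectivity
#'
#' One `<subject>.dfnc.tsv` per subject: rows = windows, columns labelled
#' `z_<i>_<j>` following the fixed upper-triangle edge order.
#'
#' @param wfcList named list of [WindowedFC-class].
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
writeWindowedFC <- function(wfcList, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (wfc in wfcList) {
    Z <- wfc@zEdges
    colnames(Z) <- paste0("z_", wfc@edgeIndex[, 1], "_", wfc@edgeIndex[, 2])
    f <- file.path(dir, paste0(wfc@subjectId, ".dfnc.tsv"))
    utils::write.table(Z, f, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <- c(paths, f)
  }
  invisible(paths)
}
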