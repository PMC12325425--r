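#' Fractional windows per state
#'
#' Proportion of a subject's windows assigned to each state.
#'
#' @param labels integer state sequence (one label per window).
#' @param k number of states.
#' @return numeric vector of length k summing to 1.
#' @export
fractionalWindows <- function(labels, k) {
  stopifnot(length(labels) > 0)
  if (any(labels < 1L | labels > k)) stop("state labels must lie in 1..k")
  tabulate(labels, k) / length(labels)
}

#' Mean dwell time per state
#'
#' Mean length (in windows) of the maximal runs of each state; a state
#' never visited has mean dwell 0 by convention.
#'
#' @inheritParams fractionalWindows
#' @return numeric vector of length k.
#' @export
meanDwellTime <- function(labels, k) {
  stopifnot(length(labels) > 0)
  if (any(labels < 1L | labels > k)) stop("state labels must lie in 1..k")
  r <- rle(as.integer(labels))
  out <- numeric(k)
  for (s in seq_len(k)) {
    runs <- r$lengths[r$values == s]
    out[s] <- if (length(runs)) mean(runs) else 0
  }
  out
}

#' Number of state transitions
#'
#' Count of window-to-window changes of state.
#'
#' @param labels integer state sequence.
#' @return integer count in `[0, length(labels) - 1]`.
#' @export
transitionCount <- function(labels) {
  stopifnot(length(labels) > 0)
  sum(labels[-1] != labels[-length(labels)])
}

#' Per-subject state sequences from a fitted model
#'
#' @param model a [StateModel-class].
#' @return named list of integer window-state sequences, in window order.
#' @export
stateSequencesFromModel <- function(model) {
  stopifnot(is(model, "StateModel"))
  labs <- model@labels
  split(labs$state[order(labs$subject, labs$window)],
        labs$subject[order(labs$subject, labs$window)])
}

#' Cohort table of temporal state properties
#'
#' Tidy long table of the three temporal metrics: one row per subject
#' and state carrying fractional windows and mean dwell time, plus the
#' subject's total transition count (repeated across its state rows).
#'
#' @param sequences named list of window-state sequences (e.g. from
#'   [stateSequencesFromModel()]).
#' @param manifest data.frame with columns `subject_id` and `group`
#'   (clinical covariates pass through untouched).
#' @param k number of states.
#' @return data.frame with columns `subject`, `group`, `state`,
#'   `fractional_windows`, `mean_dwell_time`, `n_transitions`.
#' @export
temporalTable <- function(sequences, manifest, k) {
  missing <- setdiff(manifest$subject_id, names(sequences))
  if (length(missing))
    stop("manifest subjects without a state sequence: ",
         paste(missing, collapse = ", "))
  rows <- lapply(manifest$subject_id, function(id) {
    s <- sequences[[id]]
    data.frame(
      subject = id,
      group = manifest$group[manifest$subject_id == id],
      state = seq_len(k),
      fractional_windows = fractionalWindows(s, k),
      mean_dwell_time = meanDwellTime(s, k),
      n_transitions = transitionCount(s),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
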