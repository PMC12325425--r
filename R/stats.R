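#' Mann-Whitney U test with tie-corrected normal approximation
#'
#' U is computed from rank sums with average ranks for ties;
#' `z = (U - n1 n2 / 2) / sqrt(V)` with the tie-corrected variance
#' `V = n1 n2 / 12 * ((n + 1) - sum(t^3 - t) / (n (n - 1)))` and no
#' continuity correction (matching common neuroimaging toolbox output).
#' The two-sided p comes from the normal tail; for small samples an
#' exact p by complete enumeration of group assignments is reported
#' alongside.
#'
#' @param x,y numeric samples (both nonempty).
#' @param exactMax enumerate the exact two-sided p when
#'   `length(x) + length(y) <= exactMax` (default 10).
#' @return list with `U` (for the first sample), `z`, `p` (normal
#'   approximation) and `pExact` (`NA` when not enumerated).
#' @export
mannWhitneyZ <- function(x, y, exactMax = 10L) {
  stopifnot(length(x) > 0, length(y) > 0)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(x, y))
  tieTerm <- sum(ties^3 - ties)
  V <- n1 * n2 / 12 * ((n + 1) - tieTerm / (n * (n - 1)))
  if (V <= 0) {
    z <- 0; p <- 1
  } else {
    z <- (U - n1 * n2 / 2) / sqrt(V)
    p <- 2 * pnorm(-abs(z))
  }
  pExact <- NA_real_
  if (n <= exactMax) {
    pooled <- c(x, y)
    combos <- combn(n, n1)
    rAll <- rank(pooled)
    mid <- n1 * n2 / 2
    obs <- abs(U - mid)
    Us <- apply(combos, 2, function(idx)
      sum(rAll[idx]) - n1 * (n1 + 1) / 2)
    pExact <- mean(abs(Us - mid) >= obs - 1e-12)
  }
  list(U = U, z = z, p = min(p, 1), pExact = pExact)
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson statistic with expected counts from the margins and no
#' continuity correction; df = (r - 1)(c - 1).
#'
#' @param counts contingency matrix (at least 2 x 2, nonnegative).
#' @return list with `chisq`, `df`, `p`.
#' @export
chiSquareCounts <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(counts >= 0), nrow(counts) >= 2, ncol(counts) >= 2)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("contingency table has a zero margin")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(chisq = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Two-sample t-test from summary statistics
#'
#' Welch (unequal-variance, Satterthwaite df) or classical pooled
#' two-sample t from means, SDs and group sizes, as used for
#' demographic-table comparisons.
#'
#' @param m1,s1,n1 mean, sd, n of group 1.
#' @param m2,s2,n2 mean, sd, n of group 2.
#' @param variant `"welch"` (default) or `"pooled"`.
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
tTestFromSummary <- function(m1, s1, n1, m2, s2, n2,
                             variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  stopifnot(s1 >= 0, s2 >= 0, n1 >= 2, n2 >= 2)
  if (variant == "welch") {
    v1 <- s1^2 / n1; v2 <- s2^2 / n2
    se2 <- v1 + v2
    if (se2 == 0) return(list(t = 0, df = n1 + n2 - 2, p = 1))
    t <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    if (sp2 == 0) return(list(t = 0, df = n1 + n2 - 2, p = 1))
    t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Per-subject state-specific connectivity
#'
#' The participant-specific matrix for one state: the mean Fisher-z edge
#' vector over the subject's windows assigned to that state. Subjects
#' with no window in the state return `NULL` and are excluded from that
#' state's group tests.
#'
#' @param wfc a [WindowedFC-class].
#' @param labels integer state label per window of this subject.
#' @param state state id.
#' @return numeric edge vector, or `NULL` if the subject never visits
#'   the state.
#' @export
subjectStateFc <- function(wfc, labels, state) {
  stopifnot(is(wfc, "WindowedFC"), length(labels) == nrow(wfc@zEdges))
  w <- which(labels == state)
  if (length(w) == 0L) return(NULL)
  colMeans(wfc@zEdges[w, , drop = FALSE])
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up BH adjustment (`q_i = min_{j >= rank(i)} m p_(j) / j`, capped
#' at 1) with the rejection mask at level `q`.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return list with `qvalues` and logical `rejected`.
#' @export
bhFdr <- function(p, q = 0.05) {
  stopifnot(all(p >= 0 & p <= 1))
  qv <- stats::p.adjust(p, method = "BH")
  list(qvalues = qv, rejected = qv <= q)
}

#' Edgewise between-group t-tests within one state
#'
#' Welch t-test per edge comparing the two groups' subject-level state
#' connectivity, with BH-FDR across the edges of the state (666 for 37
#' components). States missing an entire group are skipped upstream.
#'
#' @param stateFc subjects x edges matrix of per-subject state
#'   connectivity (rows = subjects with at least one window in the
#'   state).
#' @param groups group label per row of `stateFc` (two levels).
#' @param q FDR level (default 0.05).
#' @param variant `"welch"` (default) or `"pooled"`.
#' @return data.frame with one row per edge: `edge`, `t`, `p`, `q`,
#'   `direction` (group with the larger mean), `n1`, `n2`,
#'   `significant`.
#' @export
edgewiseStateTtests <- function(stateFc, groups, q = 0.05,
                                variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  lev <- unique(groups)
  if (length(lev) != 2) stop("exactly two groups required")
  g1 <- stateFc[groups == lev[1], , drop = FALSE]
  g2 <- stateFc[groups == lev[2], , drop = FALSE]
  if (nrow(g1) < 2 || nrow(g2) < 2)
    stop("at least 2 subjects per group required for the state")
  m1 <- colMeans(g1); m2 <- colMeans(g2)
  s1 <- apply(g1, 2, sd); s2 <- apply(g2, 2, sd)
  res <- mapply(function(a, b, c, d) {
    tt <- tTestFromSummary(a, b, nrow(g1), c, d, nrow(g2), variant)
    c(tt$t, tt$p)
  }, m1, s1, m2, s2)
  fdr <- bhFdr(res[2, ], q)
  data.frame(
    edge = seq_len(ncol(stateFc)),
    t = res[1, ],
    p = res[2, ],
    q = fdr$qvalues,
    direction = ifelse(m1 >= m2, lev[1], lev[2]),
    n1 = nrow(g1),
    n2 = nrow(g2),
    significant = fdr$rejected,
    stringsAsFactors = FALSE
  )
}

#' Partial correlation with covariate adjustment
#'
#' Residualises `x` and `y` on the covariates (with intercept) by least
#' squares and reports the Pearson correlation of the residuals, with
#' `t = r sqrt((n - 2 - k) / (1 - r^2))` on `n - 2 - k` degrees of
#' freedom.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric matrix (n x k) or `NULL` for a plain
#'   Pearson correlation.
#' @return list with `r`, `p`, `n`, `df`.
#' @export
partialCorrelation <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  k <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (n <= k + 2) stop("n must exceed the covariate count + 2")
  sx0 <- sd(x); sy0 <- sd(y)
  if (k > 0) {
    Z <- cbind(1, as.matrix(covariates))
    if (qr(Z)$rank < ncol(Z)) stop("rank-deficient covariates")
    x <- stats::lm.fit(Z, x)$residuals
    y <- stats::lm.fit(Z, y)$residuals
  }
  # residuals numerically indistinguishable from zero (covariates span
  # the variable) leave the correlation undefined
  if (sd(x) <= 1e-10 * max(sx0, 1) || sd(y) <= 1e-10 * max(sy0, 1))
    stop("zero residual variance; correlation undefined")
  r <- cor(x, y)
  df <- n - 2L - k
  t <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * pt(-abs(t), df), n = n, df = df)
}

#' Chi-square test of pooled state occupancy between groups
#'
#' Builds the k x 2 contingency table of pooled window counts per state
#' and group and applies the Pearson chi-square test (df = k - 1).
#' States empty in both groups are collapsed out with a warning.
#'
#' @param model a [StateModel-class].
#' @param groups named character vector: group per subject id.
#' @return list with `chisq`, `df`, `p`, `table`.
#' @export
stateOccupancyChisq <- function(model, groups) {
  stopifnot(is(model, "StateModel"))
  labs <- model@labels
  g <- groups[labs$subject]
  tab <- table(factor(labs$state, levels = seq_len(model@k)), g)
  empty <- rowSums(tab) == 0
  if (any(empty)) {
    warning("collapsing states with no windows: ",
            paste(which(empty), collapse = ", "))
    tab <- tab[!empty, , drop = FALSE]
  }
  ct <- chiSquareCounts(tab)
  c(ct, list(table = tab))
}
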