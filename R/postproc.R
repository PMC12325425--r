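#' Polynomial detrending
#'
#' Removes the least-squares polynomial of the given degree from a
#' component time course, eliminating slow scanner drift before windowed
#' covariance estimation.
#'
#' @param x numeric vector (one component's time course).
#' @param order polynomial degree (default 1, linear).
#' @return detrended vector of the same length.
#' @export
detrendTimecourse <- function(x, order = 1L) {
  stopifnot(order >= 0, length(x) > order + 1, all(is.finite(x)))
  n <- length(x)
  t <- seq_len(n) / n
  X <- outer(t, 0:order, "^")
  fit <- stats::lm.fit(X, x)
  as.numeric(fit$residuals)
}

#' Despike a time course
#'
#' Robust spike attenuation in the style of AFNI's 3dDespike: a
#' polynomial baseline is fit, residuals are standardised by the
#' MAD-based robust sigma (1.4826 * median absolute residual), and
#' residuals beyond `c1` sigmas are compressed through a tanh so that no
#' output residual exceeds `c2` sigmas. A constant series (sigma = 0) is
#' returned unchanged.
#'
#' @param x numeric vector.
#' @param c1 spike threshold in robust sigmas (default 2.5).
#' @param c2 asymptotic cap in robust sigmas (default 4); must exceed `c1`.
#' @param fitOrder baseline polynomial degree (default 4).
#' @return despiked vector.
#' @export
despikeTimecourse <- function(x, c1 = 2.5, c2 = 4, fitOrder = 4L) {
  stopifnot(c2 > c1, c1 > 0, all(is.finite(x)), length(x) > fitOrder + 1)
  n <- length(x)
  t <- seq_len(n) / n
  X <- outer(t, 0:fitOrder, "^")
  fit <- stats::lm.fit(X, x)
  baseline <- x - fit$residuals
  resid <- as.numeric(fit$residuals)
  sigma <- 1.4826 * median(abs(resid))
  if (sigma == 0) return(x)
  s <- resid / sigma
  over <- s > c1
  under <- s < -c1
  s[over] <- c1 + (c2 - c1) * tanh((s[over] - c1) / (c2 - c1))
  s[under] <- -(c1 + (c2 - c1) * tanh((-s[under] - c1) / (c2 - c1)))
  baseline + sigma * s
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies an order-`order` Butterworth low-pass forward and backward
#' (zero phase). The effective gain is the squared magnitude response,
#' so the gain at the cutoff is 0.5 rather than the single-pass 0.707;
#' DC gain is 1.
#'
#' @param x numeric vector.
#' @param trSeconds sampling interval in seconds.
#' @param cutoffHz cutoff frequency in Hz (default 0.15); must lie below
#'   the Nyquist frequency 1/(2 tr).
#' @param order filter order (default 5).
#' @return filtered vector.
#' @export
butterworthLowpass <- function(x, trSeconds, cutoffHz = 0.15, order = 5L) {
  nyquist <- 1 / (2 * trSeconds)
  if (cutoffHz <= 0 || cutoffHz >= nyquist)
    stop("cutoff must lie in (0, Nyquist)")
  bf <- signal::butter(order, cutoffHz / nyquist, type = "low")
  # filtfilt is zero-phase but assumes zero boundary state; remove the
  # mean first and restore it so the DC level passes through exactly.
  m <- mean(x)
  as.numeric(signal::filtfilt(bf, x - m)) + m
}

#' Spectral quality metrics of a component time course
#'
#' Periodogram-based inclusion metrics for independent components:
#' `dynamicRange` is the difference between the peak spectral power and
#' the minimum spectral power at frequencies above the peak, and
#' `lowHighPowerRatio` is the power below `lowHz` divided by the power
#' above `highHz` (resting-state components are dominated by
#' low-frequency signal, so credible components have a large ratio).
#'
#' @param x numeric vector, length >= 64.
#' @param trSeconds sampling interval in seconds.
#' @param lowHz upper edge of the low band (default 0.10 Hz).
#' @param highHz lower edge of the high band (default 0.15 Hz).
#' @return list with `dynamicRange` and `lowHighPowerRatio`.
#' @export
qcMetrics <- function(x, trSeconds, lowHz = 0.10, highHz = 0.15) {
  stopifnot(length(x) >= 64, all(is.finite(x)))
  n <- length(x)
  xc <- x - mean(x)
  spec <- Mod(stats::fft(xc))^2 / n
  nf <- floor(n / 2)
  freq <- (1:nf) / (n * trSeconds)
  power <- spec[2:(nf + 1L)]
  if (sum(power) == 0) stop("zero total power")
  peak <- which.max(power)
  dynamicRange <- if (peak < nf)
    power[peak] - min(power[peak:nf])
  else 0
  lowP <- sum(power[freq < lowHz])
  highP <- sum(power[freq > highHz])
  ratio <- if (highP == 0) Inf else lowP / highP
  list(dynamicRange = dynamicRange, lowHighPowerRatio = ratio)
}

#' Post-process a cohort of component time courses
#'
#' Applies the fixed cleaning cascade detrend -> despike -> zero-phase
#' Butterworth low-pass to every component of every subject.
#'
#' @param tcs a [TimecourseSet-class].
#' @param detrendOrder polynomial degree for detrending (default 1).
#' @param c1,c2 despiking thresholds in robust sigmas.
#' @param despikeOrder despiking baseline polynomial degree.
#' @param cutoffHz low-pass cutoff (default 0.15 Hz).
#' @param filterOrder Butterworth order (default 5).
#' @return a new [TimecourseSet-class] with cleaned series.
#' @export
postprocessTimecourses <- function(tcs, detrendOrder = 1L, c1 = 2.5, c2 = 4,
                                   despikeOrder = 4L, cutoffHz = 0.15,
                                   filterOrder = 5L) {
  stopifnot(is(tcs, "TimecourseSet"))
  cleaned <- lapply(tcs@timecourses, function(M) {
    apply(M, 2, function(x) {
      x <- detrendTimecourse(x, detrendOrder)
      x <- despikeTimecourse(x, c1, c2, despikeOrder)
      butterworthLowpass(x, tcs@trSeconds, cutoffHz, filterOrder)
    })
  })
  new("TimecourseSet", timecourses = cleaned, subjectIds = tcs@subjectIds,
      trSeconds = tcs@trSeconds)
}
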