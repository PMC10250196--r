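## dF/F0 trace statistics: baseline normalization, peak SBR / SNR,
## half-decay time, ratiometric correction and the responsive-cell test.

## Internal: sample indices within [start, end).
.inWindow <- function(time, window)
  time >= window[1] - 1e-12 & time < window[2] - 1e-12

#' Baseline-normalized fluorescence change dF/F0
#'
#' F0 is the mean fluorescence over the baseline window (by convention the
#' 1 s preceding stimulus onset in vivo, 0.5 s for slice-style data); the
#' response is (F - F0) / F0 samplewise. A background fluorescence level,
#' if supplied, is subtracted from the whole trace first.
#'
#' @param trace a \linkS4class{FluorescenceTrace} whose baseline window
#'   holds >= 3 samples.
#' @param background background fluorescence level to subtract (a.u.).
#' @return numeric dF/F0 series (same length as the trace), with
#'   attribute \code{"f0"}.
#' @export
deltaFOverF <- function(trace, background = 0) {
  stopifnot(is(trace, "FluorescenceTrace"))
  f <- trace@f - background
  idx <- .inWindow(trace@time, trace@baselineWindow)
  if (sum(idx) < 3)
    stop("baseline window contains fewer than 3 samples", call. = FALSE)
  f0 <- mean(f[idx])
  if (!is.finite(f0) || f0 <= 0)
    stop("baseline error: mean baseline fluorescence must be positive ",
         "(check background subtraction)", call. = FALSE)
  out <- (f - f0) / f0
  attr(out, "f0") <- f0
  out
}

#' Peak dF/F0 (SBR) and peak SNR of a stimulus response
#'
#' The peak signal-to-baseline ratio is the maximal dF/F0 within the
#' response window after the first stimulus onset; the peak SNR divides it
#' by the standard deviation of the baseline dF/F0:
#' peak SNR = peak dF/F0 / SD_baseline.
#'
#' @param trace a \linkS4class{FluorescenceTrace} with >= 1 stimulus onset.
#' @param responseWindow seconds after onset searched for the peak.
#' @param background passed to \code{\link{deltaFOverF}}.
#' @return list with \code{peakSBR}, \code{sdBaseline}, \code{peakSNR} and
#'   \code{tPeak}. A zero baseline variance (noiseless input) yields
#'   \code{peakSNR = Inf}, flagged by \code{zeroBaselineSD = TRUE} rather
#'   than an error.
#' @export
peakSNR <- function(trace, responseWindow = 6, background = 0) {
  stopifnot(is(trace, "FluorescenceTrace"))
  if (!length(trace@stimOnsets))
    stop("trace has no stimulus onsets", call. = FALSE)
  dff <- deltaFOverF(trace, background)
  onset <- min(trace@stimOnsets)
  base <- dff[.inWindow(trace@time, trace@baselineWindow)]
  resp <- .inWindow(trace@time, c(onset, onset + responseWindow))
  if (!any(resp))
    stop("no samples in the response window", call. = FALSE)
  peak <- max(dff[resp])
  tPeak <- trace@time[resp][which.max(dff[resp])]
  sdB <- stats::sd(base)
  zero <- !is.finite(sdB) || sdB == 0
  if (zero)
    warning("zero baseline variance: peak SNR is infinite/undefined")
  list(peakSBR = peak, sdBaseline = sdB,
       peakSNR = if (zero) Inf else peak / sdB,
       tPeak = tPeak, zeroBaselineSD = zero)
}

#' Half-decay time of a Ca2+ transient
#'
#' Locates the response peak after the first stimulus onset and fits a
#' single exponential dF/F0(t) = A exp(-(t - t_peak)/tau) + c from the peak
#' to the end of the response window (trust-region least squares, A and tau
#' constrained positive, tau initialized from the time to fall to 1/e of
#' the peak). The half-decay time is ln(2) tau.
#'
#' @param trace a \linkS4class{FluorescenceTrace}.
#' @param responseWindow seconds after onset searched for peak and decay.
#' @param background passed to \code{\link{deltaFOverF}}.
#' @return half-decay time (s), with attributes \code{"tau"},
#'   \code{"amplitude"}, \code{"offset"} and \code{"tPeak"}.
#' @export
halfDecayTime <- function(trace, responseWindow = 6, background = 0) {
  stopifnot(is(trace, "FluorescenceTrace"))
  if (!length(trace@stimOnsets))
    stop("trace has no stimulus onsets", call. = FALSE)
  dff <- as.numeric(deltaFOverF(trace, background))
  onset <- min(trace@stimOnsets)
  resp <- which(.inWindow(trace@time, c(onset, onset + responseWindow)))
  if (length(resp) < 6)
    stop("response window too short to identify a peak plus decay",
         call. = FALSE)
  iPeak <- resp[which.max(dff[resp])]
  decay <- iPeak:max(resp)
  if (length(decay) < 6)
    stop("need at least 5 samples of decay after the peak", call. = FALSE)
  t <- trace@time[decay] - trace@time[iPeak]
  y <- dff[decay]
  if (y[length(y)] >= y[1])
    warning("tail is not decaying; half-decay fit quality suspect")
  c0 <- min(y)
  a0 <- max(y[1] - c0, 1e-9)
  below <- which(y <= c0 + a0 / exp(1))
  tau0 <- if (length(below)) max(t[below[1]], diff(range(t)) / 50)
          else diff(range(t)) / 2
  df <- data.frame(t = t, y = y)
  fit <- minpack.lm::nlsLM(y ~ A * exp(-t / tau) + c0f, data = df,
                           start = list(A = a0, tau = tau0, c0f = c0),
                           lower = c(A = 1e-12, tau = 1e-9, c0f = -Inf),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  out <- log(2) * unname(cf["tau"])
  attr(out, "tau") <- unname(cf["tau"])
  attr(out, "amplitude") <- unname(cf["A"])
  attr(out, "offset") <- unname(cf["c0f"])
  attr(out, "tPeak") <- trace@time[iPeak]
  out
}

#' Ratiometric trace from signal and reference excitation channels
#'
#' Divides the Ca2+-sensitive channel (488/470-nm excitation) by the
#' Ca2+-independent reference channel (405/410-nm excitation) samplewise
#' after linear interpolation of both channels onto the signal time grid
#' (no extrapolation: samples outside the overlap are dropped). Common
#' multiplicative artifacts - motion, focus drift - cancel in the ratio;
#' anticorrelated channels (excitation-ratiometric sensors) amplify the
#' response instead.
#'
#' @param signal \linkS4class{FluorescenceTrace}, Ca2+-sensitive channel.
#' @param reference \linkS4class{FluorescenceTrace}, reference channel;
#'   must be strictly positive over the overlap.
#' @return a \linkS4class{FluorescenceTrace} holding the ratio on the
#'   common grid (baseline window and onsets carried over from the signal
#'   channel), suitable for \code{\link{deltaFOverF}} to obtain dR/R0.
#' @export
ratiometric <- function(signal, reference) {
  stopifnot(is(signal, "FluorescenceTrace"),
            is(reference, "FluorescenceTrace"))
  lo <- max(signal@time[1], reference@time[1])
  hi <- min(max(signal@time), max(reference@time))
  if (lo >= hi)
    stop("signal and reference have no overlapping time support",
         call. = FALSE)
  keep <- signal@time >= lo & signal@time <= hi
  tt <- signal@time[keep]
  ref <- stats::approx(reference@time, reference@f, xout = tt)$y
  if (any(ref <= 0))
    stop("channel error: reference crosses zero or negative values",
         call. = FALSE)
  FluorescenceTrace(tt, signal@f[keep] / ref,
                    baselineWindow = signal@baselineWindow,
                    stimOnsets = signal@stimOnsets)
}

#' Responsive-cell test
#'
#' Two-sample Student's t-test (classical equal-variance, two-tailed)
#' between the per-trial stimulus-window and baseline-window dF/F0 means;
#' a cell is called responsive when p < 0.01 at its optimal stimulus.
#'
#' @param stimMeans per-trial mean dF/F0 in the stimulus window (>= 2
#'   trials).
#' @param baselineMeans per-trial mean dF/F0 in the baseline window.
#' @param alpha significance threshold (default 0.01).
#' @param welch logical; use the Welch unequal-variance variant instead.
#' @return list with \code{p}, \code{responsive}, \code{statistic} and
#'   \code{df}.
#' @export
responsiveCellTest <- function(stimMeans, baselineMeans, alpha = 0.01,
                               welch = FALSE) {
  if (length(stimMeans) < 2 || length(baselineMeans) < 2)
    stop("insufficient replication: need >= 2 trials per condition",
         call. = FALSE)
  tt <- stats::t.test(stimMeans, baselineMeans, var.equal = !welch,
                      alternative = "two.sided")
  list(p = tt$p.value, responsive = tt$p.value < alpha,
       statistic = unname(tt$statistic), df = unname(tt$parameter))
}
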