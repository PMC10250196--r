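## Photochromism-enabled absolute [Ca2+] quantification (iPEAQ).
##
## Violet (405 nm) illumination superimposed on continuous 488-nm excitation
## drives the chromophore into a brighter state; under 488 nm only it
## relaxes back. The fractional drop per cycle - the photochromism contrast
## ((F0 - F_end)/F0)_hv - decreases with [Ca2+] and, unlike raw
## fluorescence, is a ratio and therefore independent of expression level
## and detector gain. Inverting an in vitro contrast calibration yields the
## absolute basal [Ca2+]; matching the in vitro fluorescence curve at that
## concentration to the measured basal fluorescence yields the gain factor
## that converts the whole live trace to [Ca2+](t).

#' Detect photochromic cycles and their contrast
#'
#' Segments a \linkS4class{PhotochromicTrace} into violet-illumination
#' epochs (contiguous blocks of \code{violetOn}), and for each cycle
#' measures the violet-elevated fluorescence (F0_hv), the relaxed
#' fluorescence under 488 nm only (F_end, within the window up to the next
#' violet onset), and the photochromism contrast (F0_hv - F_end)/F0_hv.
#' A cycle still decaying appreciably at the end of its relaxation window
#' - the mean fluorescence over the final fifth of the window sitting more
#' than 5\% of the total drop below the mean over the preceding fifth - is
#' flagged incomplete.
#'
#' With \code{robust = TRUE} (default) the two levels are estimated as
#' segment means of the plateaus they represent - the second half of the
#' violet epoch (photostationary level, rise excluded) and the final fifth
#' of the relaxation window (settled level) - which are unbiased under
#' per-sample noise. \code{robust = FALSE} takes the literal epoch maximum
#' and post-epoch minimum instead; note that raw extrema of many noisy
#' samples are biased outward and inflate the contrast.
#'
#' @param trace a \linkS4class{PhotochromicTrace} with >= 1 complete cycle.
#' @param robust logical; estimate the levels by plateau means (default)
#'   rather than raw extrema.
#' @return data.frame with one row per cycle: \code{tOn}, \code{tOff},
#'   \code{f0hv}, \code{fEnd}, \code{contrast}, \code{complete}.
#' @export
detectCycles <- function(trace, robust = TRUE) {
  stopifnot(is(trace, "PhotochromicTrace"))
  v <- trace@violetOn
  if (!any(v))
    stop("no violet epoch in trace", call. = FALSE)
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  on <- which(r$values)
  out <- lapply(seq_along(on), function(j) {
    i <- on[j]
    epoch <- starts[i]:ends[i]
    relaxEnd <- if (j < length(on)) starts[on[j + 1]] - 1
                else length(trace@f)
    if (ends[i] >= relaxEnd) return(NULL)   # no relaxation window
    relax <- (ends[i] + 1):relaxEnd
    n <- length(relax)
    seg <- function(a, b) mean(trace@f[relax[max(1L, ceiling(a * n)):
                                             max(1L, floor(b * n))]])
    if (robust) {
      f0 <- mean(trace@f[epoch[max(1L, ceiling(length(epoch) / 2)):
                               length(epoch)]])
      fEnd <- seg(0.8, 1)
    } else {
      f0 <- max(trace@f[epoch])
      fEnd <- min(trace@f[relax])
    }
    ## residual decay between the penultimate and final fifths of the
    ## relaxation window (segment means: robust to sampling noise)
    residual <- seg(0.6, 0.8) - seg(0.8, 1)
    data.frame(tOn = trace@time[starts[i]], tOff = trace@time[ends[i]],
               f0hv = f0, fEnd = fEnd,
               contrast = (f0 - fEnd) / f0,
               complete = f0 <= fEnd || residual <= 0.05 * (f0 - fEnd))
  })
  out <- do.call(rbind, out)
  if (is.null(out) || !nrow(out))
    stop("no complete cycle (violet on -> off -> relaxation) in trace",
         call. = FALSE)
  out
}

#' Fit the iPEAQ dual calibration
#'
#' Fits Hill curves to the two in vitro dose-response measurements that
#' iPEAQ inverts: photochromism contrast versus free [Ca2+] (monotone
#' decreasing) and fluorescence versus free [Ca2+] (monotone increasing).
#'
#' @param ca free [Ca2+] values (nM) of the contrast titration.
#' @param contrast photochromism contrast at each \code{ca}.
#' @param fluor fluorescence at each \code{caFluor}.
#' @param caFluor free [Ca2+] values (nM) of the fluorescence titration
#'   (defaults to \code{ca}).
#' @return an \linkS4class{IPEAQCalibration}.
#' @export
fitCalibrations <- function(ca, contrast, fluor, caFluor = ca) {
  stopifnot(length(ca) == length(contrast),
            length(caFluor) == length(fluor))
  if (stats::sd(contrast) > 0 &&
      stats::cor(log10(pmax(ca, min(ca[ca > 0]) / 10)), contrast) > 0)
    stop("orientation error: photochromism contrast must decrease with ",
         "[Ca2+]", call. = FALSE)
  cFit <- .fitHill4(ca, contrast, decreasing = TRUE)
  fFit <- .fitHill4(caFluor, fluor, decreasing = FALSE)
  new("IPEAQCalibration", contrastCurve = cFit, fluorCurve = fFit)
}

## Internal: basal fluorescence from the pre-stimulus 488-only segments.
## The relaxation tail after each violet epoch decays toward the true
## baseline, so only the final quarter of each inter-cycle gap (where the
## relaxation has settled) enters the mean.
.basalFluorescence <- function(trace, cycles, tMax) {
  segs <- lapply(seq_len(nrow(cycles)), function(j) {
    lo <- cycles$tOff[j]
    hi <- if (j < nrow(cycles)) cycles$tOn[j + 1] else tMax
    if (hi <= lo) return(numeric())
    start <- hi - (hi - lo) / 4
    trace@f[!trace@violetOn & trace@time > start & trace@time <= hi]
  })
  vals <- unlist(segs)
  if (!length(vals))
    stop("no 488-only samples available to estimate basal fluorescence",
         call. = FALSE)
  mean(vals)
}

#' Convert a live photochromic trace to absolute [Ca2+]
#'
#' The live trace must begin with one or more photochromic cycles before
#' the stimulus period. The steps are: (1) basal contrast = mean contrast
#' over the complete pre-stimulus cycles; (2) basal [Ca2+] by analytic
#' inversion of the contrast calibration; (3) normalizing factor
#' k = fluorCurve(basal [Ca2+]) / measured basal fluorescence, which
#' absorbs expression level and detector gain; (4) [Ca2+](t) by inversion
#' of the fluorescence calibration applied to k F(t), clipped to the
#' calibrated range with out-of-range flags. Samples recorded during
#' violet illumination (and, optionally, a settling window after each
#' epoch while the photochromic state relaxes) are returned as NA.
#'
#' @param live a \linkS4class{PhotochromicTrace}.
#' @param calibration an \linkS4class{IPEAQCalibration}.
#' @param stimStart time (s) at which the stimulus period begins; only
#'   cycles before it enter the basal estimate (default: all cycles).
#' @param settle seconds after each violet epoch to blank while the
#'   photochromic state relaxes (default 0).
#' @param clip fractional plateau margin for the analytic Hill inversions.
#' @return list with \code{time}, \code{ca} (nM, NA where blanked),
#'   \code{outOfRange} (logical), \code{basalContrast}, \code{basalCa}
#'   (nM), \code{k} and \code{cycles} (the pre-stimulus cycle table).
#' @export
quantifyCalcium <- function(live, calibration, stimStart = NULL,
                            settle = 0, clip = 0.005) {
  stopifnot(is(live, "PhotochromicTrace"),
            is(calibration, "IPEAQCalibration"))
  ## basal cycles come from the pre-stimulus portion only, so that a
  ## stimulus transient cannot contaminate the last relaxation window
  basalTrace <- live
  if (!is.null(stimStart)) {
    keep <- live@time < stimStart
    basalTrace <- PhotochromicTrace(live@time[keep], live@f[keep],
                                    live@violetOn[keep])
  }
  cycles <- detectCycles(basalTrace)
  if (!nrow(cycles))
    stop("no pre-stimulus photochromic cycle in the live trace",
         call. = FALSE)
  used <- cycles[cycles$complete, , drop = FALSE]
  if (!nrow(used))
    stop("all pre-stimulus cycles have incomplete relaxation", call. = FALSE)
  basalContrast <- mean(used$contrast)
  cc <- calibration@contrastCurve
  lo <- min(cc@y0, cc@yInf); hi <- max(cc@y0, cc@yInf)
  if (basalContrast <= lo + clip * (hi - lo) ||
      basalContrast >= hi - clip * (hi - lo))
    stop("out-of-calibration error: basal contrast ",
         signif(basalContrast, 4), " lies at or beyond the contrast-curve ",
         "plateaus and cannot be inverted", call. = FALSE)
  basalCa <- as.numeric(hillInverse(cc, basalContrast, clip = clip))
  basalF <- .basalFluorescence(basalTrace, cycles, max(basalTrace@time))
  if (basalF <= 0)
    stop("input error: basal fluorescence must be positive", call. = FALSE)
  k <- hillEval(calibration@fluorCurve, basalCa) / basalF
  if (!is.finite(k) || k <= 0)
    stop("input error: normalizing factor k must be positive",
         call. = FALSE)
  ca <- hillInverse(calibration@fluorCurve, k * live@f, clip = clip)
  oor <- attr(ca, "outOfRange")
  ca <- as.numeric(ca)
  blank <- live@violetOn
  if (settle > 0) {
    allCycles <- detectCycles(live)
    for (j in seq_len(nrow(allCycles)))
      blank <- blank | (live@time > allCycles$tOff[j] &
                        live@time <= allCycles$tOff[j] + settle)
  }
  ca[blank] <- NA_real_
  oor[blank] <- NA
  list(time = live@time, ca = ca, outOfRange = oor,
       basalContrast = basalContrast, basalCa = basalCa, k = k,
       cycles = cycles)
}
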