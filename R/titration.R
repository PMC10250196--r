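## In vitro Ca2+ titration: free-Ca2+ computation in EGTA-buffered mixes,
## Hill dose-response fitting, dynamic range and off-rate kinetics.

#' Free [Ca2+] in an EGTA / Ca-EGTA reciprocal-dilution mix
#'
#' Titration solutions are made by mixing equal-chelator EGTA and Ca-EGTA
#' stocks (10 mM each) in varying volume ratios. With total chelator equal
#' in both stocks, the buffered free calcium follows the reciprocal-dilution
#' relation [Ca2+]_free = Kd_EGTA x f / (1 - f), where f is the volume
#' fraction of the Ca-EGTA stock.
#'
#' @param fracCaEGTA volume fraction(s) of the Ca-EGTA stock, in [0, 1).
#' @param kdEGTA EGTA-Ca2+ dissociation constant (nM); default 150 nM
#'   (pH 7.2, ~0.1 M ionic strength, 22 C).
#' @return free [Ca2+] in nM.
#' @examples
#' freeCalcium(c(0, 0.5, 0.75))   # 0, 150, 450 nM
#' @export
freeCalcium <- function(fracCaEGTA, kdEGTA = 150) {
  stopifnot(kdEGTA > 0)
  if (any(fracCaEGTA < 0 | fracCaEGTA > 1))
    stop("fracCaEGTA must lie in [0, 1]", call. = FALSE)
  if (any(fracCaEGTA == 1))
    stop("saturated buffer: at fraction 1 the free [Ca2+] is unbounded",
         call. = FALSE)
  kdEGTA * fracCaEGTA / (1 - fracCaEGTA)
}

#' Fit a Hill dose-response curve to a Ca2+ titration
#'
#' Least-squares fit of the specific-binding-with-Hill-slope model
#' F([Ca]) = F_min + (F_max - F_min) [Ca]^h / (Kd^h + [Ca]^h) to a
#' fluorescence titration. Initialization: plateaus from the 5th/95th
#' fluorescence percentiles, Kd from the concentration nearest half-range,
#' h start 2.
#'
#' @param curve a \linkS4class{TitrationCurve} with >= 5 concentrations
#'   spanning the transition.
#' @return the input curve with its \code{fit} slot set to a
#'   \linkS4class{HillFit} (increasing orientation: y0 = F_min,
#'   yInf = F_max).
#' @seealso \code{\link{dynamicRange}}, \code{\link{hillEval}}
#' @export
fitHill <- function(curve) {
  stopifnot(is(curve, "TitrationCurve"))
  fit <- .fitHill4(curve@caFree, curve@fluorescence, decreasing = FALSE,
                   hStart = 2)
  curve@fit <- fit
  curve
}

#' Dynamic range of a sensor
#'
#' DR = (F_max - F_min) / F_min between the Ca2+-saturated and
#' Ca2+-depleted fluorescence plateaus. By default the fitted plateaus of a
#' Hill fit are used; raw extremes inflate DR when the minimal fluorescence
#' sits near the background level, so inaccurate background subtraction
#' shows up as an implausibly large raw DR.
#'
#' @param fMax saturating fluorescence, or a fitted
#'   \linkS4class{TitrationCurve} (then \code{fMin} is ignored).
#' @param fMin fluorescence at zero Ca2+; must be positive.
#' @param raw logical; when a fitted curve is given, use the raw
#'   min/max fluorescence instead of the fitted plateaus (flagged via the
#'   \code{"raw"} attribute).
#' @return the dynamic range (dimensionless).
#' @examples
#' dynamicRange(423.2, 1)   # 422.2
#' @export
dynamicRange <- function(fMax, fMin = NULL, raw = FALSE) {
  if (is(fMax, "TitrationCurve")) {
    curve <- fMax
    if (raw) {
      fMin <- min(curve@fluorescence)
      fMax <- max(curve@fluorescence)
    } else {
      if (is.null(curve@fit))
        stop("curve has no Hill fit; run fitHill() first", call. = FALSE)
      fMin <- fMin(curve@fit)
      fMax <- fMax(curve@fit)
    }
  }
  if (is.null(fMin) || !is.finite(fMin) || fMin <= 0)
    stop("background-subtraction error: F_min must be positive (minimal ",
         "fluorescence at or below background makes DR ill-defined)",
         call. = FALSE)
  dr <- (fMax - fMin) / fMin
  attr(dr, "raw") <- raw
  dr
}

#' Off-rate from a Ca2+-removal kinetic trace
#'
#' Fits a single-exponential decay F(t) = F_plateau + A exp(-koff t) to the
#' fluorescence recorded after rapid mixing with excess EGTA, and returns
#' the off-rate.
#'
#' @param trace a \linkS4class{KineticTrace} with >= 10 samples covering at
#'   least ~2 e-folds of decay.
#' @return the trace with \code{koff} set and the fit details (plateau,
#'   amplitude, half-time ln2/koff, standard errors) in its \code{fit}
#'   slot.
#' @export
fitKoff <- function(trace) {
  stopifnot(is(trace, "KineticTrace"))
  t <- trace@time; f <- trace@fluorescence
  if (length(t) < 10)
    stop("need at least 10 samples", call. = FALSE)
  if (diff(range(f)) < 1e-12 * max(abs(f), 1))
    stop("unidentifiable off-rate: trace is flat", call. = FALSE)
  if (stats::cor(t, f) > 0)
    warning("trace is rising, not decaying; koff sign suspect")
  plateau0 <- mean(utils::tail(f, max(3, length(f) %/% 10)))
  a0 <- f[1] - plateau0
  ## time to fall to 1/e of the initial amplitude
  target <- plateau0 + a0 / exp(1)
  below <- which(if (a0 >= 0) f <= target else f >= target)
  k0 <- if (length(below)) 1 / max(t[below[1]], diff(range(t)) / 100)
        else 1 / diff(range(t))
  df <- data.frame(t = t, f = f)
  fit <- tryCatch(
    minpack.lm::nlsLM(f ~ plateau + A * exp(-k * t), data = df,
                      start = list(plateau = plateau0, A = a0, k = k0),
                      lower = c(plateau = -Inf, A = -Inf, k = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("unidentifiable off-rate: exponential fit failed (",
           conditionMessage(e), ")", call. = FALSE))
  cf <- stats::coef(fit)
  k <- unname(cf["k"])
  span <- k * diff(range(t))
  if (span < 2)
    stop("unidentifiable off-rate: trace covers only ", signif(span, 3),
         " e-folds of decay (need >= 2)", call. = FALSE)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  names(se) <- c("plateau", "A", "k")
  trace@koff <- k
  trace@fit <- list(plateau = unname(cf["plateau"]), A = unname(cf["A"]),
                    halfTime = log(2) / k, se = se)
  trace
}

#' @describeIn fitKoff fitted off-rate accessor (s-1)
#' @param trace a fitted \linkS4class{KineticTrace}.
#' @export
koff <- function(trace) trace@koff
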