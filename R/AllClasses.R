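#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))
setClassUnion("listOrNULL", c("list", "NULL"))

## ---------------------------------------------------------------------------
## Spectra
## ---------------------------------------------------------------------------

#' Absorbance spectrum of a GECI chromophore
#'
#' One wavelength-indexed absorbance curve with the buffer conditions under
#' which it was recorded. The wavelength grid must be strictly increasing and,
#' for band quantification, cover at least 380-540 nm (both protonation
#' bands).
#'
#' @slot wavelength numeric, strictly increasing wavelength grid (nm).
#' @slot absorbance numeric, optical density per wavelength (dimensionless).
#' @slot ph numeric(1), buffer pH.
#' @slot caState character(1), \code{"ca_free"} or \code{"ca_saturated"}.
#' @slot mgPresent logical(1), whether Mg2+ was present.
#'
#' @export
setClass("AbsorbanceSpectrum",
  representation(
    wavelength = "numeric",
    absorbance = "numeric",
    ph         = "numeric",
    caState    = "character",
    mgPresent  = "logical"
  ),
  prototype(ph = NA_real_, caState = "ca_free", mgPresent = FALSE)
)

setValidity("AbsorbanceSpectrum", function(object) {
  msg <- character()
  if (length(object@wavelength) != length(object@absorbance))
    msg <- c(msg, "wavelength and absorbance must have the same length")
  if (length(object@wavelength) > 1 && any(diff(object@wavelength) <= 0))
    msg <- c(msg, "wavelength grid must be strictly increasing")
  if (any(!is.finite(object@absorbance)))
    msg <- c(msg, "absorbance values must be finite")
  if (!object@caState %in% c("ca_free", "ca_saturated"))
    msg <- c(msg, "caState must be 'ca_free' or 'ca_saturated'")
  if (length(msg)) msg else TRUE
})

#' Construct an AbsorbanceSpectrum
#'
#' @param wavelength strictly increasing wavelength grid (nm).
#' @param absorbance optical density at each wavelength.
#' @param ph buffer pH.
#' @param caState \code{"ca_free"} or \code{"ca_saturated"}.
#' @param mgPresent logical, Mg2+ present in the buffer.
#' @return an \linkS4class{AbsorbanceSpectrum}.
#' @examples
#' wl <- 350:700
#' sp <- AbsorbanceSpectrum(wl, exp(-(wl - 509)^2 / 200) * 0.5, ph = 7.2)
#' @export
AbsorbanceSpectrum <- function(wavelength, absorbance, ph = NA_real_,
                               caState = "ca_free", mgPresent = FALSE) {
  new("AbsorbanceSpectrum",
      wavelength = as.numeric(wavelength),
      absorbance = as.numeric(absorbance),
      ph = as.numeric(ph), caState = caState, mgPresent = mgPresent)
}

#' @exportMethod show
setMethod("show", "AbsorbanceSpectrum", function(object) {
  cat("AbsorbanceSpectrum:", length(object@wavelength), "points,",
      sprintf("%.0f-%.0f nm,", min(object@wavelength), max(object@wavelength)),
      "pH", object@ph, sprintf("(%s)\n", object@caState))
})

#' @describeIn AbsorbanceSpectrum wavelength grid accessor
#' @param object,x an AbsorbanceSpectrum.
#' @export
wavelength <- function(x) x@wavelength

#' @describeIn AbsorbanceSpectrum absorbance accessor
#' @export
absorbance <- function(x) x@absorbance

#' pH titration series of absorbance spectra
#'
#' A collection of \linkS4class{AbsorbanceSpectrum} objects at several
#' (non-denaturing) pH values plus exactly one alkaline-denatured spectrum
#' (pH >= 12), all sharing the same Ca2+ state. This is the input to the
#' extinction-coefficient pipeline.
#'
#' @slot spectra list of \linkS4class{AbsorbanceSpectrum}, the titration
#'   points (typically pH 7, 7.2, 8, 9).
#' @slot denatured \linkS4class{AbsorbanceSpectrum}, the denatured spectrum.
#'
#' @export
setClass("PHSeries",
  representation(spectra = "list", denatured = "AbsorbanceSpectrum"))

setValidity("PHSeries", function(object) {
  msg <- character()
  if (length(object@spectra) < 3)
    msg <- c(msg, "need at least 3 non-denatured pH points")
  if (!all(vapply(object@spectra, is, logical(1), "AbsorbanceSpectrum")))
    msg <- c(msg, "spectra must all be AbsorbanceSpectrum objects")
  else {
    st <- vapply(object@spectra, function(s) s@caState, character(1))
    if (length(unique(c(st, object@denatured@caState))) != 1)
      msg <- c(msg, "all spectra (incl. denatured) must share caState")
    phs <- vapply(object@spectra, function(s) s@ph, numeric(1))
    if (anyDuplicated(phs))
      msg <- c(msg, "duplicate pH points")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PHSeries
#'
#' @param spectra list of \linkS4class{AbsorbanceSpectrum} at the titration
#'   pH values.
#' @param denatured the single denatured \linkS4class{AbsorbanceSpectrum}.
#' @return a \linkS4class{PHSeries}.
#' @export
PHSeries <- function(spectra, denatured) {
  new("PHSeries", spectra = spectra, denatured = denatured)
}

setMethod("show", "PHSeries", function(object) {
  phs <- vapply(object@spectra, function(s) s@ph, numeric(1))
  cat("PHSeries:", length(phs), "titration points (pH",
      paste(sort(phs), collapse = ", "),
      ") + denatured at pH", object@denatured@ph, "\n")
})

#' @describeIn PHSeries pH values of the titration points
#' @param object,x a PHSeries.
#' @export
seriesPH <- function(x) vapply(x@spectra, function(s) s@ph, numeric(1))

## ---------------------------------------------------------------------------
## Chromophore parameters
## ---------------------------------------------------------------------------

#' Chromophore photophysical parameters
#'
#' Output of the extinction-coefficient pipeline: the regression slope S
#' between the anionic and neutral band absorbances across pH, the
#' state-specific extinction coefficients, and the state populations at the
#' evaluation pH.
#'
#' @slot slopeS numeric(1), dOD_A/dOD_N across the pH series (expected
#'   negative: protonation converts one state into the other).
#' @slot epsN numeric(1), neutral-state extinction coefficient (M-1 cm-1).
#' @slot epsA numeric(1), anionic-state extinction coefficient (M-1 cm-1).
#' @slot epsD numeric(1), denatured-chromophore extinction coefficient
#'   (M-1 cm-1; 44,000 for GFP-like green chromophores).
#' @slot rhoA,rhoN numeric(1), anionic/neutral state fractions in [0, 1]
#'   at the evaluation pH; they sum to 1.
#' @slot pka numeric(1), chromophore pKa (NA until fitted).
#' @slot hillH numeric(1), Hill coefficient of the pH sigmoid (NA until
#'   fitted).
#' @slot evalPH numeric(1), the pH at which epsN/epsA/rho were evaluated.
#' @slot residual numeric(1), residual standard error of the S regression.
#'
#' @export
setClass("ChromophoreParams",
  representation(
    slopeS = "numeric", epsN = "numeric", epsA = "numeric", epsD = "numeric",
    rhoA = "numeric", rhoN = "numeric", pka = "numeric", hillH = "numeric",
    evalPH = "numeric", residual = "numeric"
  ),
  prototype(pka = NA_real_, hillH = NA_real_, residual = NA_real_)
)

setValidity("ChromophoreParams", function(object) {
  msg <- character()
  if (length(object@rhoA) && length(object@rhoN) &&
      is.finite(object@rhoA) && is.finite(object@rhoN) &&
      abs(object@rhoA + object@rhoN - 1) > 1e-9)
    msg <- c(msg, "rhoA + rhoN must equal 1")
  if (length(object@slopeS) && length(object@epsA) && length(object@epsN) &&
      is.finite(object@slopeS) && object@slopeS < 0 &&
      abs(object@epsA - object@epsN * (-object@slopeS)) >
        1e-6 * abs(object@epsA))
    msg <- c(msg, "epsA must equal epsN * (-S)")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ChromophoreParams", function(object) {
  cat("ChromophoreParams @ pH", object@evalPH, "\n")
  cat(sprintf("  S      = %.5g\n", object@slopeS))
  cat(sprintf("  eps_A  = %.5g M-1 cm-1\n", object@epsA))
  cat(sprintf("  eps_N  = %.5g M-1 cm-1\n", object@epsN))
  cat(sprintf("  rho_A  = %.4f  rho_N = %.4f\n", object@rhoA, object@rhoN))
  if (is.finite(object@pka))
    cat(sprintf("  pKa    = %.3f (h = %.3f)\n", object@pka, object@hillH))
})

#' @describeIn ChromophoreParams anionic extinction coefficient (M-1 cm-1)
#' @param object,x a ChromophoreParams.
#' @export
epsA <- function(x) x@epsA

#' @describeIn ChromophoreParams neutral extinction coefficient (M-1 cm-1)
#' @export
epsN <- function(x) x@epsN

#' @describeIn ChromophoreParams regression slope S = dOD_A/dOD_N
#' @export
slopeS <- function(x) x@slopeS

## ---------------------------------------------------------------------------
## Hill fits / titrations
## ---------------------------------------------------------------------------

#' Hill dose-response fit
#'
#' Parameters of the four-parameter Hill ("specific binding with Hill
#' slope") model y(x) = y0 + (yInf - y0) * x^h / (kd^h + x^h), where y0 is
#' the response at zero ligand and yInf the saturating response. For an "on"
#' calcium sensor yInf > y0; a decreasing curve (e.g. photochromism contrast
#' vs Ca2+) has yInf < y0.
#'
#' @slot y0 numeric(1), response at zero ligand (a.u.).
#' @slot yInf numeric(1), saturating response (a.u.).
#' @slot kd numeric(1), half-saturation constant (nM for Ca2+ curves).
#' @slot h numeric(1), Hill coefficient.
#' @slot se named numeric, standard errors of the four parameters.
#'
#' @export
setClass("HillFit",
  representation(y0 = "numeric", yInf = "numeric", kd = "numeric",
                 h = "numeric", se = "numeric"),
  prototype(se = c(y0 = NA_real_, yInf = NA_real_, kd = NA_real_,
                   h = NA_real_)))

setValidity("HillFit", function(object) {
  if (length(object@kd) && is.finite(object@kd) && object@kd <= 0)
    "kd must be positive" else TRUE
})

setMethod("show", "HillFit", function(object) {
  dir <- if (object@yInf >= object@y0) "increasing" else "decreasing"
  cat(sprintf("HillFit (%s): y0 = %.4g, yInf = %.4g, Kd = %.4g, h = %.3f\n",
              dir, object@y0, object@yInf, object@kd, object@h))
})

#' @describeIn HillFit dissociation constant accessor
#' @param object,x a HillFit.
#' @export
kd <- function(x) x@kd

#' @describeIn HillFit Hill coefficient accessor
#' @export
hillCoef <- function(x) x@h

#' @describeIn HillFit fitted minimal fluorescence (response at zero ligand)
#' @export
fMin <- function(x) min(x@y0, x@yInf)

#' @describeIn HillFit fitted maximal fluorescence (saturating response)
#' @export
fMax <- function(x) max(x@y0, x@yInf)

#' In vitro Ca2+ titration curve
#'
#' Mean fluorescence versus free [Ca2+], with an optional attached Hill fit.
#'
#' @slot caFree numeric, free [Ca2+] (nM), strictly increasing, >= 0.
#' @slot fluorescence numeric, mean fluorescence per concentration (a.u.).
#' @slot fit a \linkS4class{HillFit} or NULL.
#' @slot truth list or NULL; generator ground truth when synthetic.
#'
#' @export
setClass("TitrationCurve",
  representation(caFree = "numeric", fluorescence = "numeric",
                 fit = "ANY", truth = "listOrNULL"),
  prototype(fit = NULL, truth = NULL))

setValidity("TitrationCurve", function(object) {
  msg <- character()
  if (length(object@caFree) != length(object@fluorescence))
    msg <- c(msg, "caFree and fluorescence must have the same length")
  if (any(object@caFree < 0)) msg <- c(msg, "caFree must be non-negative")
  if (length(object@caFree) > 1 && any(diff(object@caFree) <= 0))
    msg <- c(msg, "caFree must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Construct a TitrationCurve
#'
#' @param caFree free [Ca2+] values (nM), strictly increasing.
#' @param fluorescence mean fluorescence per concentration (a.u.).
#' @param fit optional \linkS4class{HillFit}.
#' @param truth optional generator ground-truth list.
#' @return a \linkS4class{TitrationCurve}.
#' @export
TitrationCurve <- function(caFree, fluorescence, fit = NULL, truth = NULL) {
  new("TitrationCurve", caFree = as.numeric(caFree),
      fluorescence = as.numeric(fluorescence), fit = fit, truth = truth)
}

setMethod("show", "TitrationCurve", function(object) {
  cat("TitrationCurve:", length(object@caFree), "concentrations,",
      sprintf("%.3g-%.3g nM\n", min(object@caFree), max(object@caFree)))
  if (!is.null(object@fit)) show(object@fit)
})

#' Off-rate kinetic trace
#'
#' Fluorescence decay after rapid Ca2+ removal by EGTA mixing, with an
#' optional fitted off-rate.
#'
#' @slot time numeric, time after mixing (s), strictly increasing from 0.
#' @slot fluorescence numeric (a.u.).
#' @slot koff numeric(1), fitted off-rate (s-1), NA until fitted.
#' @slot fit list or NULL; details of the exponential fit (plateau,
#'   amplitude, half-time, standard errors).
#' @slot truth list or NULL; generator ground truth when synthetic.
#'
#' @export
setClass("KineticTrace",
  representation(time = "numeric", fluorescence = "numeric",
                 koff = "numeric", fit = "listOrNULL",
                 truth = "listOrNULL"),
  prototype(koff = NA_real_, fit = NULL, truth = NULL))

setValidity("KineticTrace", function(object) {
  msg <- character()
  if (length(object@time) != length(object@fluorescence))
    msg <- c(msg, "time and fluorescence must have the same length")
  if (length(object@time) > 1 && any(diff(object@time) <= 0))
    msg <- c(msg, "time must be strictly increasing")
  if (length(object@time) && object@time[1] < 0)
    msg <- c(msg, "time must start at >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a KineticTrace
#'
#' @param time time after mixing (s), strictly increasing.
#' @param fluorescence fluorescence (a.u.).
#' @param truth optional generator ground-truth list.
#' @return a \linkS4class{KineticTrace}.
#' @export
KineticTrace <- function(time, fluorescence, truth = NULL) {
  new("KineticTrace", time = as.numeric(time),
      fluorescence = as.numeric(fluorescence), truth = truth)
}

setMethod("show", "KineticTrace", function(object) {
  cat("KineticTrace:", length(object@time), "samples over",
      sprintf("%.3g s", diff(range(object@time))))
  if (is.finite(object@koff))
    cat(sprintf("; koff = %.4g s-1 (t1/2 = %.3g s)",
                object@koff, log(2) / object@koff))
  cat("\n")
})

## ---------------------------------------------------------------------------
## Fluorescence traces
## ---------------------------------------------------------------------------

#' ROI fluorescence time series
#'
#' A single-ROI fluorescence trace with its baseline window and stimulus
#' onset times; the baseline window must end at or before the first onset.
#'
#' @slot time numeric, sample times (s), strictly increasing.
#' @slot f numeric, fluorescence (a.u.), finite.
#' @slot baselineWindow numeric(2), [start, end) of the baseline (s).
#' @slot stimOnsets numeric, stimulus onset times (s).
#' @slot truth list or NULL; generator ground truth when synthetic.
#'
#' @export
setClass("FluorescenceTrace",
  representation(time = "numeric", f = "numeric",
                 baselineWindow = "numeric", stimOnsets = "numeric",
                 truth = "listOrNULL"),
  prototype(stimOnsets = numeric(), truth = NULL))

setValidity("FluorescenceTrace", function(object) {
  msg <- character()
  if (length(object@time) != length(object@f))
    msg <- c(msg, "time and f must have the same length")
  if (length(object@time) > 1 && any(diff(object@time) <= 0))
    msg <- c(msg, "time must be strictly increasing")
  if (any(!is.finite(object@f))) msg <- c(msg, "f must be finite")
  if (length(object@baselineWindow) != 2 ||
      object@baselineWindow[2] <= object@baselineWindow[1])
    msg <- c(msg, "baselineWindow must be [start, end) with end > start")
  if (length(object@stimOnsets) &&
      length(object@baselineWindow) == 2 &&
      object@baselineWindow[2] > min(object@stimOnsets) + 1e-12)
    msg <- c(msg, "baseline window must precede the first stimulus onset")
  if (length(msg)) msg else TRUE
})

#' Construct a FluorescenceTrace
#'
#' @param time sample times (s), strictly increasing.
#' @param f fluorescence values (a.u.).
#' @param baselineWindow numeric(2), [start, end) in seconds; defaults to
#'   the 1 s preceding the first stimulus onset (in vivo convention), or
#'   the full pre-onset span when shorter.
#' @param stimOnsets stimulus onset times (s).
#' @param truth optional generator ground-truth list.
#' @return a \linkS4class{FluorescenceTrace}.
#' @export
FluorescenceTrace <- function(time, f, baselineWindow = NULL,
                              stimOnsets = numeric(), truth = NULL) {
  time <- as.numeric(time); f <- as.numeric(f)
  if (is.null(baselineWindow)) {
    end <- if (length(stimOnsets)) min(stimOnsets) else max(time)
    baselineWindow <- c(max(time[1], end - 1), end)
  }
  new("FluorescenceTrace", time = time, f = f,
      baselineWindow = as.numeric(baselineWindow),
      stimOnsets = as.numeric(stimOnsets), truth = truth)
}

setMethod("show", "FluorescenceTrace", function(object) {
  cat("FluorescenceTrace:", length(object@time), "samples,",
      sprintf("%.3g-%.3g s;", object@time[1], max(object@time)),
      "baseline", sprintf("[%.3g, %.3g) s;", object@baselineWindow[1],
                          object@baselineWindow[2]),
      length(object@stimOnsets), "stimulus onset(s)\n")
})

## ---------------------------------------------------------------------------
## Photochromic traces and iPEAQ calibration
## ---------------------------------------------------------------------------

#' Photochromic fluorescence trace
#'
#' A trace recorded under continuous 488-nm excitation with marked epochs of
#' superimposed 405-nm (violet) illumination. Violet light drives the
#' chromophore into a brighter photochromic state; under 488 nm only it
#' relaxes back. The per-cycle fractional drop is the photochromism
#' contrast, which decreases with [Ca2+].
#'
#' @slot time numeric, sample times (s), strictly increasing.
#' @slot f numeric, fluorescence under 488-nm excitation (a.u.).
#' @slot violetOn logical, per-sample flag for superimposed 405-nm light.
#' @slot truth list or NULL; generator ground truth when synthetic.
#'
#' @export
setClass("PhotochromicTrace",
  representation(time = "numeric", f = "numeric", violetOn = "logical",
                 truth = "listOrNULL"),
  prototype(truth = NULL))

setValidity("PhotochromicTrace", function(object) {
  msg <- character()
  if (length(object@time) != length(object@f) ||
      length(object@time) != length(object@violetOn))
    msg <- c(msg, "time, f and violetOn must have the same length")
  if (length(object@time) > 1 && any(diff(object@time) <= 0))
    msg <- c(msg, "time must be strictly increasing")
  if (any(!is.finite(object@f))) msg <- c(msg, "f must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a PhotochromicTrace
#'
#' @param time sample times (s), strictly increasing.
#' @param f fluorescence under 488-nm excitation (a.u.).
#' @param violetOn logical per-sample flag for 405-nm illumination.
#' @param truth optional generator ground-truth list.
#' @return a \linkS4class{PhotochromicTrace}.
#' @export
PhotochromicTrace <- function(time, f, violetOn, truth = NULL) {
  new("PhotochromicTrace", time = as.numeric(time), f = as.numeric(f),
      violetOn = as.logical(violetOn), truth = truth)
}

setMethod("show", "PhotochromicTrace", function(object) {
  nep <- sum(diff(c(FALSE, object@violetOn)) == 1)
  cat("PhotochromicTrace:", length(object@time), "samples,",
      nep, "violet epoch(s)\n")
})

#' iPEAQ dual Hill calibration
#'
#' The pair of in vitro dose-response curves that photochromism-enabled
#' absolute quantification inverts: photochromism contrast vs [Ca2+]
#' (monotone decreasing) and fluorescence vs [Ca2+] (monotone increasing).
#'
#' @slot contrastCurve \linkS4class{HillFit}, contrast vs [Ca2+] (nM),
#'   decreasing.
#' @slot fluorCurve \linkS4class{HillFit}, fluorescence vs [Ca2+] (nM),
#'   increasing.
#'
#' @export
setClass("IPEAQCalibration",
  representation(contrastCurve = "HillFit", fluorCurve = "HillFit"))

setValidity("IPEAQCalibration", function(object) {
  msg <- character()
  if (object@contrastCurve@yInf >= object@contrastCurve@y0)
    msg <- c(msg, "contrast curve must be monotone decreasing in [Ca2+]")
  if (object@fluorCurve@yInf <= object@fluorCurve@y0)
    msg <- c(msg, "fluorescence curve must be monotone increasing in [Ca2+]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "IPEAQCalibration", function(object) {
  cat("IPEAQCalibration\n  contrast: ")
  show(object@contrastCurve)
  cat("  fluorescence: ")
  show(object@fluorCurve)
})

## ---------------------------------------------------------------------------
## Tuning curves
## ---------------------------------------------------------------------------

#' Orientation tuning curve
#'
#' Mean dF/F0 response amplitude per drifting-grating direction, averaged
#' over trials. Directions must be distinct and equally spaced over 360
#' degrees (typically 8).
#'
#' @slot theta numeric, stimulus directions (degrees), equally spaced.
#' @slot r numeric, mean dF/F0 amplitude per direction.
#'
#' @export
setClass("TuningCurve", representation(theta = "numeric", r = "numeric"))

setValidity("TuningCurve", function(object) {
  msg <- character()
  if (length(object@theta) != length(object@r))
    msg <- c(msg, "theta and r must have the same length")
  if (length(object@theta) < 4)
    msg <- c(msg, "need at least 4 directions")
  if (anyDuplicated(object@theta))
    msg <- c(msg, "directions must be distinct")
  if (any(!is.finite(object@r))) msg <- c(msg, "r must be finite")
  th <- sort(object@theta %% 360)
  if (length(th) >= 2) {
    gaps <- diff(c(th, th[1] + 360))
    if (max(abs(gaps - 360 / length(th))) > 1e-6)
      msg <- c(msg, "directions must be equally spaced over 360 degrees")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TuningCurve
#'
#' @param theta stimulus directions (degrees), equally spaced over 360.
#' @param r mean dF/F0 amplitude per direction.
#' @return a \linkS4class{TuningCurve}.
#' @export
TuningCurve <- function(theta, r) {
  new("TuningCurve", theta = as.numeric(theta), r = as.numeric(r))
}

setMethod("show", "TuningCurve", function(object) {
  cat("TuningCurve:", length(object@theta), "directions; peak",
      sprintf("%.3g at %g deg\n", max(object@r),
              object@theta[which.max(object@r)]))
})
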