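## Chromophore photophysics: band quantification, the pH-titration slope,
## state-specific extinction coefficients, pKa, quantum yield and two-photon
## action cross-sections.
##
## GFP-like chromophores interconvert between a protonated neutral state
## (absorbing near 400 nm) and a deprotonated anionic state (near 500 nm).
## Because the total chromophore concentration n is conserved during an H+
## titration (n_A + n_N = n_D, with n_D fixed by the alkaline-denatured
## spectrum and eps_D), the slope S = dOD_A/dOD_N across pH fixes the ratio
## eps_A/eps_N = -S, and the denatured spectrum anchors the absolute scale:
##
##   eps_N = (OD_A/(-S) + OD_N) / (OD_D/eps_D),   eps_A = eps_N * (-S)

.NEUTRAL_WINDOW <- c(380, 430)
.ANIONIC_WINDOW <- c(470, 540)
.BASELINE_WINDOW <- c(600, 650)

## Internal: baseline-subtract and optionally median-filter a spectrum,
## then return the peak OD within [lo, hi]. Raw (unsmoothed) peak attached.
.windowPeak <- function(wl, od, window, smooth = TRUE) {
  if (wl[1] > window[1] + 1e-9 || wl[length(wl)] < window[2] - 1e-9)
    stop(sprintf("wavelength grid does not cover the %g-%g nm window",
                 window[1], window[2]), call. = FALSE)
  idx <- wl >= window[1] & wl <= window[2]
  sm <- if (smooth && sum(idx) >= 5)
    stats::runmed(od, 5, endrule = "median") else od
  c(smoothed = max(0, max(sm[idx])), raw = max(0, max(od[idx])))
}

.baselineLevel <- function(wl, od) {
  idx <- wl >= .BASELINE_WINDOW[1] & wl <= .BASELINE_WINDOW[2]
  if (any(idx)) mean(od[idx]) else 0
}

#' Peak absorbances of the neutral and anionic chromophore bands
#'
#' Quantifies the protonated (neutral, peak near 400 nm) and deprotonated
#' (anionic, peak near 500 nm) chromophore bands of an absorbance spectrum
#' as the maximal optical density within fixed wavelength windows. The mean
#' OD over 600-650 nm, where protein chromophores do not absorb, is first
#' subtracted as a baseline (when covered by the grid), and a 5-point
#' running-median filter is applied before peak-picking; the unsmoothed
#' peaks are attached as an attribute.
#'
#' @param spectrum an \linkS4class{AbsorbanceSpectrum} whose grid covers
#'   both band windows.
#' @param neutralWindow,anionicWindow numeric(2), band windows (nm).
#' @param smooth logical, apply the 5-point median filter before
#'   peak-picking.
#' @return named numeric \code{c(odN, odA)}, both >= 0, with attribute
#'   \code{"raw"} holding the unsmoothed values.
#' @examples
#' wl <- 350:700
#' ab <- 0.3 * exp(-(wl - 403)^2 / (2 * 10.6^2)) +
#'       0.6 * exp(-(wl - 509)^2 / (2 * 10.6^2))
#' bandAmplitudes(AbsorbanceSpectrum(wl, ab, ph = 7.2))
#' @export
bandAmplitudes <- function(spectrum,
                           neutralWindow = .NEUTRAL_WINDOW,
                           anionicWindow = .ANIONIC_WINDOW,
                           smooth = TRUE) {
  stopifnot(is(spectrum, "AbsorbanceSpectrum"))
  wl <- spectrum@wavelength
  od <- spectrum@absorbance - .baselineLevel(wl, spectrum@absorbance)
  n <- .windowPeak(wl, od, neutralWindow, smooth)
  a <- .windowPeak(wl, od, anionicWindow, smooth)
  out <- c(odN = unname(n["smoothed"]), odA = unname(a["smoothed"]))
  attr(out, "raw") <- c(odN = unname(n["raw"]), odA = unname(a["raw"]))
  out
}

## Internal: band table for all titration points of a series.
.seriesBands <- function(series, ...) {
  ph <- seriesPH(series)
  bands <- t(vapply(series@spectra,
                    function(s) bandAmplitudes(s, ...)[c("odN", "odA")],
                    numeric(2)))
  data.frame(ph = ph, odN = bands[, 1], odA = bands[, 2])[order(ph), ]
}

#' Protonation slope S of a pH titration series
#'
#' Ordinary least-squares slope of the anionic band absorbance OD_A
#' regressed on the neutral band absorbance OD_N across the titration pH
#' points (intercept free): S = dOD_A/dOD_N. Chromophore conservation makes
#' the two bands anticorrelate, so S < 0 for a two-state chromophore, and
#' eps_A/eps_N = -S.
#'
#' @param series a \linkS4class{PHSeries} with >= 3 titration points.
#' @return the slope (numeric), with attributes \code{"intercept"} and
#'   \code{"residual"} (residual standard error of the regression).
#' @export
titrationSlope <- function(series) {
  stopifnot(is(series, "PHSeries"))
  b <- .seriesBands(series)
  if (stats::sd(b$odN) < 1e-12 * max(abs(b$odN), 1))
    stop("degenerate regression: OD_N does not vary across pH points",
         call. = FALSE)
  fit <- stats::lm(odA ~ odN, data = b)
  s <- unname(stats::coef(fit)["odN"])
  attr(s, "intercept") <- unname(stats::coef(fit)["(Intercept)"])
  attr(s, "residual") <- suppressWarnings(summary(fit)$sigma)
  s
}

#' State-specific extinction coefficients from a pH titration
#'
#' Recovers the neutral- and anionic-state extinction coefficients and the
#' state populations of a GFP-like chromophore from a pH-titration
#' absorbance series plus one alkaline-denatured spectrum. Conservation of
#' chromophore across the titration gives eps_A/eps_N = -S (with S the
#' \code{\link{titrationSlope}}), and the denatured spectrum, whose
#' extinction coefficient eps_D is known (44,000 M-1 cm-1 for green
#' GFP-like chromophores), anchors the absolute concentration:
#' \deqn{\varepsilon_N = \frac{OD_A/(-S) + OD_N}{OD_D/\varepsilon_D},\quad
#'       \varepsilon_A = \varepsilon_N \times (-S)}
#' evaluated at \code{evalPH}. State fractions follow as
#' rho_A = n_A/(n_A + n_N), rho_N = 1 - rho_A with n = OD/eps.
#'
#' @param series a \linkS4class{PHSeries} containing \code{evalPH} among its
#'   titration points and a denatured spectrum.
#' @param evalPH pH at which eps and the state fractions are evaluated
#'   (default 7.2, the standard measurement buffer).
#' @param epsD denatured-chromophore extinction coefficient (M-1 cm-1).
#' @param fitPka logical; also fit the pKa sigmoid to the per-pH anionic
#'   fractions (see \code{\link{fitPKa}}).
#' @return a \linkS4class{ChromophoreParams}.
#' @export
extinctionCoefficients <- function(series, evalPH = 7.2, epsD = 44000,
                                   fitPka = FALSE) {
  stopifnot(is(series, "PHSeries"))
  b <- .seriesBands(series)
  i <- which(abs(b$ph - evalPH) < 1e-6)
  if (!length(i))
    stop("evalPH ", evalPH, " is not among the titration points",
         call. = FALSE)
  sFull <- titrationSlope(series)
  s <- as.numeric(sFull)
  if (s >= 0)
    stop("slope S is non-negative: neutral/anionic band anticorrelation ",
         "violated; the series carries no two-state titration information",
         call. = FALSE)
  dn <- series@denatured
  odD <- .windowPeak(dn@wavelength,
                     dn@absorbance - .baselineLevel(dn@wavelength,
                                                    dn@absorbance),
                     c(380, 540))[["smoothed"]]
  if (odD <= 0)
    stop("invalid denatured spectrum: OD_D must be positive", call. = FALSE)
  odA <- b$odA[i[1]]; odN <- b$odN[i[1]]
  epsNval <- (odA / (-s) + odN) / (odD / epsD)
  epsAval <- epsNval * (-s)
  nA <- odA / epsAval
  nN <- odN / epsNval
  rhoA <- nA / (nA + nN)
  params <- new("ChromophoreParams",
                slopeS = as.numeric(s), epsN = epsNval, epsA = epsAval,
                epsD = epsD, rhoA = rhoA, rhoN = 1 - rhoA,
                evalPH = evalPH, residual = attr(sFull, "residual"))
  if (fitPka) {
    pk <- fitPKa(data.frame(ph = b$ph,
                            rhoA = .rhoSeries(b, epsAval, epsNval)))
    params@pka <- pk$pka
    params@hillH <- pk$h
  }
  params
}

## Internal: per-pH anionic fractions given the recovered eps values.
.rhoSeries <- function(bands, epsAval, epsNval) {
  nA <- bands$odA / epsAval
  nN <- bands$odN / epsNval
  nA / (nA + nN)
}

#' Chromophore pKa from anionic-fraction titration
#'
#' Fits the anionic state fraction against pH with the specific-binding-
#' with-Hill-slope sigmoid rho_A(pH) = 1 / (1 + 10^(h (pKa - pH))) by
#' nonlinear least squares (Hill coefficient h fitted, start 1).
#'
#' Accepts either a \linkS4class{PHSeries} (the anionic fractions are then
#' derived through \code{\link{extinctionCoefficients}}) or a data.frame
#' with columns \code{ph} and \code{rhoA}.
#'
#' @param x a \linkS4class{PHSeries} or a data.frame(ph, rhoA).
#' @param evalPH,epsD passed to \code{\link{extinctionCoefficients}} when
#'   \code{x} is a series.
#' @return list with elements \code{pka}, \code{h} and \code{se}; a flat or
#'   non-monotone fraction profile triggers a fit-quality warning (with
#'   \code{pka = NA} when unidentifiable).
#' @export
fitPKa <- function(x, evalPH = 7.2, epsD = 44000) {
  if (is(x, "PHSeries")) {
    b <- .seriesBands(x)
    cp <- extinctionCoefficients(x, evalPH = evalPH, epsD = epsD)
    x <- data.frame(ph = b$ph, rhoA = .rhoSeries(b, cp@epsA, cp@epsN))
  }
  stopifnot(is.data.frame(x), all(c("ph", "rhoA") %in% names(x)))
  if (nrow(x) < 3)
    stop("need at least 3 pH points", call. = FALSE)
  x <- x[order(x$ph), ]
  if (diff(range(x$rhoA)) < 1e-6) {
    warning("anionic fraction does not vary with pH: pKa unidentifiable")
    return(list(pka = NA_real_, h = NA_real_, se = c(pka = NA_real_,
                                                     h = NA_real_)))
  }
  if (any(diff(x$rhoA) < -0.02 * diff(range(x$rhoA))))
    warning("anionic fraction is non-monotone in pH beyond noise tolerance; ",
            "check the titration (fit proceeds)")
  pkStart <- x$ph[which.min(abs(x$rhoA - 0.5))]
  fit <- minpack.lm::nlsLM(
    rhoA ~ 1 / (1 + 10^(h * (pka - ph))), data = x,
    start = list(pka = pkStart, h = 1),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(NA_real_, NA_real_))
  names(se) <- c("pka", "h")
  list(pka = unname(cf["pka"]), h = unname(cf["h"]), se = se)
}

#' Fluorescence quantum yield by the slope-ratio method
#'
#' Estimates the quantum yield of a protein relative to a reference dye
#' from total integrated fluorescence (TIF) measured at several
#' concentrations: Phi_protein = Phi_standard x (S_protein / S_standard),
#' where each S is the OLS slope of TIF versus absorbance. Standard
#' references: fluorescein in 0.1 M NaOH (Phi = 0.925, anionic chromophore,
#' 470-nm excitation) and TOLLES (Phi = 0.79, neutral chromophore, 405-nm
#' excitation).
#'
#' @param absorbance sample absorbances at >= 2 concentrations.
#' @param tif total integrated fluorescence at the same concentrations.
#' @param standardSlope TIF-vs-absorbance slope of the reference dye.
#' @param standardPhi reference quantum yield, or one of
#'   \code{"fluorescein"} (0.925) / \code{"tolles"} (0.79).
#' @return the quantum yield (numeric), with attributes
#'   \code{"sampleSlope"} and \code{"se"}; values > 1 are returned with a
#'   warning.
#' @examples
#' quantumYield(c(0.02, 0.05, 0.1), c(20, 50, 100),
#'              standardSlope = 1000, standardPhi = "fluorescein")
#' @export
quantumYield <- function(absorbance, tif, standardSlope,
                         standardPhi = "fluorescein") {
  if (is.character(standardPhi))
    standardPhi <- switch(match.arg(standardPhi, c("fluorescein", "tolles")),
                          fluorescein = 0.925, tolles = 0.79)
  stopifnot(length(absorbance) == length(tif), length(absorbance) >= 2,
            all(absorbance >= 0))
  if (standardSlope == 0)
    stop("standard slope is zero", call. = FALSE)
  if (stats::sd(absorbance) < 1e-12 * max(abs(absorbance), 1))
    stop("degenerate regression: sample absorbances do not vary",
         call. = FALSE)
  fit <- stats::lm(tif ~ absorbance)
  s <- unname(stats::coef(fit)["absorbance"])
  phi <- standardPhi * s / standardSlope
  if (is.finite(phi) && phi > 1)
    warning("quantum yield > 1: check absorbance calibration or standard")
  attr(phi, "sampleSlope") <- s
  attr(phi, "se") <- tryCatch(
    standardPhi / standardSlope * suppressWarnings(
      summary(fit)$coefficients["absorbance", "Std. Error"]),
    error = function(e) NA_real_)
  phi
}

#' Two-photon action cross-section relative to fluorescein
#'
#' Computes the two-photon action cross-section of a sample from
#' time-averaged fluorescence photon fluxes measured side-by-side with a
#' fluorescein standard on the same system. All system constants (pulse
#' shape, repetition rate, pulse width, incident power, collection
#' efficiency, refractive index) cancel in the sample/standard ratio:
#' \deqn{\delta_{sample} = \frac{\langle F\rangle_{sample}\,
#'   \eta_{2,std}\, C_{std}}{\langle F\rangle_{std}\,
#'   \eta_{2,sample}\, C_{sample}} \times \delta_{std}}
#'
#' @param fSample,fStandard time-averaged fluorescence photon fluxes of
#'   sample and standard (same arbitrary units, same system).
#' @param cSample,cStandard concentrations (M).
#' @param eta2Sample two-photon quantum yield of the sample.
#' @param eta2Standard two-photon quantum yield of the standard (0.925 for
#'   fluorescein, taken wavelength-independent).
#' @param wavelength excitation wavelength (nm); used to look up the
#'   bundled fluorescein reference when \code{deltaStandard} is missing.
#' @param deltaStandard cross-section of the standard at this wavelength
#'   (GM); overrides the bundled fluorescein table.
#' @return cross-section of the sample (GM).
#' @examples
#' twoPhotonCrossSection(fSample = 2, fStandard = 1, cSample = 1e-6,
#'                       cStandard = 1e-6, eta2Sample = 0.6,
#'                       wavelength = 920)
#' @export
twoPhotonCrossSection <- function(fSample, fStandard, cSample, cStandard,
                                  eta2Sample, eta2Standard = 0.925,
                                  wavelength = NULL, deltaStandard = NULL) {
  vals <- c(fSample, fStandard, cSample, cStandard, eta2Sample,
            eta2Standard)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all fluxes, concentrations and quantum yields must be positive",
         call. = FALSE)
  if (is.null(deltaStandard)) {
    if (is.null(wavelength))
      stop("missing reference: supply either deltaStandard or a wavelength ",
           "within the bundled fluorescein table (750-990 nm)",
           call. = FALSE)
    deltaStandard <- fluoresceinCrossSection(wavelength)
  }
  (fSample * eta2Standard * cStandard) /
    (fStandard * eta2Sample * cSample) * deltaStandard
}
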