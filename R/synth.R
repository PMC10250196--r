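## Synthetic-data generators. Every input the analysis modules consume can
## be generated here with known ground truth, a stated noise model
## (multiplicative Gaussian, CV-parameterized, reflecting shot-noise-
## dominated imaging) and a fixed seed. Each generator returns its ground
## truth in machine-readable form so that every estimator has a round-trip
## test.

## Run expr under a fixed seed without disturbing the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

.mnoise <- function(x, cv) {
  if (cv <= 0) return(x)
  x * (1 + stats::rnorm(length(x), 0, cv))
}

.gauss <- function(wl, center, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  exp(-(wl - center)^2 / (2 * sigma^2))
}

#' Generate a pH-titration absorbance series
#'
#' Forward model of a two-state GFP-like chromophore: the anionic fraction
#' at each pH follows the Henderson-Hasselbalch sigmoid
#' rho_A = 1/(1 + 10^(h (pKa - pH))), and each spectrum is the sum of two
#' Gaussian bands (neutral and anionic, amplitudes eps_state x
#' concentration x state fraction) plus a denatured spectrum at pH 12.5
#' whose single band has amplitude eps_D x concentration.
#'
#' @param epsA,epsN anionic/neutral extinction coefficients (M-1 cm-1).
#' @param pka,h chromophore pKa and Hill coefficient of the pH sigmoid.
#' @param concentration chromophore concentration (M).
#' @param phValues titration pH points.
#' @param denaturedPH pH of the denatured spectrum.
#' @param epsD denatured extinction coefficient (M-1 cm-1).
#' @param centers numeric(2), neutral and anionic band centers (nm).
#' @param denaturedCenter denatured band center (nm).
#' @param fwhm Gaussian band full width at half maximum (nm).
#' @param wavelength wavelength grid (nm).
#' @param caState Ca2+ state label shared by all spectra.
#' @param noiseCv multiplicative noise coefficient of variation.
#' @param seed RNG seed.
#' @return list with \code{series} (a \linkS4class{PHSeries}) and
#'   \code{truth} (the generating parameters, including the implied
#'   slope S = -epsA/epsN).
#' @examples
#' g <- genPHSpectra(noiseCv = 0)
#' epsA(extinctionCoefficients(g$series))
#' @export
genPHSpectra <- function(epsA = 64260, epsN = 21420, pka = 7.0, h = 1,
                         concentration = 4e-6,
                         phValues = c(7, 7.2, 8, 9), denaturedPH = 12.5,
                         epsD = 44000, centers = c(403, 509),
                         denaturedCenter = 447, fwhm = 25,
                         wavelength = 350:700, caState = "ca_saturated",
                         noiseCv = 0, seed = 1) {
  stopifnot(epsA > 0, epsN > 0, concentration > 0, fwhm > 0)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  ## band-overlap guard: appreciable cross-band energy breaks the two-band
  ## peak quantification this generator is meant to exercise
  if (exp(-diff(centers)^2 / (8 * sigma^2)) > 0.1)
    stop("config error: neutral and anionic bands overlap by more than ",
         "10% energy at this width", call. = FALSE)
  .withSeed(seed, {
    spectra <- lapply(phValues, function(p) {
      rhoA <- 1 / (1 + 10^(h * (pka - p)))
      ab <- epsN * concentration * (1 - rhoA) *
              .gauss(wavelength, centers[1], fwhm) +
            epsA * concentration * rhoA *
              .gauss(wavelength, centers[2], fwhm)
      AbsorbanceSpectrum(wavelength, .mnoise(ab, noiseCv), ph = p,
                         caState = caState)
    })
    den <- AbsorbanceSpectrum(
      wavelength,
      .mnoise(epsD * concentration *
                .gauss(wavelength, denaturedCenter, fwhm), noiseCv),
      ph = denaturedPH, caState = caState)
    list(series = PHSeries(spectra, den),
         truth = list(epsA = epsA, epsN = epsN, epsD = epsD, pka = pka,
                      h = h, concentration = concentration,
                      slopeS = -epsA / epsN))
  })
}

#' Generate a Ca2+ titration curve
#'
#' Hill forward model sampled at log-spaced free [Ca2+] over
#' [kd/100, kd x 100].
#'
#' @param fMin,fMax fluorescence plateaus (a.u.).
#' @param kd half-saturation (nM).
#' @param h Hill coefficient.
#' @param nPoints number of concentrations (>= 5).
#' @param noiseCv multiplicative noise CV.
#' @param seed RNG seed.
#' @return a \linkS4class{TitrationCurve} with the generating parameters in
#'   its \code{truth} slot.
#' @export
genTitration <- function(fMin = 1, fMax = 103.3, kd = 200, h = 2,
                         nPoints = 12, noiseCv = 0, seed = 1) {
  stopifnot(kd > 0, fMin > 0)
  if (nPoints < 5)
    stop("config error: need at least 5 concentrations", call. = FALSE)
  .withSeed(seed, {
    ca <- 10^seq(log10(kd / 100), log10(kd * 100), length.out = nPoints)
    f <- fMin + (fMax - fMin) * ca^h / (kd^h + ca^h)
    TitrationCurve(ca, .mnoise(f, noiseCv),
                   truth = list(fMin = fMin, fMax = fMax, kd = kd, h = h,
                                dr = (fMax - fMin) / fMin))
  })
}

#' Generate an off-rate kinetic trace
#'
#' Single-exponential decay F(t) = plateau + A exp(-koff t) after Ca2+
#' removal; the default duration covers 6 e-folds.
#'
#' @param koff off-rate (s-1).
#' @param plateau,amplitude plateau and initial amplitude (a.u.).
#' @param samplingHz sampling rate (Hz).
#' @param duration trace duration (s); default 6/koff.
#' @param noiseCv multiplicative noise CV.
#' @param seed RNG seed.
#' @return a \linkS4class{KineticTrace} with ground truth attached.
#' @export
genKinetic <- function(koff = 2, plateau = 1, amplitude = 5,
                       samplingHz = 100, duration = 6 / koff,
                       noiseCv = 0, seed = 1) {
  stopifnot(koff > 0, samplingHz > 0, duration > 0)
  .withSeed(seed, {
    t <- seq(0, duration, by = 1 / samplingHz)
    f <- plateau + amplitude * exp(-koff * t)
    KineticTrace(t, .mnoise(f, noiseCv),
                 truth = list(koff = koff, plateau = plateau,
                              amplitude = amplitude))
  })
}

#' Default synthetic iPEAQ calibration truth
#'
#' The pair of Hill curves used by \code{\link{genPhotochromic}} unless
#' overridden: photochromism contrast decreasing from 0.6 to 0.05 with
#' half-point 250 nM (h = 1), and fluorescence increasing 30-fold with the
#' same half-point.
#'
#' @return list with \code{contrastCurve} and \code{fluorCurve}
#'   (\linkS4class{HillFit} objects).
#' @export
ipeaqTruthCurves <- function() {
  list(contrastCurve = new("HillFit", y0 = 0.6, yInf = 0.05, kd = 250,
                           h = 1, se = c(y0 = 0, yInf = 0, kd = 0, h = 0)),
       fluorCurve = new("HillFit", y0 = 1, yInf = 30, kd = 250,
                        h = 1, se = c(y0 = 0, yInf = 0, kd = 0, h = 0)))
}

#' Generate a photochromic trace with known [Ca2+](t)
#'
#' Forward model of an iPEAQ recording: the 488-nm baseline fluorescence
#' tracks fluorCurve([Ca2+](t)) scaled by a gain factor; each violet epoch
#' raises fluorescence to baseline/(1 - contrast), where contrast =
#' contrastCurve([Ca2+]) at the epoch time; after the epoch the elevation
#' relaxes exponentially with time constant tau.
#'
#' @param caTruth ground-truth free [Ca2+] (nM): a constant or a function
#'   of time (s).
#' @param curves list with \code{contrastCurve} and \code{fluorCurve}
#'   \linkS4class{HillFit} truth curves (default
#'   \code{\link{ipeaqTruthCurves}()}).
#' @param gain multiplicative detector/expression gain applied to the
#'   whole trace (iPEAQ output must be invariant to it).
#' @param nCycles number of photochromic cycles.
#' @param violetDur violet epoch duration (s).
#' @param cyclePeriod onset-to-onset cycle spacing (s).
#' @param cycleStart time of the first violet onset (s).
#' @param tau relaxation time constant (s).
#' @param duration total trace duration (s); default extends one period
#'   past the last cycle plus 10 s.
#' @param samplingHz sampling rate (Hz).
#' @param noiseCv multiplicative noise CV.
#' @param seed RNG seed.
#' @return a \linkS4class{PhotochromicTrace}; its \code{truth} slot holds
#'   \code{ca} (the ground-truth series), the truth curves, \code{tau} and
#'   \code{gain}.
#' @export
genPhotochromic <- function(caTruth = 100, curves = ipeaqTruthCurves(),
                            gain = 1, nCycles = 5, violetDur = 2.5,
                            cyclePeriod = 10, cycleStart = 2.5, tau = 0.5,
                            duration = NULL, samplingHz = 20,
                            noiseCv = 0, seed = 1) {
  stopifnot(gain > 0, tau > 0, violetDur > 0, cyclePeriod > violetDur)
  lastOff <- cycleStart + (nCycles - 1) * cyclePeriod + violetDur
  if (is.null(duration)) duration <- lastOff + cyclePeriod - violetDur + 10
  caFun <- if (is.function(caTruth)) caTruth else function(t)
    rep_len(caTruth, length(t))
  .withSeed(seed, {
    t <- seq(0, duration, by = 1 / samplingHz)
    ca <- caFun(t)
    onsets <- cycleStart + (seq_len(nCycles) - 1) * cyclePeriod
    violet <- rep(FALSE, length(t))
    for (on in onsets)
      violet <- violet | (t >= on & t < on + violetDur)
    base <- hillEval(curves$fluorCurve, ca)
    contrast <- hillEval(curves$contrastCurve, ca)
    f <- base
    f[violet] <- base[violet] / (1 - contrast[violet])
    ## exponential relaxation of the violet-induced elevation
    for (on in onsets) {
      off <- on + violetDur
      iOff <- max(which(t < off))
      elev <- base[iOff] / (1 - contrast[iOff]) - base[iOff]
      after <- which(t >= off)
      if (length(after))
        f[after] <- f[after] + elev * exp(-(t[after] - off) / tau) *
          !violet[after]
    }
    caEpoch <- vapply(onsets, function(on)
      max(abs(ca[t >= on & t < on + violetDur] -
              ca[which(t >= on)[1]])), numeric(1))
    if (any(caEpoch > 0.01 * pmax(abs(ca[1]), 1)))
      warning("cycle schedule overlaps [Ca2+] transients: per-cycle ",
              "contrast will mix concentrations")
    PhotochromicTrace(t, .mnoise(gain * f, noiseCv), violet,
                      truth = list(ca = ca, curves = curves, tau = tau,
                                   gain = gain, onsets = onsets,
                                   violetDur = violetDur))
  })
}

#' Generate an action-potential-train fluorescence trace
#'
#' Convolves spike times at a fixed frequency with a double-exponential
#' kernel (rise/decay), scales by the per-AP amplitude, adds the baseline
#' F0 and multiplicative noise. The kernel peak is normalized to 1, so a
#' single noiseless AP has peak dF/F0 = kernelAmp / f0.
#'
#' @param freqHz AP frequency (Hz).
#' @param nAp number of APs.
#' @param kernelAmp fluorescence amplitude per AP (a.u.).
#' @param f0 baseline fluorescence (a.u.).
#' @param riseMs kernel rise time constant (ms).
#' @param decayHalfMs kernel half-decay time (ms); presets: 409 (fast
#'   indicator), 482 (slower reference indicator).
#' @param samplingHz sampling rate (Hz).
#' @param onset time of the first AP (s).
#' @param baselineS baseline window length before onset (s).
#' @param duration total duration (s); default onset + train + 5 half
#'   decays.
#' @param noiseCv multiplicative noise CV.
#' @param seed RNG seed.
#' @return a \linkS4class{FluorescenceTrace} with ground truth attached.
#' @export
genAPTrain <- function(freqHz = 10, nAp = 10, kernelAmp = 20, f0 = 100,
                       riseMs = 10, decayHalfMs = 409, samplingHz = 100,
                       onset = 2, baselineS = 1, duration = NULL,
                       noiseCv = 0, seed = 1) {
  stopifnot(freqHz > 0, nAp >= 1, f0 > 0, samplingHz > 0)
  tauR <- riseMs / 1000
  tauD <- decayHalfMs / 1000 / log(2)
  if (samplingHz < 1 / (pi * tauR))
    warning("aliasing: sampling rate is below the kernel bandwidth")
  spikes <- onset + (seq_len(nAp) - 1) / freqHz
  if (is.null(duration))
    duration <- max(spikes) + 5 * tauD * log(2) + 1
  .withSeed(seed, {
    t <- seq(0, duration, by = 1 / samplingHz)
    ## double-exponential kernel, peak-normalized
    tPk <- tauR * tauD / (tauD - tauR) * log(tauD / tauR)
    pk <- exp(-tPk / tauD) - exp(-tPk / tauR)
    f <- rep(f0, length(t))
    for (s in spikes) {
      dt <- t - s
      f <- f + kernelAmp *
        ifelse(dt >= 0, (exp(-dt / tauD) - exp(-dt / tauR)) / pk, 0)
    }
    FluorescenceTrace(t, .mnoise(f, noiseCv),
                      baselineWindow = c(onset - baselineS, onset),
                      stimOnsets = onset,
                      truth = list(f0 = f0, kernelAmp = kernelAmp,
                                   tauRise = tauR, tauDecay = tauD,
                                   halfDecayS = decayHalfMs / 1000,
                                   spikes = spikes))
  })
}

#' Generate a trial-structured drifting-grating response table
#'
#' Response amplitudes follow a von Mises tuning profile over direction,
#' exp(kappa (cos(theta - thetaPref) - 1)), scaled by the peak amplitude;
#' within the stimulus window each sample is the trial plateau plus
#' additive Gaussian noise. kappa = 0 gives an untuned cell.
#'
#' @param kappa von Mises concentration (0 = untuned).
#' @param thetaPref preferred direction (deg).
#' @param amp peak dF/F0 plateau at the preferred direction.
#' @param nTheta number of equally spaced directions (default 8).
#' @param trials trials per direction (default 6).
#' @param stimS stimulus duration (s).
#' @param samplingHz sampling rate (Hz).
#' @param noiseSd additive noise SD on dF/F0 samples.
#' @param seed RNG seed.
#' @return list with \code{trials} (long data.frame: theta, trial, time,
#'   dff) and \code{truth} (tuning profile and parameters).
#' @export
genTuning <- function(kappa = 4, thetaPref = 90, amp = 2, nTheta = 8,
                      trials = 6, stimS = 4, samplingHz = 11,
                      noiseSd = 0.2, seed = 1) {
  stopifnot(kappa >= 0, amp >= 0, nTheta >= 4, trials >= 1)
  thetas <- seq(0, 360 - 360 / nTheta, by = 360 / nTheta)
  profile <- amp * exp(kappa * (cos((thetas - thetaPref) * pi / 180) - 1))
  nS <- max(4, round(stimS * samplingHz))
  .withSeed(seed, {
    tab <- data.frame(
      theta = rep(thetas, each = trials * nS),
      trial = rep(rep(seq_len(trials), each = nS), times = nTheta),
      time = rep((seq_len(nS) - 1) / samplingHz, times = nTheta * trials),
      dff = rep(profile, each = trials * nS) +
        stats::rnorm(nTheta * trials * nS, 0, noiseSd))
    list(trials = tab,
         truth = list(theta = thetas, profile = profile, kappa = kappa,
                      thetaPref = thetaPref, amp = amp))
  })
}
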