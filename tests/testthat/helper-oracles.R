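## Independent oracles used across tests.

## Complex-resultant OSI, independent of the package implementation.
osiOracle <- function(theta, r) {
  r <- pmax(r, 0)
  Mod(sum(r * exp(2i * theta * pi / 180))) / sum(r)
}

## Gaussian band evaluated directly from generator parameters (FWHM).
gaussBand <- function(wl, center, amp, fwhm = 25) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  amp * exp(-(wl - center)^2 / (2 * sigma^2))
}

## Build an AbsorbanceSpectrum from explicit band amplitudes.
bandSpectrum <- function(odN, odA, ph = 7, wl = 350:700,
                         caState = "ca_free") {
  AbsorbanceSpectrum(wl, gaussBand(wl, 403, odN) + gaussBand(wl, 509, odA),
                     ph = ph, caState = caState)
}

## PHSeries with prescribed per-pH band amplitudes plus a denatured band.
bandSeries <- function(phValues, odN, odA, odD = 0.176,
                       denaturedCenter = 447, wl = 350:700) {
  spectra <- mapply(function(p, n, a) bandSpectrum(n, a, ph = p, wl = wl),
                    phValues, odN, odA, SIMPLIFY = FALSE)
  den <- AbsorbanceSpectrum(wl, gaussBand(wl, denaturedCenter, odD),
                            ph = 12.5)
  PHSeries(spectra, den)
}

## Hill evaluation from raw parameters (generator-side closed form).
hillValue <- function(x, y0, yInf, kdv, h)
  y0 + (yInf - y0) * x^h / (kdv^h + x^h)
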