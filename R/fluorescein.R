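## Bundled fluorescein two-photon reference.

#' Fluorescein two-photon action cross-section reference
#'
#' Two-photon action cross-sections of fluorescein (pH ~13, aqueous NaOH)
#' at 750-990 nm in 10-nm steps, the standard reference for relative
#' two-photon measurements. Values (GM) are approximate digitizations of
#' the tabulation of Xu & Webb, J. Opt. Soc. Am. B 13, 481-491 (1996);
#' treat them as ~10\% accurate and override \code{deltaStandard} in
#' \code{\link{twoPhotonCrossSection}} when a better calibration is
#' available. Intermediate wavelengths are linearly interpolated.
#'
#' @param wavelength excitation wavelength(s) in nm, within 750-990.
#' @return cross-section(s) in GM.
#' @examples
#' fluoresceinCrossSection(c(800, 920))
#' @export
fluoresceinCrossSection <- function(wavelength) {
  tab <- fluoresceinReference()
  if (any(wavelength < min(tab$wavelength) |
          wavelength > max(tab$wavelength)))
    stop("missing reference: wavelength outside the bundled fluorescein ",
         "table (750-990 nm); supply deltaStandard explicitly",
         call. = FALSE)
  stats::approx(tab$wavelength, tab$delta, xout = wavelength)$y
}

#' @describeIn fluoresceinCrossSection the full reference table as a
#'   data.frame with columns \code{wavelength} (nm) and \code{delta} (GM).
#' @export
fluoresceinReference <- function() {
  data.frame(
    wavelength = seq(750, 990, by = 10),
    delta = c(36, 37, 36, 37, 36, 36, 38, 36, 31, 28, 24, 20, 18,
              16, 15, 16, 18, 21, 23, 26, 28, 29, 28, 24, 16))
}
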