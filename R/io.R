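## Delimited-text readers for the formats the analysis functions consume,
## and JSON persistence for iPEAQ calibrations.

## Internal: read a delimited table, tolerating '#' comments and an
## optional header line.
.readTable <- function(file, nCols = NULL) {
  first <- utils::read.table(file, comment.char = "#", nrows = 1,
                             stringsAsFactors = FALSE)
  header <- !all(vapply(first, is.numeric, logical(1)))
  tab <- utils::read.table(file, comment.char = "#", header = header,
                           stringsAsFactors = FALSE)
  if (!is.null(nCols) && ncol(tab) < nCols)
    stop("expected at least ", nCols, " columns in ", file, call. = FALSE)
  tab
}

#' Read an absorbance spectrum from a two-column text file
#'
#' Format: wavelength (nm) and value per line, any whitespace/comma
#' delimiter, '#' comments, header optional. Condition metadata are given
#' as arguments.
#'
#' @param file path to the spectrum file.
#' @param ph,caState,mgPresent condition metadata (see
#'   \linkS4class{AbsorbanceSpectrum}).
#' @return an \linkS4class{AbsorbanceSpectrum}.
#' @export
readSpectrum <- function(file, ph = NA_real_, caState = "ca_free",
                         mgPresent = FALSE) {
  tab <- .readTable(file, 2)
  AbsorbanceSpectrum(tab[[1]], tab[[2]], ph = ph, caState = caState,
                     mgPresent = mgPresent)
}

#' Read ROI fluorescence traces from a delimited table
#'
#' Format: first column time (s), remaining columns one per ROI.
#'
#' @param file path to the trace table.
#' @param baselineWindow,stimOnsets passed to
#'   \code{\link{FluorescenceTrace}} for each ROI.
#' @return a named list of \linkS4class{FluorescenceTrace}, one per ROI
#'   column.
#' @export
readTraceTable <- function(file, baselineWindow = NULL,
                           stimOnsets = numeric()) {
  tab <- .readTable(file, 2)
  time <- tab[[1]]
  rois <- tab[-1]
  out <- lapply(rois, function(f)
    FluorescenceTrace(time, f, baselineWindow = baselineWindow,
                      stimOnsets = stimOnsets))
  names(out) <- names(rois)
  out
}

#' Read a photochromic trace (time, fluorescence, violet flag)
#'
#' Format: three columns - time (s), fluorescence (a.u.), violet-on flag
#' (0/1).
#'
#' @param file path to the trace file.
#' @return a \linkS4class{PhotochromicTrace}.
#' @export
readPhotochromicTrace <- function(file) {
  tab <- .readTable(file, 3)
  PhotochromicTrace(tab[[1]], tab[[2]], tab[[3]] != 0)
}

#' Read a trial-structured tuning table
#'
#' Format: columns \code{theta} (deg), \code{trial}, \code{dff} (and
#' optionally \code{time}, \code{roi}); header required.
#'
#' @param file path to the trial table.
#' @return a data.frame suitable for \code{\link{tuningCurve}}.
#' @export
readTrialTable <- function(file) {
  tab <- utils::read.table(file, comment.char = "#", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("theta", "trial", "dff")
  if (!all(need %in% names(tab)))
    stop("trial table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  tab
}

#' Save / load an iPEAQ calibration as JSON
#'
#' @param calibration an \linkS4class{IPEAQCalibration}.
#' @param file path to the JSON file.
#' @return \code{loadCalibration} returns the
#'   \linkS4class{IPEAQCalibration}; \code{saveCalibration} returns
#'   \code{file} invisibly.
#' @export
saveCalibration <- function(calibration, file) {
  stopifnot(is(calibration, "IPEAQCalibration"))
  asList <- function(h) list(y0 = h@y0, yInf = h@yInf, kd = h@kd, h = h@h,
                             se = as.list(h@se))
  jsonlite::write_json(
    list(contrastCurve = asList(calibration@contrastCurve),
         fluorCurve = asList(calibration@fluorCurve)),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname saveCalibration
#' @export
loadCalibration <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  asFit <- function(l) {
    se <- unlist(l$se)
    if (is.null(se)) se <- c(y0 = NA_real_, yInf = NA_real_,
                             kd = NA_real_, h = NA_real_)
    new("HillFit", y0 = l$y0, yInf = l$yInf, kd = l$kd, h = l$h, se = se)
  }
  new("IPEAQCalibration", contrastCurve = asFit(x$contrastCurve),
      fluorCurve = asFit(x$fluorCurve))
}
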