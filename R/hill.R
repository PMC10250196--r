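## Shared Hill ("specific binding with Hill slope") machinery used by the
## titration, pKa and iPEAQ fits.

#' Evaluate a Hill curve
#'
#' @param fit a \linkS4class{HillFit}.
#' @param x ligand concentration(s), same units as \code{kd(fit)}.
#' @return response at \code{x}.
#' @export
hillEval <- function(fit, x) {
  stopifnot(is(fit, "HillFit"))
  frac <- ifelse(x <= 0, 0, x^fit@h / (fit@kd^fit@h + x^fit@h))
  fit@y0 + (fit@yInf - fit@y0) * frac
}

#' Invert a Hill curve analytically
#'
#' Solves y = y0 + (yInf - y0) x^h / (kd^h + x^h) for x. Responses are
#' clipped to the open range of the curve at a fractional margin from each
#' plateau (default 0.5\% of the span) to bound the error amplification near
#' saturation; clipped points are flagged via the \code{"outOfRange"}
#' attribute.
#'
#' @param fit a \linkS4class{HillFit}.
#' @param y response value(s) to invert.
#' @param clip fractional distance from each plateau at which to clip.
#' @return concentrations, with logical attribute \code{outOfRange}.
#' @export
hillInverse <- function(fit, y, clip = 0.005) {
  stopifnot(is(fit, "HillFit"))
  span <- fit@yInf - fit@y0
  lo <- fit@y0 + clip * span
  hi <- fit@yInf - clip * span
  ymin <- min(lo, hi); ymax <- max(lo, hi)
  out <- y < ymin | y > ymax
  yc <- pmin(pmax(y, ymin), ymax)
  frac <- (yc - fit@y0) / span           # in (0, 1) after clipping
  x <- fit@kd * (frac / (1 - frac))^(1 / fit@h)
  attr(x, "outOfRange") <- out
  x
}

## Internal: 4-parameter Hill fit by Levenberg-Marquardt least squares.
## Initialization per the package conventions: plateaus from the 5th/95th
## percentiles, kd from the concentration nearest half-range, h start 2.
## `decreasing = NA` lets the data decide the orientation.
.fitHill4 <- function(x, y, decreasing = NA, hStart = 2) {
  stopifnot(length(x) == length(y))
  if (length(x) < 5)
    stop("need at least 5 concentrations for a Hill fit")
  if (diff(range(y)) <= 1e-12 * max(abs(y), 1))
    stop("unidentifiable Kd: response is constant across concentrations")
  dec <- if (is.na(decreasing)) {
    stats::cor(log10(pmax(x, min(x[x > 0]) / 10)), y) < 0
  } else decreasing
  qs <- stats::quantile(y, c(0.05, 0.95), names = FALSE)
  y0s <- if (dec) qs[2] else qs[1]
  yIs <- if (dec) qs[1] else qs[2]
  half <- (y0s + yIs) / 2
  kds <- x[which.min(abs(y - half))]
  if (kds <= 0) kds <- stats::median(x[x > 0])
  df <- data.frame(x = x, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ y0 + (yInf - y0) * ifelse(x <= 0, 0, x^h / (kd^h + x^h)),
      data = df,
      start = list(y0 = y0s, yInf = yIs, kd = kds, h = hStart),
      lower = c(y0 = -Inf, yInf = -Inf, kd = 1e-12, h = 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("unidentifiable Kd: Hill fit failed (", conditionMessage(e), ")",
           call. = FALSE))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 4))
  names(se) <- c("y0", "yInf", "kd", "h")
  if (cf[["kd"]] < min(x[x > 0]) / 50 || cf[["kd"]] > max(x) * 50)
    stop("unidentifiable Kd: fitted half-saturation (", signif(cf[["kd"]], 3),
         ") lies far outside the sampled concentration range",
         call. = FALSE)
  new("HillFit", y0 = unname(cf["y0"]), yInf = unname(cf["yInf"]),
      kd = unname(cf["kd"]), h = unname(cf["h"]), se = se)
}
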