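# Temperature calibration: set temperature vs measured (surface or well)
# temperature, and conversion of pad-scale melting points to the well scale.

#' Fit a temperature calibration line
#'
#' Ordinary least squares of measured temperature on set temperature, as in
#' the instrument validation where averaged probe readings are plotted
#' against the software setpoint. The measured pad-surface relation is
#' y = 1.008 x + 0.366 and the in-well relation y = 0.681 x + 7.034.
#'
#' @param set_temps Set temperatures, degC; at least 3 distinct values.
#' @param measured Measured temperatures, degC; same length.
#'
#' @return An object of class `calibration_line` with `slope`, `intercept`,
#'   their standard errors `slope_se`, `intercept_se`, and the residual sd
#'   `resid_sd` (degC).
#' @export
fit_calibration <- function(set_temps, measured) {
  stopifnot(is.numeric(set_temps), is.numeric(measured),
            length(set_temps) == length(measured))
  if (length(set_temps) < 3) stop("need at least 3 points", call. = FALSE)
  if (stats::var(set_temps) == 0) {
    stop("set temperatures have zero variance", call. = FALSE)
  }
  fit <- stats::lm(measured ~ set_temps)
  sm <- suppressWarnings(summary(fit))  # exact fits trip lm's sigma warning
  cf <- sm$coefficients
  structure(list(slope = unname(cf["set_temps", "Estimate"]),
                 intercept = unname(cf["(Intercept)", "Estimate"]),
                 slope_se = unname(cf["set_temps", "Std. Error"]),
                 intercept_se = unname(cf["(Intercept)", "Std. Error"]),
                 resid_sd = sm$sigma),
            class = "calibration_line")
}

#' Construct a calibration line directly
#'
#' @param slope Dimensionless slope; positive.
#' @param intercept Intercept, degC.
#' @param slope_se,intercept_se,resid_sd Optional uncertainties, degC.
#' @return A `calibration_line`.
#' @export
calibration_line <- function(slope = 0.681, intercept = 7.034,
                             slope_se = NA_real_, intercept_se = NA_real_,
                             resid_sd = NA_real_) {
  stopifnot(slope > 0)
  structure(list(slope = slope, intercept = intercept, slope_se = slope_se,
                 intercept_se = intercept_se, resid_sd = resid_sd),
            class = "calibration_line")
}

#' @export
print.calibration_line <- function(x, ...) {
  cat(sprintf("Calibration line: y = %.3f x + %.3f (SE %.3g / %.3g, resid sd %.3g degC)\n",
              x$slope, x$intercept, x$slope_se, x$intercept_se, x$resid_sd))
  invisible(x)
}

#' Convert a pad-scale temperature to the well scale
#'
#' Applies `tm_well = slope * tm_pad + intercept`. The experimentally
#' determined well line lets the actual sample temperature be computed from
#' the pad reference scale (e.g. a 95 degC pad setpoint corresponds to
#' about 71.7 degC in the wells with the default line).
#'
#' @param tm_pad Pad-scale temperature(s), degC.
#' @param cal A `calibration_line`.
#' @return Well-scale temperature(s), degC.
#' @export
apply_well_calibration <- function(tm_pad, cal = calibration_line()) {
  stopifnot(inherits(cal, "calibration_line"))
  cal$slope * tm_pad + cal$intercept
}
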