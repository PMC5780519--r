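# Pad-to-well thermal lag

#' Well thermal-lag model
#'
#' The sample-well temperature lags the heat-pad temperature; validation
#' with in-well probes gives a linear transfer
#' `t_well = gain * t_pad + offset` with well-to-well Gaussian scatter.
#' Defaults are the measured line y = 0.681 x + 7.034 and the measured
#' average well-to-well standard deviation of 0.8 degC.
#'
#' @param gain Dimensionless slope; positive.
#' @param offset Intercept, degC.
#' @param well_noise_sd Well-to-well Gaussian sd, degC; non-negative.
#'
#' @return An object of class `well_thermal_model`.
#' @export
well_thermal_model <- function(gain = 0.681, offset = 7.034,
                               well_noise_sd = 0.8) {
  stopifnot(gain > 0, well_noise_sd >= 0)
  structure(list(gain = gain, offset = offset,
                 well_noise_sd = well_noise_sd),
            class = "well_thermal_model")
}

#' Map pad temperature to well temperature
#'
#' `t_well = gain * t_pad + offset + N(0, well_noise_sd)`. Vectorised over
#' `t_pad`; noise is drawn from the current RNG stream (seed it with
#' `set.seed()` for reproducibility), independently per element.
#'
#' @param t_pad Pad temperature(s), degC.
#' @param model A [well_thermal_model()].
#'
#' @return Well temperature(s), degC.
#' @examples
#' pad_to_well_temperature(95, well_thermal_model(well_noise_sd = 0))
#' # 0.681 * 95 + 7.034 = 71.729 degC
#' @export
pad_to_well_temperature <- function(t_pad, model = well_thermal_model()) {
  stopifnot(inherits(model, "well_thermal_model"), is.numeric(t_pad))
  out <- model$gain * t_pad + model$offset
  if (model$well_noise_sd > 0) {
    out <- out + stats::rnorm(length(t_pad), 0, model$well_noise_sd)
  }
  out
}
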