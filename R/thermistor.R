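# NTC thermistor model (beta equation)

#' Thermistor specification
#'
#' Describes a negative-temperature-coefficient (NTC) glass-bead thermistor
#' by its beta equation constants: `1/T = 1/t0 + ln(R/r0)/beta`, with all
#' temperatures in kelvin.
#'
#' @param beta Beta value in kelvin. Must be positive.
#' @param r0 Resistance in ohm at the reference temperature. Must be positive.
#' @param t0 Reference temperature in kelvin. Must be positive.
#'
#' @return An object of class `thermistor_spec`.
#' @examples
#' spec <- thermistor_spec(beta = 3950, r0 = 10000, t0 = 298.15)
#' ntc_temperature(10000, spec)  # 25 degC at the reference resistance
#' @export
thermistor_spec <- function(beta = 3950, r0 = 10000, t0 = 298.15) {
  stopifnot(is.numeric(beta), length(beta) == 1, beta > 0,
            is.numeric(r0), length(r0) == 1, r0 > 0,
            is.numeric(t0), length(t0) == 1, t0 > 0)
  structure(list(beta = beta, r0 = r0, t0 = t0), class = "thermistor_spec")
}

KELVIN_OFFSET <- 273.15

#' Convert thermistor resistance to temperature
#'
#' Applies the beta equation `1/T = 1/t0 + ln(R/r0)/beta` (kelvin internally)
#' and returns the temperature in degrees Celsius. Vectorised over
#' `resistance`.
#'
#' @param resistance Resistance in ohm; all values must be positive.
#' @param spec A [thermistor_spec()].
#'
#' @return Temperature in degrees Celsius.
#' @seealso [ntc_resistance()] for the inverse.
#' @export
ntc_temperature <- function(resistance, spec = thermistor_spec()) {
  stopifnot(inherits(spec, "thermistor_spec"), is.numeric(resistance))
  if (length(resistance) == 0 || any(!is.finite(resistance)) ||
      any(resistance <= 0)) {
    stop("`resistance` must be finite and positive", call. = FALSE)
  }
  inv_t <- 1 / spec$t0 + log(resistance / spec$r0) / spec$beta
  1 / inv_t - KELVIN_OFFSET
}

#' Convert temperature to thermistor resistance
#'
#' Inverse of [ntc_temperature()]: `R = r0 * exp(beta * (1/T - 1/t0))` with
#' `T` in kelvin.
#'
#' @param temperature Temperature in degrees Celsius; must exceed absolute
#'   zero.
#' @param spec A [thermistor_spec()].
#'
#' @return Resistance in ohm.
#' @export
ntc_resistance <- function(temperature, spec = thermistor_spec()) {
  stopifnot(inherits(spec, "thermistor_spec"), is.numeric(temperature))
  t_k <- temperature + KELVIN_OFFSET
  if (any(t_k <= 0)) stop("temperature below absolute zero", call. = FALSE)
  spec$r0 * exp(spec$beta * (1 / t_k - 1 / spec$t0))
}
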