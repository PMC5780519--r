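# Discrete PID controller with anti-windup, plus the sensor averaging step
# the firmware performs before each control decision.

#' PID controller configuration
#'
#' Gains are expressed in heater-duty units: `kp` in duty per degC of error,
#' `ki` in duty per degC*s of accumulated error, `kd` in duty per degC/s of
#' error rate. The integral contribution (`ki * I`) is clamped to
#' `+/- integral_clamp` duty units (anti-windup), and the final duty is
#' clamped into `[duty_min, duty_max]`.
#'
#' The default gains are package constants tuned for the default heat-pad
#' plant; they are configuration values, not measured hardware properties.
#'
#' @param kp,ki,kd Proportional, integral and derivative gains.
#' @param duty_min,duty_max Output saturation bounds, dimensionless in
#'   `[0, 1]`.
#' @param integral_clamp Bound on the integral contribution, in duty units.
#' @param tick Control-loop period in seconds.
#' @param n_average Number of raw sensor readings averaged per control
#'   decision (at least 1).
#'
#' @return An object of class `pid_config`.
#' @export
pid_config <- function(kp = 1.0, ki = 0.02, kd = 0,
                       duty_min = 0, duty_max = 1,
                       integral_clamp = 0.9, tick = 1, n_average = 8) {
  stopifnot(duty_min < duty_max, tick > 0, n_average >= 1,
            integral_clamp >= 0, kp >= 0, ki >= 0, kd >= 0)
  structure(list(kp = kp, ki = ki, kd = kd,
                 duty_min = duty_min, duty_max = duty_max,
                 integral_clamp = integral_clamp,
                 tick = tick, n_average = as.integer(n_average)),
            class = "pid_config")
}

#' Fresh internal state for a PID controller
#'
#' @return A list with zeroed integral and no previous error.
#' @export
pid_state <- function() {
  list(integral = 0, prev_error = NA_real_)
}

#' Average a window of sensor readings
#'
#' The firmware reduces sensor noise by averaging several consecutive
#' temperature readings before each control decision; this is that
#' arithmetic mean.
#'
#' @param samples Numeric vector of temperature readings in degC; must be
#'   non-empty.
#'
#' @return The arithmetic mean, a single temperature in degC.
#' @export
average_sensor_readings <- function(samples) {
  if (!is.numeric(samples) || length(samples) == 0) {
    stop("`samples` must be a non-empty numeric vector", call. = FALSE)
  }
  mean(samples)
}

#' One PID update step
#'
#' Computes the saturated duty cycle
#' `clamp(kp*e + clamp(ki*I, +/-integral_clamp) + kd*de/dt)` for the error
#' `e = setpoint - measured`, and returns the updated controller state. The
#' integral accumulates `e * dt`; its contribution is clamped before the
#' output saturation (anti-windup). The derivative term is zero on the first
#' call, when no previous error exists.
#'
#' @param state Controller state from [pid_state()] or a previous call.
#' @param setpoint Target temperature, degC.
#' @param measured Measured (averaged) temperature, degC.
#' @param dt Time step in seconds, positive.
#' @param cfg A [pid_config()].
#'
#' @return A list with elements `duty` (in `[duty_min, duty_max]`) and
#'   `state` (the updated state).
#' @export
pid_update <- function(state, setpoint, measured, dt, cfg = pid_config()) {
  stopifnot(inherits(cfg, "pid_config"), dt > 0)
  e <- setpoint - measured

  integral <- state$integral + e * dt
  i_term <- cfg$ki * integral
  if (i_term > cfg$integral_clamp) {
    i_term <- cfg$integral_clamp
    if (cfg$ki > 0) integral <- cfg$integral_clamp / cfg$ki
  } else if (i_term < -cfg$integral_clamp) {
    i_term <- -cfg$integral_clamp
    if (cfg$ki > 0) integral <- -cfg$integral_clamp / cfg$ki
  }

  d_term <- if (is.na(state$prev_error)) 0 else cfg$kd * (e - state$prev_error) / dt
  duty <- cfg$kp * e + i_term + d_term
  duty <- min(max(duty, cfg$duty_min), cfg$duty_max)

  list(duty = duty, state = list(integral = integral, prev_error = e))
}
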