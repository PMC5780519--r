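# Closed-loop simulation of the silicone heat pad under PID control.
#
# The plant is a first-order lumped thermal model integrated by explicit
# Euler at the controller tick:
#   dT/dt = (max_power * duty - loss_coeff * (T - t_ambient)) / heat_capacity
# The solid-state relay is represented by its time-proportioned mean power,
# i.e. a continuous duty in [0, 1] per tick.

#' Heat-pad plant parameters
#'
#' A first-order lumped thermal model of the silicone heat pad, plus the
#' pad-surface calibration line relating the internal (thermistor) pad
#' temperature to the calibrated surface temperature reported by the
#' instrument: `surface = surface_gain * pad + surface_offset`. The default
#' surface line is the measured relation y = 1.008 x + 0.366.
#'
#' The thermal constants (`heat_capacity`, `max_power`, `loss_coeff`) are
#' package defaults chosen so the closed loop settles well within a 5-minute
#' dwell; they parameterise the simulator, not a specific physical pad.
#'
#' @param heat_capacity Lumped heat capacity, J/degC.
#' @param max_power Heater power at duty 1, W.
#' @param loss_coeff Heat-loss coefficient to ambient, W/degC.
#' @param t_ambient Ambient temperature, degC.
#' @param sensor_noise_sd Gaussian noise sd of a single thermistor reading,
#'   degC.
#' @param surface_gain,surface_offset Pad-surface calibration line
#'   (dimensionless gain, degC offset).
#'
#' @return An object of class `heat_pad_plant`.
#' @export
heat_pad_plant <- function(heat_capacity = 200, max_power = 50,
                           loss_coeff = 0.5, t_ambient = 22,
                           sensor_noise_sd = 0.1,
                           surface_gain = 1.008, surface_offset = 0.366) {
  stopifnot(heat_capacity > 0, max_power > 0, loss_coeff > 0,
            sensor_noise_sd >= 0, surface_gain > 0)
  structure(list(heat_capacity = heat_capacity, max_power = max_power,
                 loss_coeff = loss_coeff, t_ambient = t_ambient,
                 sensor_noise_sd = sensor_noise_sd,
                 surface_gain = surface_gain,
                 surface_offset = surface_offset),
            class = "heat_pad_plant")
}

#' Simulate the PID-controlled heat pad over a schedule
#'
#' Runs the closed loop tick by tick: at each control tick `n_average` noisy
#' thermistor readings are drawn and averaged, the PID law produces a duty
#' cycle, and the plant temperature is advanced by explicit Euler. Each
#' setpoint is held for the schedule dwell. The trace is deterministic for a
#' fixed seed.
#'
#' @param plant A [heat_pad_plant()].
#' @param cfg A [pid_config()].
#' @param schedule A [build_schedule()] schedule; must be non-empty.
#' @param seed Integer seed for the sensor-noise stream.
#'
#' @return A data frame of class `temperature_trace` with one row per
#'   control tick: `time` (s), `setpoint` (degC), `pad_temp` (degC, true
#'   plant temperature), `duty` (in `[duty_min, duty_max]`).
#' @export
simulate_heat_pad <- function(plant = heat_pad_plant(), cfg = pid_config(),
                              schedule = build_schedule(), seed = 1) {
  stopifnot(inherits(plant, "heat_pad_plant"), inherits(cfg, "pid_config"),
            inherits(schedule, "dsf_schedule"))
  if (length(schedule$setpoints) == 0) stop("empty schedule", call. = FALSE)
  set.seed(as.integer(seed))

  ticks_per_step <- max(1L, round(schedule$dwell * 60 / cfg$tick))
  n_total <- ticks_per_step * length(schedule$setpoints)
  time <- numeric(n_total); sp <- numeric(n_total)
  temp <- numeric(n_total); duty <- numeric(n_total)

  state <- pid_state()
  t_pad <- plant$t_ambient
  i <- 0L
  for (setpoint in schedule$setpoints) {
    for (k in seq_len(ticks_per_step)) {
      i <- i + 1L
      readings <- t_pad + if (plant$sensor_noise_sd > 0) {
        stats::rnorm(cfg$n_average, 0, plant$sensor_noise_sd)
      } else rep(0, cfg$n_average)
      measured <- average_sensor_readings(readings)
      upd <- pid_update(state, setpoint, measured, cfg$tick, cfg)
      state <- upd$state
      dT <- (plant$max_power * upd$duty -
               plant$loss_coeff * (t_pad - plant$t_ambient)) /
        plant$heat_capacity
      t_pad <- t_pad + dT * cfg$tick
      time[i] <- i * cfg$tick
      sp[i] <- setpoint
      temp[i] <- t_pad
      duty[i] <- upd$duty
    }
  }
  structure(data.frame(time = time, setpoint = sp, pad_temp = temp,
                       duty = duty),
            class = c("temperature_trace", "data.frame"))
}

#' Terminal steady-state pad temperature per setpoint
#'
#' For each setpoint of a trace, averages the pad temperature over the last
#' `window` seconds of its dwell — the value the instrument reports as the
#' achieved step temperature.
#'
#' @param trace A `temperature_trace` from [simulate_heat_pad()].
#' @param window Averaging window at the end of each dwell, seconds.
#'
#' @return A data frame with columns `setpoint` and `pad_temp`.
#' @export
steady_state_temps <- function(trace, window = 60) {
  stopifnot(inherits(trace, "temperature_trace"), window > 0)
  sps <- unique(trace$setpoint)
  out <- vapply(sps, function(s) {
    seg <- trace[trace$setpoint == s, ]
    t_end <- max(seg$time)
    mean(seg$pad_temp[seg$time > t_end - window])
  }, numeric(1))
  data.frame(setpoint = sps, pad_temp = out)
}

#' Calibrated pad-surface temperature
#'
#' Applies the pad-surface calibration line of the plant to internal pad
#' temperatures.
#'
#' @param t_pad Internal pad temperature(s), degC.
#' @param plant A [heat_pad_plant()].
#' @return Surface temperature(s), degC.
#' @export
pad_surface_temperature <- function(t_pad, plant = heat_pad_plant()) {
  stopifnot(inherits(plant, "heat_pad_plant"))
  plant$surface_gain * t_pad + plant$surface_offset
}
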