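# Heat/incubate/measure step schedule

#' Build a temperature step schedule
#'
#' The instrument cycles through heating, incubation and measurement at a
#' ladder of setpoints. The default routine steps from 25 degC in 3 degC
#' increments up to a 95 degC ceiling, dwelling 5 minutes per step
#' (incubation plus measurement), for 24 steps and 120 minutes total.
#'
#' @param start First setpoint, degC.
#' @param step Setpoint increment, degC; must be positive.
#' @param ceiling Maximal setpoint, degC; setpoints never exceed it.
#' @param dwell Dwell (incubation + measurement) per step, minutes; positive.
#'
#' @return An object of class `dsf_schedule` with fields `start`, `step`,
#'   `ceiling`, `dwell` and the derived `setpoints` vector (degC, strictly
#'   increasing) plus `total_minutes`.
#' @examples
#' sch <- build_schedule()
#' length(sch$setpoints)  # 24
#' sch$total_minutes      # 120
#' @export
build_schedule <- function(start = 25, step = 3, ceiling = 95, dwell = 5) {
  if (!is.numeric(step) || step <= 0) stop("`step` must be > 0", call. = FALSE)
  if (!is.numeric(dwell) || dwell <= 0) stop("`dwell` must be > 0", call. = FALSE)
  if (ceiling < start) stop("`ceiling` must be >= `start`", call. = FALSE)
  setpoints <- seq(start, ceiling, by = step)
  structure(list(start = start, step = step, ceiling = ceiling,
                 dwell = dwell, setpoints = setpoints,
                 total_minutes = length(setpoints) * dwell),
            class = "dsf_schedule")
}

#' @export
print.dsf_schedule <- function(x, ...) {
  cat(sprintf("DSF schedule: %d setpoints from %.1f to %.1f degC (step %.1f), %g min dwell, %g min total\n",
              length(x$setpoints), x$setpoints[1],
              x$setpoints[length(x$setpoints)], x$step, x$dwell,
              x$total_minutes))
  invisible(x)
}
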