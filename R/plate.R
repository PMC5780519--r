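# Plate layouts and synthetic plate runs

VALID_WELLS <- as.vector(outer(LETTERS[1:8], 1:12, paste0))

#' Define one plate group
#'
#' A group is a set of wells sharing a condition: replicate sample wells or
#' blank wells (reaction mixture without protein). Blank groups must not
#' carry an unfolding model.
#'
#' @param wells Character vector of well ids (`A1`..`H12`).
#' @param condition Condition label (e.g. `"pH 6.0"`).
#' @param dye A [dye_model()].
#' @param unfolding An [unfolding_model()] for sample groups; `NULL` for
#'   blanks.
#' @param blank Logical: is this a blank group?
#' @param replicate_group Replicate-group label; defaults to `condition`.
#' @param blank_condition For sample groups, the condition label of the
#'   blank group to subtract during analysis (`NULL`: use the plate's single
#'   blank group if there is exactly one).
#'
#' @return A `plate_group` list.
#' @export
plate_group <- function(wells, condition, dye = dye_model(),
                        unfolding = NULL, blank = FALSE,
                        replicate_group = condition,
                        blank_condition = NULL) {
  stopifnot(length(wells) >= 1, all(wells %in% VALID_WELLS),
            inherits(dye, "dye_model"))
  if (blank && !is.null(unfolding)) {
    stop("blank groups must not have an unfolding model", call. = FALSE)
  }
  if (!blank && is.null(unfolding)) {
    stop("sample groups need an unfolding model", call. = FALSE)
  }
  structure(list(wells = wells, condition = condition, dye = dye,
                 unfolding = unfolding, blank = blank,
                 replicate_group = replicate_group,
                 blank_condition = blank_condition),
            class = "plate_group")
}

#' Assemble a plate layout
#'
#' @param ... [plate_group()] objects (or a single list of them).
#'
#' @return An object of class `plate_layout`: a list of groups plus a
#'   well-to-group index. Errors on overlapping well assignments.
#' @export
plate_layout <- function(...) {
  groups <- list(...)
  if (length(groups) == 1 && !inherits(groups[[1]], "plate_group")) {
    groups <- groups[[1]]
  }
  stopifnot(length(groups) >= 1,
            all(vapply(groups, inherits, logical(1), "plate_group")))
  all_wells <- unlist(lapply(groups, `[[`, "wells"))
  dup <- all_wells[duplicated(all_wells)]
  if (length(dup) > 0) {
    stop("well(s) assigned to more than one group: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  structure(list(groups = groups, wells = all_wells),
            class = "plate_layout")
}

layout_group_of_well <- function(layout, well) {
  for (g in layout$groups) if (well %in% g$wells) return(g)
  NULL
}

#' Simulate a full plate run
#'
#' For every schedule step and well, the signal chain is: pad setpoint ->
#' well temperature (linear lag + well noise) -> unfolded fraction ->
#' dye fluorescence (+ measurement noise). Blank wells produce only
#' background and interference. Temperatures are recorded on the pad
#' (setpoint) scale, the reference scale of the instrument. Deterministic
#' for a fixed seed.
#'
#' @param layout A [plate_layout()].
#' @param schedule A [build_schedule()] schedule.
#' @param well_model A [well_thermal_model()].
#' @param seed Integer seed.
#'
#' @return An object of class `raw_run`: a list with `data` (data frame
#'   `step`, `setpoint`, `well`, `fluorescence`; `n_steps * n_wells` rows),
#'   `schedule`, `seed` and `layout` metadata.
#' @export
simulate_plate_run <- function(layout, schedule = build_schedule(),
                               well_model = well_thermal_model(),
                               seed = 1) {
  stopifnot(inherits(layout, "plate_layout"),
            inherits(schedule, "dsf_schedule"),
            inherits(well_model, "well_thermal_model"))
  if (length(layout$wells) == 0) stop("empty layout", call. = FALSE)
  set.seed(as.integer(seed))

  wells <- layout$wells
  setpoints <- schedule$setpoints
  n_steps <- length(setpoints)
  rows <- vector("list", n_steps)
  for (s in seq_len(n_steps)) {
    t_pad <- setpoints[s]
    fl <- numeric(length(wells))
    for (w in seq_along(wells)) {
      g <- layout_group_of_well(layout, wells[w])
      t_well <- pad_to_well_temperature(t_pad, well_model)
      if (g$blank) {
        f <- g$dye$background +
          g$dye$interference_level * interference_profile(t_well)
      } else {
        frac <- unfolded_fraction(t_well, g$unfolding)
        f <- fluorescence_signal(frac, t_well, g$dye,
                                 full_denaturation_temp(g$unfolding))
      }
      noise_sd <- g$dye$noise_floor + g$dye$noise_prop * abs(f)
      if (noise_sd > 0) f <- f + stats::rnorm(1, 0, noise_sd)
      fl[w] <- max(f, 0)
    }
    rows[[s]] <- data.frame(step = s, setpoint = t_pad, well = wells,
                            fluorescence = fl)
  }
  structure(list(data = do.call(rbind, rows), schedule = schedule,
                 seed = as.integer(seed), layout = layout),
            class = "raw_run")
}

#' @export
print.raw_run <- function(x, ...) {
  cat(sprintf("DSF raw run: %d wells x %d steps (%.1f-%.1f degC), seed %d\n",
              length(unique(x$data$well)), max(x$data$step),
              min(x$data$setpoint), max(x$data$setpoint), x$seed))
  invisible(x)
}
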