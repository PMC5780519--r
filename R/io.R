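# Run-workbook reader/writer and plate-map parsing.
#
# The instrument stores one table of per-well fluorescence per temperature
# step in a single output workbook. The package's on-disk dialect is a plain
# run directory: a JSON manifest plus one delimited table per step, named
# "T_<setpoint>.csv" with the setpoint at 1 decimal — equivalent in content
# to a one-sheet-per-step spreadsheet and diffable under version control.

sheet_name <- function(setpoint) sprintf("T_%.1f", setpoint)

#' Write a run workbook
#'
#' Writes a `raw_run` as a run directory: `manifest.json` (schedule, seed,
#' well list, ordered sheet names) and one CSV per temperature step with
#' columns `well` and `fluorescence`, named `T_<setpoint>.csv`.
#'
#' @param run A `raw_run`.
#' @param path Directory to create/populate.
#'
#' @return `path`, invisibly.
#' @export
write_run_workbook <- function(run, path) {
  stopifnot(inherits(run, "raw_run"))
  if (nrow(run$data) == 0 || length(unique(run$data$well)) == 0) {
    stop("run has no wells", call. = FALSE)
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  sch <- run$schedule
  sheets <- vapply(sch$setpoints, sheet_name, character(1))
  manifest <- list(
    format = "dsf-run-directory-v1",
    schedule = list(start = sch$start, step = sch$step,
                    ceiling = sch$ceiling, dwell = sch$dwell),
    seed = run$seed,
    wells = unique(run$data$well),
    sheets = sheets)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (s in seq_along(sch$setpoints)) {
    sub <- run$data[run$data$step == s, c("well", "fluorescence")]
    utils::write.csv(format(sub, digits = 17, trim = TRUE, scientific = FALSE),
                     file.path(path, paste0(sheets[s], ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a run workbook
#'
#' Inverse of [write_run_workbook()]. Validates that every per-step table
#' carries exactly the manifest's well set; a ragged sheet is rejected with
#' an error naming it.
#'
#' @param path Run directory written by [write_run_workbook()].
#'
#' @return A `raw_run` (with `layout = NULL`).
#' @export
read_run_workbook <- function(path) {
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path)) {
    stop("missing manifest.json in ", path, call. = FALSE)
  }
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  sch <- build_schedule(start = mf$schedule$start, step = mf$schedule$step,
                        ceiling = mf$schedule$ceiling,
                        dwell = mf$schedule$dwell)
  if (length(mf$sheets) != length(sch$setpoints)) {
    stop("manifest sheet count does not match schedule", call. = FALSE)
  }
  wells <- mf$wells
  rows <- vector("list", length(mf$sheets))
  for (s in seq_along(mf$sheets)) {
    f <- file.path(path, paste0(mf$sheets[s], ".csv"))
    if (!file.exists(f)) stop("missing sheet ", mf$sheets[s], call. = FALSE)
    tab <- utils::read.csv(f, stringsAsFactors = FALSE)
    if (!setequal(tab$well, wells) || nrow(tab) != length(wells)) {
      stop("sheet ", mf$sheets[s], " has an inconsistent well set",
           call. = FALSE)
    }
    tab <- tab[match(wells, tab$well), ]
    rows[[s]] <- data.frame(step = s, setpoint = sch$setpoints[s],
                            well = wells,
                            fluorescence = as.numeric(tab$fluorescence))
  }
  structure(list(data = do.call(rbind, rows), schedule = sch,
                 seed = if (is.null(mf$seed)) NA_integer_ else
                   as.integer(mf$seed),
                 layout = NULL),
            class = "raw_run")
}

#' Export a run as a tidy long table
#'
#' @param run A `raw_run`.
#' @param path CSV destination.
#' @return `path`, invisibly.
#' @export
write_run_long <- function(run, path) {
  stopifnot(inherits(run, "raw_run"))
  utils::write.csv(format(run$data, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a tidy long-format run table
#'
#' Reads a CSV with columns `step`, `setpoint`, `well`, `fluorescence` (as
#' written by [write_run_long()]) back into a `raw_run`.
#'
#' @param path CSV source.
#' @param dwell Dwell minutes recorded in the rebuilt schedule.
#' @return A `raw_run`.
#' @export
read_run_long <- function(path, dwell = 5) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("step", "setpoint", "well", "fluorescence") %in% names(d)))
  d$fluorescence <- as.numeric(d$fluorescence)
  sps <- unique(d[order(d$step), "setpoint"])
  step_size <- if (length(sps) > 1) stats::median(diff(sps)) else 1
  sch <- build_schedule(start = sps[1], step = step_size,
                        ceiling = sps[length(sps)], dwell = dwell)
  structure(list(data = d[, c("step", "setpoint", "well", "fluorescence")],
                 schedule = sch, seed = NA_integer_, layout = NULL),
            class = "raw_run")
}

dye_from_config <- function(cfg) {
  if (is.null(cfg)) return(dye_model())
  do.call(dye_model, cfg)
}

unfolding_from_config <- function(cfg) {
  if (is.null(cfg)) return(NULL)
  unfolding_model(tm_true = unlist(cfg$tm),
                  slope_factor = if (is.null(cfg$slope_factor)) 2 else
                    unlist(cfg$slope_factor),
                  weight = if (is.null(cfg$weight)) NULL else
                    unlist(cfg$weight))
}

#' Parse a plate-map config file
#'
#' Reads a YAML plate map with a `groups` list; each entry gives `wells`,
#' `condition`, optional `blank` flag, optional `dye` block (arguments of
#' [dye_model()]), an `unfolding` block (`tm`, `slope_factor`, `weight`) for
#' sample groups, and an optional `blank_condition`. Overlapping well
#' assignments, unknown dye kinds and blank groups carrying unfolding
#' parameters are rejected.
#'
#' @param path YAML file.
#' @return A [plate_layout()].
#' @export
parse_plate_map <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$groups) || length(cfg$groups) == 0) {
    stop("plate map has no `groups`", call. = FALSE)
  }
  groups <- lapply(cfg$groups, function(g) {
    if (is.null(g$wells) || is.null(g$condition)) {
      stop("each group needs `wells` and `condition`", call. = FALSE)
    }
    blank <- isTRUE(g$blank)
    if (blank && !is.null(g$unfolding)) {
      stop("blank group '", g$condition,
           "' must not have unfolding parameters", call. = FALSE)
    }
    plate_group(wells = unlist(g$wells), condition = g$condition,
                dye = dye_from_config(g$dye),
                unfolding = unfolding_from_config(g$unfolding),
                blank = blank,
                replicate_group = if (is.null(g$replicate_group))
                  g$condition else g$replicate_group,
                blank_condition = g$blank_condition)
  })
  plate_layout(groups)
}

#' Write a screening report as CSV
#'
#' @param report A `screen_report` from [analyze_run()].
#' @param path CSV destination.
#' @return `path`, invisibly.
#' @export
write_screen_report <- function(report, path) {
  stopifnot(inherits(report, "screen_report"))
  utils::write.csv(report, path, row.names = FALSE)
  invisible(path)
}

#' Export a temperature trace as a tidy table
#'
#' @param trace A `temperature_trace`.
#' @param path CSV destination.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "temperature_trace"))
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}
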