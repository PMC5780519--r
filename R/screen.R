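# Delta-Tm screening: thermal-shift arithmetic, fold-CMC bookkeeping and
# the end-to-end plate analysis.

#' Thermal shift between two fits
#'
#' `shift = tm_a - tm_b`, with the uncertainty combined in quadrature. A
#' positive shift means condition `a` stabilises the protein relative to
#' `b`.
#'
#' @param fit_a,fit_b Converged `boltzmann_fit` objects (or any list with
#'   `tm`, `tm_sd`, `converged`, `no_melt`).
#'
#' @return A list with `shift` and `shift_sd`, degC. If either fit is
#'   no-melt or unconverged, both are `NA` and `defined` is `FALSE`.
#' @export
delta_tm <- function(fit_a, fit_b) {
  ok <- function(f) isTRUE(f$converged) && !isTRUE(f$no_melt) &&
    is.finite(f$tm)
  if (!ok(fit_a) || !ok(fit_b)) {
    return(list(shift = NA_real_, shift_sd = NA_real_, defined = FALSE))
  }
  sd2 <- function(s) if (is.finite(s)) s^2 else 0
  list(shift = fit_a$tm - fit_b$tm,
       shift_sd = sqrt(sd2(fit_a$tm_sd) + sd2(fit_b$tm_sd)),
       defined = TRUE)
}

#' Detergent concentration as fold-CMC
#'
#' Detergent doses are conventionally expressed as multiples of the
#' critical micellar concentration; e.g. 0.05% (w/v) DDM at a CMC of
#' 0.0087% is 5.7-fold CMC.
#'
#' @param concentration Detergent concentration, % w/v.
#' @param cmc Critical micellar concentration, % w/v; positive.
#' @return Fold-CMC, rounded to 1 decimal.
#' @export
fold_cmc <- function(concentration, cmc) {
  if (!is.numeric(cmc) || any(cmc <= 0)) {
    stop("`cmc` must be > 0", call. = FALSE)
  }
  round(concentration / cmc, 1)
}

# Curves for all wells of a run, keyed by well id (temps = pad setpoints).
run_well_curves <- function(run) {
  d <- run$data
  sps <- run$schedule$setpoints
  wells <- unique(d$well)
  out <- lapply(wells, function(w) {
    sub <- d[d$well == w, ]
    sub <- sub[order(sub$step), ]
    melt_curve(sps, sub$fluorescence)
  })
  names(out) <- wells
  out
}

fit_one_curve <- function(curve, noise_mult = 5) {
  # returns list(type, tm1, tm1_sd, tm2, tm2_sd, fallback, no_melt)
  res <- list(type = "no_melt", tm1 = NA_real_, tm1_sd = NA_real_,
              tm2 = NA_real_, tm2_sd = NA_real_, fallback = FALSE,
              no_melt = TRUE)
  if (length(curve$temps) < 7) return(res)
  n_infl <- count_inflections(curve, noise_mult = noise_mult)
  if (n_infl == 0) return(res)
  if (n_infl >= 2) {
    fd <- fit_double_boltzmann(curve, noise_mult = noise_mult)
    if (fd$converged && !fd$no_melt) {
      return(list(type = "double_boltzmann", tm1 = fd$tm1,
                  tm1_sd = fd$tm1_sd, tm2 = fd$tm2, tm2_sd = fd$tm2_sd,
                  fallback = FALSE, no_melt = FALSE))
    }
  } else {
    fb <- fit_boltzmann(curve, noise_mult = noise_mult)
    if (fb$converged && !fb$no_melt) {
      return(list(type = "boltzmann", tm1 = fb$tm, tm1_sd = fb$tm_sd,
                  tm2 = NA_real_, tm2_sd = NA_real_, fallback = FALSE,
                  no_melt = FALSE))
    }
    if (fb$no_melt) return(res)
  }
  # sigmoid fit did not converge: second-derivative fallback
  tm <- tm_by_second_derivative(curve)
  if (is.na(tm)) return(res)
  list(type = "derivative", tm1 = tm, tm1_sd = NA_real_, tm2 = NA_real_,
       tm2_sd = NA_real_, fallback = TRUE, no_melt = FALSE)
}

#' Analyze a plate run into a screening report
#'
#' Runs the full evaluation pipeline per condition: per-replicate blank
#' subtraction (the mean curve of the matched blank group), replicate
#' averaging, truncation of the post-denaturation tail, transition counting,
#' Boltzmann or double-Boltzmann fitting with second-derivative fallback,
#' and delta-Tm against a reference condition. The reported Tm uncertainty
#' is the sd of replicate-wise fits when at least 3 replicates fit
#' successfully, otherwise the fit standard error.
#'
#' @param run A `raw_run` from [simulate_plate_run()] or
#'   [read_run_workbook()].
#' @param layout The matching [plate_layout()]; every well in the run must
#'   appear in it.
#' @param reference Condition label used as the delta-Tm reference
#'   (`NULL`: the first non-blank condition).
#' @param well_scale Optional `calibration_line` to report Tm on the well
#'   scale instead of the pad scale.
#' @param noise_mult Amplitude-to-noise multiple for the no-melt rule.
#'
#' @return A data frame of class `screen_report`, one row per non-blank
#'   condition: `condition`, `n_replicates`, `fit_type`, `tm1`, `tm1_sd`,
#'   `tm2`, `tm2_sd`, `fallback_used`, `no_melt`, `delta_tm`,
#'   `delta_tm_sd`, `rank` (1 = highest Tm).
#' @export
analyze_run <- function(run, layout, reference = NULL, well_scale = NULL,
                        noise_mult = 5) {
  stopifnot(inherits(run, "raw_run"), inherits(layout, "plate_layout"))
  run_wells <- unique(run$data$well)
  missing <- setdiff(run_wells, layout$wells)
  if (length(missing) > 0) {
    stop("wells in run missing from layout: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  curves <- run_well_curves(run)

  groups <- layout$groups
  blanks <- Filter(function(g) g$blank, groups)
  samples <- Filter(function(g) !g$blank, groups)
  if (length(samples) == 0) {
    rep0 <- data.frame(condition = character(0), n_replicates = integer(0),
                       fit_type = character(0), tm1 = numeric(0),
                       tm1_sd = numeric(0), tm2 = numeric(0),
                       tm2_sd = numeric(0), fallback_used = logical(0),
                       no_melt = logical(0), delta_tm = numeric(0),
                       delta_tm_sd = numeric(0), rank = integer(0))
    class(rep0) <- c("screen_report", "data.frame")
    return(rep0)
  }

  blank_means <- lapply(blanks, function(g) {
    average_replicates(curves[intersect(g$wells, names(curves))])
  })
  names(blank_means) <- vapply(blanks, `[[`, character(1), "condition")

  find_blank <- function(g) {
    if (!is.null(g$blank_condition)) {
      if (!g$blank_condition %in% names(blank_means)) {
        stop("blank condition not on plate: ", g$blank_condition,
             call. = FALSE)
      }
      return(blank_means[[g$blank_condition]])
    }
    if (length(blank_means) == 1) return(blank_means[[1]])
    NULL
  }

  rows <- lapply(samples, function(g) {
    wells <- intersect(g$wells, names(curves))
    reps <- curves[wells]
    bl <- find_blank(g)
    if (!is.null(bl)) reps <- lapply(reps, subtract_blank, blank = bl)
    avg <- average_replicates(reps)
    avg$condition <- g$condition
    trunc <- truncate_post_denaturation(avg)
    res <- fit_one_curve(trunc, noise_mult = noise_mult)

    # replicate-wise Tm scatter when enough replicates fit
    if (!res$no_melt && length(reps) >= 3) {
      rep_tms <- vapply(reps, function(cv) {
        tr <- tryCatch(truncate_post_denaturation(cv),
                       error = function(e) NULL)
        if (is.null(tr)) return(NA_real_)
        r <- fit_one_curve(tr, noise_mult = noise_mult)
        if (r$no_melt) NA_real_ else r$tm1
      }, numeric(1))
      if (sum(is.finite(rep_tms)) >= 3) {
        res$tm1_sd <- stats::sd(rep_tms[is.finite(rep_tms)])
      }
    }
    data.frame(condition = g$condition, n_replicates = length(reps),
               fit_type = res$type, tm1 = res$tm1, tm1_sd = res$tm1_sd,
               tm2 = res$tm2, tm2_sd = res$tm2_sd,
               fallback_used = res$fallback, no_melt = res$no_melt)
  })
  rep <- do.call(rbind, rows)

  if (!is.null(well_scale)) {
    for (col in c("tm1", "tm2")) {
      rep[[col]] <- ifelse(is.na(rep[[col]]), NA_real_,
                           apply_well_calibration(rep[[col]], well_scale))
    }
    for (col in c("tm1_sd", "tm2_sd")) {
      rep[[col]] <- rep[[col]] * well_scale$slope
    }
  }

  ref_cond <- if (is.null(reference)) rep$condition[1] else reference
  ref_row <- rep[rep$condition == ref_cond, ]
  if (nrow(ref_row) == 1 && !ref_row$no_melt) {
    rep$delta_tm <- rep$tm1 - ref_row$tm1
    rep$delta_tm_sd <- sqrt(ifelse(is.finite(rep$tm1_sd), rep$tm1_sd^2, 0) +
                              if (is.finite(ref_row$tm1_sd))
                                ref_row$tm1_sd^2 else 0)
    rep$delta_tm[rep$no_melt] <- NA_real_
    rep$delta_tm_sd[rep$no_melt] <- NA_real_
  } else {
    rep$delta_tm <- NA_real_
    rep$delta_tm_sd <- NA_real_
  }

  rep$rank <- NA_integer_
  ok <- !rep$no_melt & is.finite(rep$tm1)
  rep$rank[ok] <- rank(-rep$tm1[ok], ties.method = "first")
  rownames(rep) <- NULL
  class(rep) <- c("screen_report", "data.frame")
  rep
}
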