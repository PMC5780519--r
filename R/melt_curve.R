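# Melt-curve container and preprocessing: blank subtraction, replicate
# averaging, truncation of the post-denaturation tail.

#' Construct a melt curve
#'
#' A fluorescence-vs-temperature series for one condition. Temperatures are
#' on the pad (setpoint) scale unless converted with
#' [apply_well_calibration()].
#'
#' @param temps Strictly increasing temperature grid, degC.
#' @param signal Fluorescence, AU; same length as `temps`.
#' @param sd Optional per-point replicate sd, AU (`NULL` if unavailable).
#' @param n_replicates Number of replicates averaged into the curve.
#' @param condition Condition label.
#'
#' @return An object of class `melt_curve`.
#' @export
melt_curve <- function(temps, signal, sd = NULL, n_replicates = 1,
                       condition = "") {
  stopifnot(is.numeric(temps), is.numeric(signal),
            length(temps) == length(signal), all(diff(temps) > 0))
  if (!is.null(sd)) stopifnot(length(sd) == length(temps), all(sd >= 0))
  structure(list(temps = temps, signal = signal, sd = sd,
                 n_replicates = as.integer(n_replicates),
                 condition = condition),
            class = "melt_curve")
}

#' @export
print.melt_curve <- function(x, ...) {
  cat(sprintf("Melt curve '%s': %d points, %.1f-%.1f degC, %d replicate(s)\n",
              x$condition, length(x$temps), min(x$temps), max(x$temps),
              x$n_replicates))
  invisible(x)
}

check_same_grid <- function(a, b) {
  if (length(a$temps) != length(b$temps) ||
      any(abs(a$temps - b$temps) > 1e-9)) {
    stop("temperature grids do not match", call. = FALSE)
  }
}

#' Subtract a blank curve
#'
#' Pointwise signal difference on an identical temperature grid; per-point
#' sds, when both are present, are combined in quadrature.
#'
#' @param curve,blank [melt_curve()] objects on the same grid.
#' @return A `melt_curve` with the blank removed.
#' @export
subtract_blank <- function(curve, blank) {
  stopifnot(inherits(curve, "melt_curve"), inherits(blank, "melt_curve"))
  check_same_grid(curve, blank)
  sd <- if (!is.null(curve$sd) && !is.null(blank$sd)) {
    sqrt(curve$sd^2 + blank$sd^2)
  } else curve$sd
  melt_curve(curve$temps, curve$signal - blank$signal, sd = sd,
             n_replicates = curve$n_replicates, condition = curve$condition)
}

#' Average replicate curves
#'
#' Pointwise mean of replicate curves recorded under one condition, with the
#' pointwise sample sd attached when at least two replicates are available
#' (`sd = NULL` flags it unavailable for a single curve).
#'
#' @param curves Non-empty list of [melt_curve()]s sharing one grid.
#' @return A `melt_curve` with `n_replicates = length(curves)`.
#' @export
average_replicates <- function(curves) {
  if (!is.list(curves) || length(curves) == 0) {
    stop("`curves` must be a non-empty list", call. = FALSE)
  }
  stopifnot(all(vapply(curves, inherits, logical(1), "melt_curve")))
  for (c2 in curves[-1]) check_same_grid(curves[[1]], c2)
  mat <- vapply(curves, `[[`, numeric(length(curves[[1]]$temps)), "signal")
  mat <- matrix(mat, ncol = length(curves))
  m <- rowMeans(mat)
  sd <- if (ncol(mat) >= 2) apply(mat, 1, stats::sd) else NULL
  melt_curve(curves[[1]]$temps, m, sd = sd, n_replicates = length(curves),
             condition = curves[[1]]$condition)
}

#' Centered moving-average smoother
#'
#' Window must be odd; edges use shrinking windows so output length equals
#' input length.
#'
#' @param x Numeric vector.
#' @param window Odd window size in points.
#' @return Smoothed vector, same length.
#' @export
smooth_signal <- function(x, window = 5) {
  stopifnot(window >= 1, window %% 2 == 1)
  n <- length(x)
  if (window == 1 || n < 2) return(x)
  h <- (window - 1) / 2
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - h); hi <- min(n, i + h)
    mean(x[lo:hi])
  }, numeric(1))
}

#' Truncate the post-denaturation tail
#'
#' Fluorescence declines after full denaturation; those trailing points
#' degrade sigmoid fits and are dropped. The curve is retained up to and
#' including the argmax of the lightly smoothed signal (ties broken toward
#' the higher temperature, keeping more data); if the argmax is the last
#' point the curve is returned unchanged.
#'
#' @param curve A [melt_curve()] with at least 5 points.
#' @param window Smoothing window (odd), points.
#' @return The truncated `melt_curve`.
#' @export
truncate_post_denaturation <- function(curve, window = 5) {
  stopifnot(inherits(curve, "melt_curve"))
  n <- length(curve$temps)
  if (n < 5) stop("need at least 5 points", call. = FALSE)
  sm <- smooth_signal(curve$signal, window)
  # last index achieving the (near-)max: ties toward higher temperature
  peak <- max(which(sm >= max(sm) - 1e-12))
  if (peak >= n) return(curve)
  keep <- seq_len(peak)
  melt_curve(curve$temps[keep], curve$signal[keep],
             sd = if (is.null(curve$sd)) NULL else curve$sd[keep],
             n_replicates = curve$n_replicates, condition = curve$condition)
}
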