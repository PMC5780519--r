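# Boltzmann / double-Boltzmann melting-curve fits, transition counting and
# the second-derivative fallback.
#
# Parameterization (Origin-style): a1 = pre-transition (low-T) plateau,
# a2 = post-transition plateau,
#   F(T) = a2 + (a1 - a2) / (1 + exp((T - tm) / dt))
# so F(tm) = (a1 + a2) / 2 and dt > 0 gives a rising transition when
# a2 > a1.

boltzmann_f <- function(t, a1, a2, tm, dt) {
  a2 + (a1 - a2) / (1 + exp((t - tm) / dt))
}

double_boltzmann_f <- function(t, a1, a2, frac, tm1, dt1, tm2, dt2) {
  a2 + (a1 - a2) * (frac / (1 + exp((t - tm1) / dt1)) +
                      (1 - frac) / (1 + exp((t - tm2) / dt2)))
}

# Bounded Levenberg-Marquardt least squares on a residual function.
# Returns parameters, standard errors (from the Jacobian at the optimum;
# zero for an exact fit), the residual sum of squares and an honest
# convergence flag.
lm_least_squares <- function(resid_fn, start, lower, upper, maxiter = 300) {
  res <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid_fn,
                       lower = lower, upper = upper,
                       control = minpack.lm::nls.lm.control(
                         maxiter = maxiter, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) NULL)
  # info 1-4: converged; 6-8: requested tolerance below machine limit,
  # i.e. the estimate cannot be improved further - also a valid optimum
  if (is.null(res) || !(res$info %in% c(1:4, 6:8))) {
    return(list(converged = FALSE, par = start * NA_real_,
                se = start * NA_real_, rss = NA_real_))
  }
  rss <- res$deviance
  se <- tryCatch({
    cf <- summary(res)$coefficients
    stats::setNames(cf[, "Std. Error"], rownames(cf))
  }, error = function(e) stats::setNames(rep(NA_real_, length(start)),
                                         names(start)))
  list(converged = TRUE, par = res$par, se = se, rss = rss)
}

# Per-point noise scale of a curve: the mean replicate scatter when
# replicate sds are attached (a transition must clearly exceed the
# well-to-well reproducibility), otherwise a robust estimate from second
# differences (curvature concentrates near the transition, so the median
# over the whole curve reflects noise, not shape).
curve_noise_scale <- function(curve) {
  if (!is.null(curve$sd) && any(curve$sd > 0)) {
    return(mean(curve$sd))
  }
  x <- curve$signal
  n <- length(x)
  if (n < 3) return(0)
  d2 <- x[3:n] - 2 * x[2:(n - 1)] + x[1:(n - 2)]
  1.4826 * stats::median(abs(d2)) / sqrt(6)
}

# Smoothed signal range vs noise: TRUE when the curve carries no transition
# distinguishable from noise.
is_no_melt <- function(curve, window = 5, noise_mult = 5) {
  sm <- smooth_signal(curve$signal, window)
  amp <- max(sm) - min(sm)
  amp < noise_mult * curve_noise_scale(curve)
}

#' Count unfolding transitions in a melt curve
#'
#' Counts well-separated peaks in the smoothed first difference of the
#' signal. A peak qualifies when its height exceeds `prominence_frac` of
#' the maximal slope and it is at least `min_separation` grid steps from a
#' larger peak. A curve whose amplitude does not exceed the noise scale
#' (see [fit_boltzmann()]) counts zero transitions, i.e. no melt.
#'
#' @param curve A [melt_curve()] with at least 7 points.
#' @param prominence_frac Fraction of the maximal slope a peak must reach.
#' @param min_separation Minimal peak separation, grid steps.
#' @param window Smoothing window (odd), points.
#' @param noise_mult Amplitude-to-noise multiple below which the curve is
#'   declared melt-free.
#'
#' @return Integer 0, 1 or 2 (two or more distinct transitions report 2).
#' @export
count_inflections <- function(curve, prominence_frac = 0.25,
                              min_separation = 3, window = 5,
                              noise_mult = 5) {
  stopifnot(inherits(curve, "melt_curve"))
  if (length(curve$temps) < 7) stop("need at least 7 points", call. = FALSE)
  if (is_no_melt(curve, window, noise_mult)) return(0L)
  sm <- smooth_signal(curve$signal, window)
  d <- diff(sm) / diff(curve$temps)
  if (max(d) <= 0) return(0L)
  pk <- pracma::findpeaks(d, minpeakheight = prominence_frac * max(d),
                          minpeakdistance = min_separation)
  # findpeaks misses a maximum on the boundary; the global max always counts
  n <- if (is.null(pk)) 1L else nrow(pk)
  min(as.integer(n), 2L)
}

new_boltzmann_fit <- function(a1 = NA_real_, a2 = NA_real_, tm = NA_real_,
                              dt = NA_real_, tm_sd = NA_real_,
                              rss = NA_real_, converged = FALSE,
                              no_melt = FALSE) {
  structure(list(a1 = a1, a2 = a2, tm = tm, dt = dt, tm_sd = tm_sd,
                 rss = rss, converged = converged, no_melt = no_melt),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  if (x$no_melt || !x$converged) {
    cat("Boltzmann fit: no melt / not converged\n")
  } else {
    cat(sprintf("Boltzmann fit: Tm = %.2f +/- %.2f degC (dt = %.2f, plateaus %.1f -> %.1f)\n",
                x$tm, x$tm_sd, x$dt, x$a1, x$a2))
  }
  invisible(x)
}

#' Fit a Boltzmann sigmoid to a melt curve
#'
#' Least-squares fit of `F(T) = a2 + (a1 - a2)/(1 + exp((T - tm)/dt))` by
#' Levenberg-Marquardt. Starting values come from the data: `a1` is the
#' first-decile mean, `a2` the last-decile mean, `tm` the temperature of
#' steepest ascent of the smoothed signal, `dt` one grid step. A curve
#' whose smoothed amplitude is below `noise_mult` times the noise scale
#' (replicate sd of the mean when available, otherwise a robust
#' second-difference estimate) is reported as `no_melt` without fitting;
#' non-convergence is reported via `converged = FALSE`, never as an error.
#'
#' @param curve A truncated [melt_curve()] with at least 5 points.
#' @param noise_mult Amplitude-to-noise multiple for the no-melt rule.
#'
#' @return A `boltzmann_fit`: `a1`, `a2` (plateaus, AU), `tm` (degC),
#'   `dt` (slope factor, degC), `tm_sd` (fit standard error, degC), `rss`,
#'   `converged`, `no_melt`.
#' @export
fit_boltzmann <- function(curve, noise_mult = 5) {
  stopifnot(inherits(curve, "melt_curve"))
  n <- length(curve$temps)
  if (n < 5) stop("need at least 5 points", call. = FALSE)
  if (is_no_melt(curve, noise_mult = noise_mult)) {
    return(new_boltzmann_fit(no_melt = TRUE))
  }
  tt <- curve$temps; yy <- curve$signal
  k <- max(1, floor(n / 10))
  a1_0 <- mean(yy[seq_len(k)])
  a2_0 <- mean(yy[seq.int(n - k + 1, n)])
  sm <- smooth_signal(yy, 5)
  d <- diff(sm) / diff(tt)
  tm_0 <- tt[which.max(d)]
  dt_0 <- stats::median(diff(tt))

  fit <- lm_least_squares(
    function(p) yy - boltzmann_f(tt, p["a1"], p["a2"], p["tm"], p["dt"]),
    start = c(a1 = a1_0, a2 = a2_0, tm = tm_0, dt = dt_0),
    lower = c(-Inf, -Inf, min(tt), 1e-3),
    upper = c(Inf, Inf, max(tt), diff(range(tt))))
  if (!fit$converged) return(new_boltzmann_fit(converged = FALSE))

  p <- fit$par
  amp_ok <- abs(p[["a2"]] - p[["a1"]]) >=
    noise_mult * curve_noise_scale(curve)
  new_boltzmann_fit(a1 = p[["a1"]], a2 = p[["a2"]], tm = p[["tm"]],
                    dt = p[["dt"]], tm_sd = fit$se[["tm"]],
                    rss = fit$rss, converged = TRUE, no_melt = !amp_ok)
}

new_double_fit <- function(a1 = NA_real_, a2 = NA_real_, frac = NA_real_,
                           tm1 = NA_real_, tm2 = NA_real_, dt1 = NA_real_,
                           dt2 = NA_real_, tm1_sd = NA_real_,
                           tm2_sd = NA_real_, rss = NA_real_,
                           converged = FALSE, no_melt = FALSE) {
  structure(list(a1 = a1, a2 = a2, frac = frac, tm1 = tm1, tm2 = tm2,
                 dt1 = dt1, dt2 = dt2, tm1_sd = tm1_sd, tm2_sd = tm2_sd,
                 rss = rss, converged = converged, no_melt = no_melt),
            class = "double_boltzmann_fit")
}

#' @export
print.double_boltzmann_fit <- function(x, ...) {
  if (x$no_melt || !x$converged) {
    cat("Double-Boltzmann fit: no melt / not converged\n")
  } else {
    cat(sprintf("Double-Boltzmann fit: Tm1 = %.2f +/- %.2f, Tm2 = %.2f +/- %.2f degC (frac = %.2f)\n",
                x$tm1, x$tm1_sd, x$tm2, x$tm2_sd, x$frac))
  }
  invisible(x)
}

#' Fit a double-Boltzmann sigmoid (two transitions)
#'
#' Least-squares fit of
#' `F(T) = a2 + (a1 - a2) * (frac/(1 + exp((T - tm1)/dt1)) +
#' (1 - frac)/(1 + exp((T - tm2)/dt2)))`, used when a melt curve shows two
#' inflection points. Midpoint starting values come from the two largest
#' slope peaks. The output always satisfies `tm1 < tm2` (components are
#' reordered after the fit if the optimizer swapped them).
#'
#' @param curve A truncated [melt_curve()] with at least 7 points.
#' @param noise_mult Amplitude-to-noise multiple for the no-melt rule.
#'
#' @return A `double_boltzmann_fit` with plateaus `a1`, `a2`, amplitude
#'   fraction `frac` of the first transition, midpoints `tm1 < tm2`, slope
#'   factors `dt1`, `dt2`, fit standard errors, `rss`, `converged`,
#'   `no_melt`. On non-convergence `converged = FALSE`; callers fall back
#'   to [tm_by_second_derivative()].
#' @export
fit_double_boltzmann <- function(curve, noise_mult = 5) {
  stopifnot(inherits(curve, "melt_curve"))
  n <- length(curve$temps)
  if (n < 7) stop("need at least 7 points", call. = FALSE)
  if (is_no_melt(curve, noise_mult = noise_mult)) {
    return(new_double_fit(no_melt = TRUE))
  }
  tt <- curve$temps; yy <- curve$signal
  k <- max(1, floor(n / 10))
  a1_0 <- mean(yy[seq_len(k)])
  a2_0 <- mean(yy[seq.int(n - k + 1, n)])
  sm <- smooth_signal(yy, 5)
  d <- diff(sm) / diff(tt)
  pk <- pracma::findpeaks(d, minpeakheight = 0.1 * max(d),
                          minpeakdistance = 3)
  if (!is.null(pk) && nrow(pk) >= 2) {
    ord <- order(pk[, 1], decreasing = TRUE)[1:2]
    tms <- sort(tt[pk[ord, 2]])
  } else {
    i_max <- which.max(d)
    tms <- sort(c(tt[i_max], tt[i_max] + diff(range(tt)) / 3))
  }
  dt_0 <- stats::median(diff(tt))

  rng <- diff(range(tt))
  fit <- lm_least_squares(
    function(p) yy - double_boltzmann_f(tt, p["a1"], p["a2"], p["frac"],
                                        p["tm1"], p["dt1"], p["tm2"],
                                        p["dt2"]),
    start = c(a1 = a1_0, a2 = a2_0, frac = 0.5,
              tm1 = tms[1], dt1 = dt_0, tm2 = tms[2], dt2 = dt_0),
    lower = c(-Inf, -Inf, 1e-3, min(tt), 1e-3, min(tt), 1e-3),
    upper = c(Inf, Inf, 1 - 1e-3, max(tt), rng, max(tt), rng))
  if (!fit$converged) return(new_double_fit(converged = FALSE))

  p <- fit$par
  se <- fit$se
  out <- list(frac = p[["frac"]], tm1 = p[["tm1"]], dt1 = p[["dt1"]],
              tm1_sd = unname(se[["tm1"]]),
              tm2 = p[["tm2"]], dt2 = p[["dt2"]],
              tm2_sd = unname(se[["tm2"]]))
  if (out$tm1 > out$tm2) {  # ordering contract: tm1 < tm2
    out <- list(frac = 1 - out$frac, tm1 = out$tm2, dt1 = out$dt2,
                tm1_sd = out$tm2_sd, tm2 = out$tm1, dt2 = out$dt1,
                tm2_sd = out$tm1_sd)
  }
  new_double_fit(a1 = p[["a1"]], a2 = p[["a2"]], frac = out$frac,
                 tm1 = out$tm1, tm2 = out$tm2, dt1 = out$dt1,
                 dt2 = out$dt2, tm1_sd = out$tm1_sd, tm2_sd = out$tm2_sd,
                 rss = fit$rss, converged = TRUE)
}

#' Melting point from the second-derivative zero crossing
#'
#' Fallback for curves where the sigmoid fits do not converge: the smoothed
#' numerical second difference is computed and the positive-to-negative
#' zero crossing nearest the point of steepest ascent is located by linear
#' interpolation between the bracketing grid points.
#'
#' @param curve A [melt_curve()] with at least 7 points.
#' @param window Smoothing window (odd), points.
#'
#' @return The melting temperature in degC, or `NA_real_` when the second
#'   derivative has no sign change (no melt).
#' @export
tm_by_second_derivative <- function(curve, window = 5) {
  stopifnot(inherits(curve, "melt_curve"))
  n <- length(curve$temps)
  if (n < 7) stop("need at least 7 points", call. = FALSE)
  tt <- curve$temps
  sm <- smooth_signal(curve$signal, window)
  h <- stats::median(diff(tt))
  # restrict to points where the smoother used a full window, so the
  # shrinking-window edges cannot inject spurious curvature
  half <- (window - 1) / 2
  idx <- seq.int(half + 2, n - half - 1)   # interior second differences
  if (length(idx) < 3) return(NA_real_)
  d2 <- (sm[idx + 1] - 2 * sm[idx] + sm[idx - 1]) / h^2
  d2 <- smooth_signal(d2, 3)
  t_mid <- tt[idx]

  d1 <- diff(sm) / diff(tt)
  t_steep <- tt[which.max(d1)]

  cross <- which(d2[-length(d2)] > 0 & d2[-1] <= 0)
  if (length(cross) == 0) return(NA_real_)
  t_cross <- vapply(cross, function(i) {
    t_mid[i] + d2[i] / (d2[i] - d2[i + 1]) * (t_mid[i + 1] - t_mid[i])
  }, numeric(1))
  t_cross[which.min(abs(t_cross - t_steep))]
}
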