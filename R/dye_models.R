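# Two-state (and stepwise multi-transition) unfolding models and
# dye-specific fluorescence response.

#' Protein unfolding model
#'
#' A weighted sum of two-state sigmoidal transitions. Each transition is a
#' Boltzmann sigmoid in temperature with midpoint `tm_true` (degC) and
#' slope factor `slope_factor` (degC); `weight`s must sum to 1 and midpoints
#' must be strictly increasing. A single transition models ordinary
#' two-state unfolding; several closely spaced equal-weight transitions
#' reproduce the shallow curves of thiol-reactive (CPM) detection, where
#' buried cysteines become exposed stepwise; two well-separated transitions
#' model sequential denaturation of subunits.
#'
#' @param tm_true Numeric vector of true midpoints, degC, strictly
#'   increasing.
#' @param slope_factor Slope factor(s), degC, positive; recycled to the
#'   number of transitions.
#' @param weight Transition weights in (0, 1], summing to 1; defaults to
#'   equal weights.
#'
#' @return An object of class `unfolding_model`.
#' @export
unfolding_model <- function(tm_true = 50, slope_factor = 2, weight = NULL) {
  k <- length(tm_true)
  stopifnot(k >= 1, all(diff(tm_true) > 0), all(slope_factor > 0))
  slope_factor <- rep_len(slope_factor, k)
  if (is.null(weight)) weight <- rep(1 / k, k)
  stopifnot(length(weight) == k, all(weight > 0), all(weight <= 1),
            abs(sum(weight) - 1) < 1e-8)
  structure(list(tm_true = tm_true, slope_factor = slope_factor,
                 weight = weight),
            class = "unfolding_model")
}

#' CPM-style stepwise unfolding model
#'
#' Convenience constructor: `k` equal-weight transitions spread
#' symmetrically around a central midpoint, emulating the stepwise reaction
#' of cysteine residues that makes CPM melting curves less steep than
#' SYPRO curves.
#'
#' @param tm_center Central midpoint, degC.
#' @param k Number of sub-transitions.
#' @param spread Half-range of the midpoints around `tm_center`, degC.
#' @param slope_factor Per-transition slope factor, degC.
#' @return An [unfolding_model()].
#' @export
stepwise_unfolding_model <- function(tm_center = 50, k = 3, spread = 4,
                                     slope_factor = 2) {
  tms <- if (k == 1) tm_center else
    seq(tm_center - spread, tm_center + spread, length.out = k)
  unfolding_model(tm_true = tms, slope_factor = slope_factor)
}

#' Unfolded fraction at a well temperature
#'
#' `sum_i weight_i / (1 + exp((tm_i - T) / slope_i))`; monotonically
#' non-decreasing in temperature, in `[0, 1]`. Vectorised over `t_well`.
#'
#' @param t_well Well temperature(s), degC.
#' @param model An [unfolding_model()].
#' @return Unfolded fraction(s) in `[0, 1]`.
#' @export
unfolded_fraction <- function(t_well, model = unfolding_model()) {
  stopifnot(inherits(model, "unfolding_model"), is.numeric(t_well))
  out <- numeric(length(t_well))
  for (i in seq_along(model$tm_true)) {
    out <- out + model$weight[i] /
      (1 + exp((model$tm_true[i] - t_well) / model$slope_factor[i]))
  }
  out
}

#' Dye response model
#'
#' Maps unfolded fraction and temperature to a fluorescence signal for one
#' of the supported probes: `"SYPRO"` (hydrophobic-core binding),
#' `"CPM"` (thiol-reactive) or `"FAD"` (intrinsic flavin, ThermoFAD).
#' Beyond the native/unfolded levels the model carries the artefacts seen in
#' real runs: a linear fluorescence decay past full denaturation, an
#' additive temperature-coupled background for interfering additives (the
#' DDAO failure mode, visible in blanks), and a global amplitude loss for
#' partially aggregated samples (air-exposed oxygen-sensitive proteins lose
#' about 30% of maximal fluorescence after the aggregate is spun down).
#'
#' @param kind One of `"SYPRO"`, `"CPM"`, `"FAD"`.
#' @param f_native Fluorescence of the fully folded state, AU.
#' @param f_unfolded Fluorescence of the fully unfolded state, AU; must
#'   exceed `f_native`.
#' @param background Temperature-independent background, AU.
#' @param decay_rate Linear signal loss per degC past full denaturation,
#'   AU/degC; non-negative.
#' @param interference_level Amplitude of the additive interference profile,
#'   AU (0 = none).
#' @param aggregated_fraction Fraction of protein lost to aggregation, in
#'   `[0, 1)`.
#' @param noise_prop,noise_floor Measurement-noise model: per-reading
#'   Gaussian sd `= noise_floor + noise_prop * |signal|`.
#'
#' @return An object of class `dye_model`.
#' @export
dye_model <- function(kind = c("SYPRO", "CPM", "FAD"),
                      f_native = 100, f_unfolded = 1000, background = 50,
                      decay_rate = 0, interference_level = 0,
                      aggregated_fraction = 0,
                      noise_prop = 0.02, noise_floor = 1) {
  kind <- match.arg(kind)
  stopifnot(f_native >= 0, f_unfolded > f_native, decay_rate >= 0,
            interference_level >= 0,
            aggregated_fraction >= 0, aggregated_fraction < 1,
            noise_prop >= 0, noise_floor >= 0)
  structure(list(kind = kind, f_native = f_native, f_unfolded = f_unfolded,
                 background = background, decay_rate = decay_rate,
                 interference_level = interference_level,
                 aggregated_fraction = aggregated_fraction,
                 noise_prop = noise_prop, noise_floor = noise_floor),
            class = "dye_model")
}

# Fixed monotone interference profile g(T) in [0, 1]: a broad sigmoid that
# rises with temperature, as detergent-probe interactions strengthen on
# heating. Shared by samples and blanks of a condition.
interference_profile <- function(t_well) {
  1 / (1 + exp((60 - t_well) / 10))
}

#' Fluorescence signal of a well
#'
#' `F = background + interference_level * g(T) +
#'  (1 - aggregated_fraction) * (f_native + fraction * (f_unfolded - f_native))
#'  - decay_rate * max(0, T - t_full_denat)`, floored at 0. `g(T)` is a
#' fixed monotone profile shared by samples and blanks. For blanks pass
#' `fraction = 0` with a dye whose `f_native = 0` (no protein component).
#'
#' @param fraction Unfolded fraction(s) in `[0, 1]`.
#' @param t_well Well temperature(s), degC.
#' @param dye A [dye_model()].
#' @param t_full_denat Temperature of full denaturation, degC; decay applies
#'   past it. `NULL` disables decay.
#'
#' @return Fluorescence in AU (non-negative).
#' @export
fluorescence_signal <- function(fraction, t_well, dye = dye_model(),
                                t_full_denat = NULL) {
  stopifnot(inherits(dye, "dye_model"),
            all(fraction >= -1e-12), all(fraction <= 1 + 1e-12))
  f <- dye$background + dye$interference_level * interference_profile(t_well) +
    (1 - dye$aggregated_fraction) *
      (dye$f_native + fraction * (dye$f_unfolded - dye$f_native))
  if (!is.null(t_full_denat) && dye$decay_rate > 0) {
    f <- f - dye$decay_rate * pmax(0, t_well - t_full_denat)
  }
  pmax(f, 0)
}

# Default full-denaturation temperature for an unfolding model: the signal
# is essentially saturated at max(tm) + 3 * slope_factor.
full_denaturation_temp <- function(model) {
  k <- length(model$tm_true)
  model$tm_true[k] + 3 * model$slope_factor[k]
}
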