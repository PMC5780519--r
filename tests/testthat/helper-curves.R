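# Shared fixture builders: synthetic melt curves on the default schedule grid.

default_grid <- function() build_schedule()$setpoints

# Single- or multi-transition sigmoid curve with optional Gaussian noise
# (sd expressed as a fraction of the amplitude) and optional linear decay
# past full denaturation.
make_sigmoid_curve <- function(tm = 50, dt = 2, a1 = 100, a2 = 1000,
                               noise_frac = 0, seed = NULL,
                               temps = default_grid(), decay_rate = 0,
                               t_full_denat = NULL, condition = "synthetic") {
  if (!is.null(seed)) set.seed(seed)
  um <- unfolding_model(tm_true = tm, slope_factor = dt)
  y <- a1 + (a2 - a1) * unfolded_fraction(temps, um)
  if (decay_rate > 0) {
    if (is.null(t_full_denat)) t_full_denat <- max(tm) + 3 * max(dt)
    y <- y - decay_rate * pmax(0, temps - t_full_denat)
  }
  if (noise_frac > 0) {
    y <- y + stats::rnorm(length(temps), 0, noise_frac * abs(a2 - a1))
  }
  melt_curve(temps, y, condition = condition)
}

# A small two-condition + blank triplicate layout used by pipeline tests.
make_test_layout <- function(tms = c(48, 53), decay_rate = 20) {
  plate_layout(
    plate_group(c("A1", "A2", "A3"), "cond1",
                dye_model("SYPRO", decay_rate = decay_rate),
                unfolding_model(tms[1], 2)),
    plate_group(c("B1", "B2", "B3"), "cond2",
                dye_model("SYPRO", decay_rate = decay_rate),
                unfolding_model(tms[2], 2)),
    plate_group(c("H10", "H11", "H12"), "blank", dye_model("SYPRO"),
                blank = TRUE))
}
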