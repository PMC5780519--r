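---
title: "Simulating a PID-heated DSF instrument and evaluating melting curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating a PID-heated DSF instrument and evaluating melting curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsfsim)
```

`dsfsim` models a differential scanning fluorimetry (DSF) setup in which a
silicone heat pad under a 96-well plate is driven by a microcontroller PID
loop, the plate is stepped through a temperature ladder, and a fluorescence
reader records one per-well table per temperature step. This vignette
documents the models, the tunable parameters and their defaults, the
numerical choices, and what the synthetic data can and cannot tell you
about real experiments.

## The thermal model

### Thermistor

The pad temperature sensor is an NTC glass-bead thermistor converted by the
β-equation, `1/T = 1/T0 + ln(R/R0)/β` with temperatures in kelvin
(`ntc_temperature()`, inverse `ntc_resistance()`). Defaults are a common
bead (β = 3950 K, R0 = 10 kΩ at 25 °C). All user-facing temperatures are
°C; kelvin appears only inside the β-equation.

### Plant and controller

The pad is a first-order lumped thermal mass,

$$\frac{dT}{dt} = \frac{P_{max}\,u - k_{loss}(T - T_{amb})}{C},$$

integrated by explicit Euler at the controller tick (1 s). This is the
simplest plant that reproduces both the settling transient and the
zero-steady-state-error behaviour of the real loop; no attempt is made to
model spatial gradients across the pad. The solid-state relay is
represented by its time-proportioned mean power, a continuous duty
$u \in [0,1]$ per tick, which has the same mean power as discrete on/off
switching without its waveform detail.

The PID law acts on the averaged sensor reading (8 noisy readings per
decision by default; averaging n readings reduces the noise sd by
$1/\sqrt{n}$). The integral contribution is clamped (anti-windup, ±0.9
duty by default) so that the long saturated heat-up phases between
setpoints do not overshoot. Default gains (kp = 1 duty/°C, ki = 0.02
duty/°C·s, kd = 0) are package constants chosen once for the default
plant: the closed loop is overdamped with a slow pole of roughly 45 s, so
a 3 °C step settles to < 0.05 °C well inside a 5-minute dwell. Gains are
configuration, not measured hardware values, and other plants will need
retuning.

### Schedule

`build_schedule()` produces the heat/incubate/measure ladder. The default
start of 25 °C is a deliberate choice for "room temperature": together
with 3 °C steps to a 95 °C ceiling and 5 min dwell it yields 24 setpoints
and a 2 h total run, matching how such routines are operated in practice.

### Two temperature scales

Two linear transfer lines connect the scales:

* pad surface vs set temperature: `y = 1.008 x + 0.366` — essentially the
  identity, with a steady-state reproducibility of about 0.2 °C;
* sample well vs set temperature: `y = 0.681 x + 7.034`, with a
  well-to-well sd of 0.8 °C — wells run substantially cooler than the pad
  (a 95 °C setpoint gives ≈ 71.7 °C in the well).

These constants are the package defaults of `heat_pad_plant()` and
`well_thermal_model()`. All melting temperatures are reported on the pad
scale by default, the instrument's reference scale; `analyze_run(...,
well_scale = calibration_line())` converts to actual well temperatures.
The ambiguity in what "average sd of 0.2 °C" aggregates over is resolved
here as the per-setpoint steady-state sd across seeded replicate runs,
averaged over setpoints.

## The fluorescence model

No quantitative photophysical model is attempted. Unfolding is a weighted
sum of two-state sigmoids (`unfolding_model()`): fraction unfolded
$\theta(T) = \sum_i w_i / (1 + e^{(T_{m,i}-T)/dT_i})$. This minimal family
covers every curve shape the pipeline must handle:

* a single sigmoid (typical SYPRO curve);
* several closely spaced equal-weight transitions
  (`stepwise_unfolding_model()`) giving the shallower curves of
  thiol-reactive CPM detection, where buried cysteines react stepwise;
* two well-separated transitions for multi-subunit proteins.

The dye response (`fluorescence_signal()`) is
`background + interference·g(T) + (1 − aggregated)·(F_native + θ·(F_unfolded − F_native)) − decay·max(0, T − T_full)`,
floored at zero, with:

* **post-denaturation decay**: a linear signal loss past
  `T_full = max(Tm) + 3·dT`, where the transition is saturated — this is
  what the truncation step removes before fitting;
* **interference**: an additive, temperature-coupled background `g(T)` (a
  broad fixed sigmoid rising with temperature) shared by samples and
  blanks; at high levels it reproduces the failure of amine-oxide
  detergents such as DDAO, where the probe signal is dominated by the
  detergent and blanks look like samples. Whether that failure is additive
  background or probe quenching is unknown; additivity is the assumption
  here;
* **aggregation loss**: air-exposed oxygen-sensitive samples lose a
  fraction of protein to aggregation (removed by centrifugation), modeled
  purely as an amplitude scale of `(1 − aggregated_fraction)` — curve
  shapes stay unchanged, which is exactly the observed signature (≈ 30%
  lower maximal fluorescence, nearly unaltered midpoints). Any genuine Tm
  shift is left to the user's generating parameters.

Measurement noise is Gaussian per reading with
`sd = noise_floor + noise_prop·|signal|` (defaults 1 AU + 2%); the
proportional part is what makes heavy interference drown small protein
amplitudes, as in real DDAO wells. Synthetic triplicate scatter resembles
real replicate error bars qualitatively; no quantitative noise claim is
made. Dye saturation (e.g. limited CPM stoichiometry), inner-filter
effects, evaporation (an oil overlay is assumed) and aggregation kinetics
are not modeled — passing recovery tests on this generator therefore
demonstrates correctness of the pipeline, not robustness to every real
artefact.

## The evaluation pipeline

`analyze_run()` composes, per condition: blank subtraction (per replicate,
against the mean curve of the matched blank group) → replicate averaging
(pointwise mean and sample sd) → truncation → transition counting →
sigmoid fit → fallback → report. Whether blanks should be subtracted
per replicate or after averaging is not settled practice; per-replicate
subtraction is used because it also propagates blank noise into the
replicate scatter.

**Truncation.** The curve is kept up to the argmax of a lightly smoothed
signal (centered moving average, window 5, shrinking at the edges), ties
broken toward higher temperature so no usable data is lost. Because decay
begins only past `T_full > Tm`, truncation can never remove points at or
below the midpoint in the synthetic family.

**Transition counting.** "One or two inflection points" is made
operational as peak counting on the smoothed first difference: a peak
counts if it reaches 25% of the maximal slope and is ≥ 3 grid steps from a
larger peak (both configurable). Zero countable transitions means no melt.

**Fitting.** Both sigmoids are fit by bounded Levenberg–Marquardt
(`minpack.lm::nls.lm`, ftol = ptol = 1e−15, tolerance-limited stops
accepted as optima so exact synthetic data converges to machine
precision). Starting values are always data-derived: plateaus from the
first/last deciles, midpoints from slope peaks, slope factors from the
grid step. The double fit enforces `tm1 < tm2` by reordering components
after the fit. Non-convergence is an honest flag, not an exception, and
triggers the second-derivative fallback: the zero crossing of the smoothed
second difference nearest the steepest ascent, located by linear
interpolation between bracketing grid points. Second differences are only
computed where the smoother used a full window, so edge effects cannot
fabricate crossings on transition-free curves.

**No-melt rule.** A fit (or count) is reported as "no melt" when the
smoothed amplitude is below 5× the curve's noise scale — the mean
replicate sd when replicates exist, otherwise a robust estimate from
second differences (1.4826·median|Δ²F|/√6, valid because curvature
concentrates near the transition while plateaus dominate the median).
Using the replicate scatter (not the sd of the mean) makes the rule
demand a transition that clearly exceeds well-to-well reproducibility,
which is what flags interference-dominated conditions.

**Uncertainties.** The reported `tm_sd` is the sd across replicate-wise
fits when ≥ 3 replicates fit successfully, else the fit standard error;
published ± values in this field are ambiguous between the two, and the
replicate scatter is the more conservative choice. ΔTm combines the two
uncertainties in quadrature. Screens are ranked descriptively by Tm; no
multiple-testing machinery is applied.

## Problem sizes and determinism

All randomness flows from single integer seeds (`set.seed` per
simulation), making every trace, run and report bit-reproducible. The
test-suite simulations are sized for tightness of the checks, not for
minimality: 200 seeded single-transition curves for the Tm-recovery
property (median |error| < 0.3 °C at 2% noise, bias < 0.1 °C), 25 two-
transition curves at 1% noise, 100-seed calibration-recovery ensembles,
10⁴-draw Monte-Carlo checks of the averaging law, and full 24-step
closed-loop traces (7200 control ticks each).

## File formats

Run workbooks are plain directories: a JSON manifest (schedule, seed, well
list, ordered sheet names) plus one CSV per temperature step named
`T_<setpoint>.csv` with one row per well — the direct analogue of a
one-sheet-per-step spreadsheet, chosen so runs are diffable and
dependency-free; a tidy long-format CSV export (`write_run_long()`)
round-trips to identical analysis results. Plate maps and calibration
lines are YAML. Temperatures in files are pad-scale °C at one decimal.

## Known limitations

* The plant is single-zone; spatial pad gradients only enter through the
  static well-to-well noise term.
* The well thermal lag is static (no per-step dynamics); during short
  dwells a real well lags further behind.
* Interference is strictly additive; quenching mechanisms would need a
  multiplicative model.
* The derivative fallback assumes an approximately uniform temperature
  grid.
* `fold_cmc()` reports one decimal, the convention for detergent dosing,
  and nothing finer.
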