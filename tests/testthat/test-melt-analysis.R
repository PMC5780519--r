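# Preprocessing, sigmoid fitting, fallback, calibration and screening.

test_that("blank subtraction is pointwise with quadrature sd", {
  tt <- default_grid()
  c1 <- melt_curve(tt, seq_along(tt) + 10, sd = rep(2, length(tt)))
  bl <- melt_curve(tt, rep(10, length(tt)), sd = rep(1.5, length(tt)))
  out <- subtract_blank(c1, bl)
  expect_equal(out$signal, seq_along(tt))
  expect_equal(out$sd, rep(sqrt(2^2 + 1.5^2), length(tt)))
  expect_equal(subtract_blank(c1, c1)$signal, rep(0, length(tt)))
  zero <- melt_curve(tt, rep(0, length(tt)))
  expect_equal(subtract_blank(c1, zero)$signal, c1$signal)
  short <- melt_curve(tt[-1], c1$signal[-1])
  expect_error(subtract_blank(c1, short), "grid")
})

test_that("replicate averaging gives pointwise mean and sample sd", {
  tt <- default_grid()
  mk <- function(v) melt_curve(tt, rep(v, length(tt)))
  out <- average_replicates(list(mk(1), mk(2), mk(3)))
  expect_equal(out$signal, rep(2, length(tt)))
  expect_equal(out$sd, rep(1, length(tt)))  # sd of {1,2,3}
  expect_equal(out$n_replicates, 3L)
  same <- average_replicates(list(mk(5), mk(5), mk(5)))
  expect_equal(same$signal, rep(5, length(tt)))
  expect_equal(same$sd, rep(0, length(tt)))
  single <- average_replicates(list(mk(4)))
  expect_equal(single$signal, rep(4, length(tt)))
  expect_null(single$sd)  # flagged unavailable for n = 1
  expect_error(average_replicates(list()), "non-empty")
})

test_that("truncation removes exactly the post-peak decay tail", {
  # increasing sigmoid: untouched
  cv <- make_sigmoid_curve(tm = 50, dt = 2)
  expect_equal(truncate_post_denaturation(cv), cv)
  # sigmoid + linear decay after saturation: cut at the known peak
  tt <- default_grid()
  cvd <- make_sigmoid_curve(tm = 50, dt = 2, decay_rate = 30,
                            t_full_denat = 60)
  peak <- which.max(smooth_signal(cvd$signal, 5))
  out <- truncate_post_denaturation(cvd)
  expect_length(out$temps, peak)
  expect_equal(out$temps, tt[seq_len(peak)])
  # no point at or below the transition is ever lost
  expect_gte(max(out$temps), 50)
  # flat curve: unchanged
  flat <- melt_curve(tt, rep(7, length(tt)))
  expect_equal(truncate_post_denaturation(flat)$signal, flat$signal)
  expect_error(truncate_post_denaturation(melt_curve(1:4, 1:4)), "5 points")
})

test_that("Boltzmann fit recovers exact parameters and the midpoint identity", {
  cv <- make_sigmoid_curve(tm = 50, dt = 2, a1 = 0, a2 = 1000)
  f <- fit_boltzmann(cv)
  expect_true(f$converged)
  expect_false(f$no_melt)
  expect_equal(c(f$a1, f$a2, f$tm, f$dt), c(0, 1000, 50, 2),
               tolerance = 1e-6)
  expect_equal(f$tm, 50, tolerance = 1e-7)
  expect_equal(f$dt, 2, tolerance = 1e-6)
  # model value at tm is (a1 + a2) / 2
  expect_equal(dsfsim:::boltzmann_f(f$tm, f$a1, f$a2, f$tm, f$dt),
               (f$a1 + f$a2) / 2, tolerance = 1e-12)
})

test_that("flat noise-only curves are reported as no-melt, not errors", {
  set.seed(9)
  tt <- default_grid()
  flat <- melt_curve(tt, rnorm(length(tt), 100, 5))
  f <- fit_boltzmann(flat)
  expect_true(f$no_melt)
  expect_equal(count_inflections(flat), 0L)
})

test_that("Boltzmann Tm recovery: median error < 0.3 degC at 2% noise", {
  errs <- vapply(1:200, function(s) {
    cv <- make_sigmoid_curve(tm = 52, dt = 2, a1 = 100, a2 = 1000,
                             noise_frac = 0.02, seed = s)
    f <- fit_boltzmann(cv)
    if (f$converged && !f$no_melt) f$tm - 52 else NA_real_
  }, numeric(1))
  expect_true(all(is.finite(errs)))
  expect_lt(median(abs(errs)), 0.3)
  expect_lt(abs(mean(errs)), 0.1)  # unbiased
})

test_that("transition counting distinguishes 0, 1 and 2 transitions", {
  expect_equal(count_inflections(make_sigmoid_curve(tm = 50)), 1L)
  two <- make_sigmoid_curve(tm = c(46, 64), dt = 2)
  expect_equal(count_inflections(two), 2L)
  tt <- default_grid()
  set.seed(4)
  expect_equal(count_inflections(melt_curve(tt, rnorm(length(tt)))), 0L)
})

test_that("double-Boltzmann recovers two separated midpoints", {
  # generating midpoints 46.1 / 63.1 degC, 1% noise
  errs <- t(vapply(1:25, function(s) {
    cv <- make_sigmoid_curve(tm = c(46.1, 63.1), dt = 2, a1 = 100,
                             a2 = 1000, noise_frac = 0.01, seed = s)
    f <- fit_double_boltzmann(cv)
    expect_true(f$converged)
    expect_lt(f$tm1, f$tm2)  # ordering contract
    c(f$tm1 - 46.1, f$tm2 - 63.1)
  }, numeric(2)))
  expect_lt(median(abs(errs[, 1])), 0.3)
  expect_lt(median(abs(errs[, 2])), 0.3)
})

test_that("degenerate double fit agrees with the single-model Tm", {
  cv <- make_sigmoid_curve(tm = 50, dt = 2, a1 = 100, a2 = 1000,
                           noise_frac = 0.005, seed = 77)
  fs <- fit_boltzmann(cv)
  fd <- fit_double_boltzmann(cv)
  expect_true(fd$converged)
  # one component carries (almost) all the amplitude and matches
  tm_major <- if (fd$frac >= 0.5) fd$tm1 else fd$tm2
  expect_equal(tm_major, fs$tm, tolerance = 0.1)
})

test_that("second-derivative fallback locates the sigmoid inflection", {
  # fine grid: zero-crossing equals the analytic midpoint within half a step
  tt <- seq(30, 70, by = 0.5)
  cv <- melt_curve(tt, 100 + 900 / (1 + exp((50 - tt) / 2)))
  expect_equal(tm_by_second_derivative(cv), 50, tolerance = 0.25)
  # strictly linear curve has no crossing: no-melt
  lin <- melt_curve(tt, tt * 3)
  expect_true(is.na(tm_by_second_derivative(lin)))
})

test_that("fallback and sigmoid fit agree within one grid step at 1% noise", {
  agree <- vapply(1:100, function(s) {
    cv <- make_sigmoid_curve(tm = 52, dt = 2, a1 = 100, a2 = 1000,
                             noise_frac = 0.01, seed = 1000 + s)
    f <- fit_boltzmann(cv)
    tm2 <- tm_by_second_derivative(cv)
    abs(f$tm - tm2)
  }, numeric(1))
  expect_true(all(is.finite(agree)))
  expect_lt(median(agree), 3)  # one default grid step
  expect_lt(stats::quantile(agree, 0.9), 3)
})

test_that("calibration fit is exact on exact lines and errors on bad input", {
  x <- c(20, 40, 60, 80)
  cal <- fit_calibration(x, 2 * x + 1)
  expect_equal(cal$slope, 2, tolerance = 1e-12)
  expect_equal(cal$intercept, 1, tolerance = 1e-10)
  expect_equal(cal$resid_sd, 0, tolerance = 1e-10)
  expect_error(fit_calibration(c(1, 2), c(1, 2)), "3 points")
  expect_error(fit_calibration(c(5, 5, 5), c(1, 2, 3)), "variance")
})

test_that("well calibration maps pad-scale temperatures linearly", {
  ident <- calibration_line(slope = 1, intercept = 0)
  expect_equal(apply_well_calibration(55, ident), 55)
  cal <- calibration_line()  # default well line
  expect_equal(apply_well_calibration(95, cal), 71.729)
  expect_equal(apply_well_calibration(0, cal), 7.034)
})

test_that("delta-Tm subtracts midpoints with quadrature uncertainty", {
  fa <- list(tm = 48.3, tm_sd = 1.1, converged = TRUE, no_melt = FALSE)
  fb <- list(tm = 46.0, tm_sd = 0.5, converged = TRUE, no_melt = FALSE)
  d <- delta_tm(fa, fb)
  expect_equal(d$shift, 2.3, tolerance = 1e-12)
  expect_equal(d$shift_sd, sqrt(1.1^2 + 0.5^2), tolerance = 1e-12)
  expect_equal(delta_tm(fa, fa)$shift, 0)
  bad <- list(tm = NA_real_, tm_sd = NA_real_, converged = FALSE,
              no_melt = TRUE)
  expect_false(delta_tm(fa, bad)$defined)
})

test_that("fold-CMC arithmetic matches the DDM worked example", {
  expect_equal(fold_cmc(0.05, 0.0087), 5.7)
  expect_equal(fold_cmc(0.0087, 0.0087), 1)
  expect_error(fold_cmc(0.05, 0), "cmc")
})

test_that("plate analysis ranks conditions by their generating stability", {
  # four conditions with distinct true Tm; ranking must match generation
  tms <- c(44, 48, 52, 56)
  groups <- lapply(seq_along(tms), function(i) {
    rows <- LETTERS[i]
    plate_group(paste0(rows, 1:3), paste0("cond", i),
                dye_model("SYPRO", decay_rate = 20),
                unfolding_model(tms[i], 2))
  })
  groups <- c(groups, list(plate_group(c("H10", "H11", "H12"), "blank",
                                       dye_model("SYPRO"), blank = TRUE)))
  layout <- plate_layout(groups)
  run <- simulate_plate_run(layout, build_schedule(), seed = 21)
  rep <- analyze_run(run, layout, reference = "cond1")
  expect_equal(nrow(rep), 4)
  expect_equal(anyDuplicated(rep$condition), 0)
  expect_equal(rep$condition[order(rep$rank)],
               paste0("cond", 4:1))  # rank 1 = most stable
  expect_equal(rep$delta_tm[rep$condition == "cond1"], 0)
  expect_true(all(diff(rep$tm1) > 0))  # Tm increases with true Tm
})

test_that("replicate-wise Tm scatter is reported as the uncertainty", {
  layout <- make_test_layout()
  run <- simulate_plate_run(layout, build_schedule(), seed = 3)
  rep <- analyze_run(run, layout)
  expect_true(all(is.finite(rep$tm1_sd)))
  expect_true(all(rep$tm1_sd > 0))
})

test_that("DDAO-like probe interference yields a no-melt flag", {
  dye_ddao <- dye_model("CPM", f_native = 100, f_unfolded = 1000,
                        background = 50, interference_level = 5e4)
  dye_ddm <- dye_model("CPM", f_native = 100, f_unfolded = 1000,
                       background = 50)
  # each detergent condition carries its own matched blank
  layout <- plate_layout(
    plate_group(c("A1", "A2", "A3"), "DDAO", dye_ddao,
                unfolding_model(48, 2), blank_condition = "blank DDAO"),
    plate_group(c("B1", "B2", "B3"), "DDM", dye_ddm,
                unfolding_model(48, 2), blank_condition = "blank DDM"),
    plate_group(c("H1", "H2", "H3"), "blank DDAO", dye_ddao, blank = TRUE),
    plate_group(c("G1", "G2", "G3"), "blank DDM", dye_ddm, blank = TRUE))
  run <- simulate_plate_run(layout, build_schedule(), seed = 13)
  rep <- analyze_run(run, layout, reference = "DDM")
  expect_true(rep$no_melt[rep$condition == "DDAO"])
  expect_false(rep$no_melt[rep$condition == "DDM"])
  expect_true(is.na(rep$tm1[rep$condition == "DDAO"]))
})

test_that("analysis errors when run wells are missing from the layout", {
  layout <- make_test_layout()
  run <- simulate_plate_run(layout, build_schedule(), seed = 2)
  small <- plate_layout(plate_group(c("A1", "A2", "A3"), "cond1",
                                    dye_model("SYPRO"),
                                    unfolding_model(48, 2)))
  expect_error(analyze_run(run, small), "missing from layout")
})

test_that("an all-blank plate yields an empty report", {
  layout <- plate_layout(plate_group(c("H1", "H2"), "blank",
                                     dye_model("SYPRO"), blank = TRUE))
  run <- simulate_plate_run(layout, build_schedule(), seed = 2)
  rep <- analyze_run(run, layout)
  expect_equal(nrow(rep), 0)
  expect_s3_class(rep, "screen_report")
})
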