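test_that("environmental mortality is the Abbott-corrected control ratio", {
  expect_equal(compute_env_mortality(0.9, 1.0), 0.10)
  expect_equal(compute_env_mortality(0.9, 0.9), 0)
  expect_equal(compute_env_mortality(0.72, 0.9), 0.20)
  expect_equal(compute_env_mortality(0.95, 0.9), 0)  # noise clamps at 0
  expect_error(compute_env_mortality(NULL, 0.9), "required")
})

test_that("normalisation pins LC1 and LC99 to the unit interval", {
  curve <- ll5_params(b = 1.3, c = 0, d = 0.9, e = 7, f = 1.6)
  nc <- normalize_curve(curve)
  expect_equal(1 - norm_survival(nc, 0), 0.01, tolerance = 1e-9)
  expect_equal(1 - norm_survival(nc, 1), 0.99, tolerance = 1e-9)
  u <- seq(0, 1, length.out = 50)
  expect_true(all(diff(norm_survival(nc, u)) < 0))
  # LCx position agrees with an independent grid inversion mapped linearly
  lc1 <- grid_invert(function(C) effect_mortality(curve, C), 0.01, 1e-4, 1e4)
  lc50 <- grid_invert(function(C) effect_mortality(curve, C), 0.50, 1e-4, 1e4)
  lc99 <- grid_invert(function(C) effect_mortality(curve, C), 0.99, 1e-4, 1e4)
  expect_equal(norm_lc(nc, 50), (lc50 - lc1) / (lc99 - lc1), tolerance = 1e-4)
  expect_error(normalize_curve(ll5_params(b = 1, c = 0.5, d = 0.51, e = 1)),
               "LC99")
})

test_that("curve averaging takes pointwise medians with SE bands at 10 levels", {
  curve <- ll5_params(b = 1.3, c = 0, d = 0.9, e = 7, f = 1.6)
  nc <- normalize_curve(curve)
  same <- average_curves(list(nc, nc, nc))
  expect_equal(same$levels, seq(0, 1, length.out = 10))
  expect_equal(same$median, norm_survival(nc, same$levels))
  expect_equal(same$se, rep(0, 10))
  curves <- lapply(c(0.9, 1.3, 2.1), function(b)
    normalize_curve(ll5_params(b = b, c = 0, d = 0.95, e = 3, f = 1.1)))
  avg <- average_curves(curves)
  S <- sapply(curves, norm_survival, u = avg$levels)
  expect_equal(avg$median, apply(S, 1, median))
  expect_equal(avg$se, apply(S, 1, sd) / sqrt(3))
  # band fits bracket the median fit at the averaging levels
  u <- avg$levels[-1]
  expect_true(all(ll5_survival(avg$upper_params, u) >=
                    ll5_survival(avg$median_params, u) - 1e-3))
  expect_true(all(ll5_survival(avg$lower_params, u) <=
                    ll5_survival(avg$median_params, u) + 1e-3))
  expect_error(average_curves(list(nc)), "at least 2")
})

test_that("observed shifts recover constructed displacements", {
  curve <- ll5_params(b = 1.5, c = 0, d = 0.95, e = 2, f = 1.2)
  conc <- exp(seq(log(lc(curve, 2)), log(lc(curve, 99)), length.out = 10))
  arm <- dose_response_data(conc, ll5_survival(curve, conc),
                            control_survival = curve$d)
  # identical arms: no environmental effect, shift is 1
  rec <- observed_shift(study_pair("same", arm, arm), 50)
  expect_equal(rec$shift, 1, tolerance = 1e-6)
  # combined arm displaced by exactly a factor 10 in concentration
  arm10 <- dose_response_data(conc / 10, ll5_survival(curve, conc),
                              control_survival = curve$d)
  rec10 <- observed_shift(study_pair("x10", arm, arm10), 50)
  expect_equal(rec10$shift, 10, tolerance = 1e-6)
})

test_that("noise-free SAM pairs give identical observed and pipeline-predicted shifts", {
  curve <- ll5_params(b = 1.5, c = 0, d = 1, e = 20, f = 1.3)
  pair <- make_sam_pair(curve, m_env = 0.2)
  fits <- fit_study_pair(pair)
  obs <- observed_shift(fits, 50)
  pred <- predicted_shift(fits, stress_capacity(3.2), 50)
  expect_equal(obs$shift, pred, tolerance = 1e-4)
  # the closed-form shift is the same quantity up to the documented LL.5
  # approximation error of refitting a non-log-logistic curve
  closed <- sam_lcx_shift(stress_capacity(3.2), curve, 0.2, 50)
  expect_equal(obs$shift, closed, tolerance = 0.2)
})

test_that("R-squared of shift predictions follows the direct formula", {
  obs <- c(1.5, 3, 8, 40)
  expect_equal(model_r2(obs, obs), 1)
  const <- rep(10^mean(log10(obs)), 4)
  expect_equal(model_r2(obs, const), 0, tolerance = 1e-12)
  pred <- c(2, 2.5, 10, 30)
  lo <- log10(obs); lp <- log10(pred)
  expect_equal(model_r2(obs, pred),
               1 - sum((lo - lp)^2) / sum((lo - mean(lo))^2))
  expect_equal(model_r2(obs, pred, scale = "raw"),
               1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2))
  expect_error(model_r2(c(2, 2), c(1, 3)), "zero variance")
  expect_error(model_r2(1, 1), "length >= 2")
})

test_that("shape calibration is invariant to study order and concentration units", {
  ds <- generate_meta_dataset(sim_config(seed = 13, n_studies = 4,
                                         noise = "none"))
  pairs <- ds$pairs
  cal <- calibrate_shape(pairs)
  cal_rev <- calibrate_shape(rev(pairs))
  expect_equal(cal$shape, cal_rev$shape, tolerance = 1e-6)
  # rescale one study's concentration axis by 1000 (a pure unit change)
  rescale_arm <- function(arm, k) {
    arm$concentrations <- arm$concentrations * k
    arm
  }
  p1 <- pairs[[1]]
  pairs[[1]] <- study_pair(p1$study_id, rescale_arm(p1$tox_arm, 1000),
                           rescale_arm(p1$combined_arm, 1000), p1$m_env)
  cal_scaled <- calibrate_shape(pairs)
  expect_equal(cal$shape, cal_scaled$shape, tolerance = 1e-4)
})

test_that("calibration refuses datasets without environmental stress", {
  ds <- generate_meta_dataset(sim_config(seed = 17, n_studies = 2,
                                         env_mortality_range = c(0, 0),
                                         noise = "none"))
  expect_error(calibrate_shape(ds$pairs), "calibration impossible")
})

test_that("the overall prediction table orders the models as SAM >= CA >= EA", {
  ds <- generate_meta_dataset(sim_config(seed = 5, n_studies = 6,
                                         noise = "none"))
  fits <- lapply(ds$pairs, fit_study_pair)
  avg <- average_curves(lapply(fits, function(f) normalize_curve(f$tox_fit)))
  op <- overall_prediction(avg, stress_capacity(3.2),
                           env_grid = c(0.01, 0.03, 0.05, 0.08, 0.2, 0.4))
  ea <- op[op$model == "ea", ]
  expect_true(all(ea$shift == 1))
  wide <- merge(merge(op[op$model == "sam", c("env_mortality", "x", "shift")],
                      op[op$model == "ca", c("env_mortality", "x", "shift")],
                      by = c("env_mortality", "x"),
                      suffixes = c("_sam", "_ca")),
                ea[, c("env_mortality", "x", "shift")],
                by = c("env_mortality", "x"))
  ok <- stats::complete.cases(wide)
  expect_gt(sum(ok), 5)
  expect_true(all(wide$shift_sam[ok] >= wide$shift_ca[ok]))
  expect_true(all(wide$shift_ca[ok] >= wide$shift[ok]))
  # low-effect sensitivity reacts more strongly than high-effect sensitivity
  sam <- op[op$model == "sam" & op$attainable, ]
  for (m in unique(sam$env_mortality)) {
    s10 <- sam$shift[sam$env_mortality == m & sam$x == 10]
    s50 <- sam$shift[sam$env_mortality == m & sam$x == 50]
    if (length(s10) && length(s50)) expect_gte(s10, s50)
  }
})
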