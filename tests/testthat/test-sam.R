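test_that("stress-dependent survival honours the boundary conventions", {
  d <- stress_capacity(3.2)
  expect_equal(survival_at_stress(d, 0), 1)
  expect_equal(survival_at_stress(d, 1), 0)
  expect_equal(survival_at_stress(d, 1.3), 0)  # uncapped totals allowed
  expect_equal(survival_at_stress(d, 0.5), 0.5)  # symmetry of p = q
  expect_error(survival_at_stress(d, -0.1), ">= 0")
  s <- survival_at_stress(d, seq(0.01, 0.99, by = 0.01))
  expect_true(all(diff(s) < 0))
})

test_that("mortality-to-stress transfer is the beta quantile with exact round trip", {
  for (shape in c(1.5, 3.2, 7)) {
    d <- stress_capacity(shape)
    expect_equal(mortality_to_stress(d, 0), 0)
    expect_equal(mortality_to_stress(d, 1), 1)
    expect_equal(mortality_to_stress(d, 0.5), 0.5)  # p = q symmetry
    S <- seq(0.02, 0.98, by = 0.02)
    expect_equal(mortality_to_stress(d, 1 - survival_at_stress(d, S)), S,
                 tolerance = 1e-9)
  }
  expect_error(mortality_to_stress(stress_capacity(3.2), 1.2), "\\[0, 1\\]")
})

test_that("the grid-reporting convention reproduces the published stress levels", {
  # the original spreadsheet tabulated the distribution at 0.01 resolution;
  # 10% and 15% mortality then read as stress 0.26 and 0.30
  d <- stress_capacity(3.2)
  expect_equal(mortality_to_stress(d, c(0.10, 0.15), resolution = 0.01),
               c(0.26, 0.30))
  # the grid value is the smallest multiple whose cumulative mortality
  # reaches m — never below the continuous quantile
  set.seed(401)
  m <- runif(50)
  s_cont <- mortality_to_stress(d, m)
  s_grid <- mortality_to_stress(d, m, resolution = 0.01)
  expect_true(all(s_grid >= s_cont - 1e-12))
  expect_true(all(s_grid - s_cont < 0.01 + 1e-12))
})

test_that("general stress levels add arithmetically", {
  expect_equal(add_stress(c(0.2, 0.25)), 0.45)
  expect_equal(add_stress(numeric(0)), 0)
  expect_equal(add_stress(c(0.3, 0)), 0.3)
  set.seed(402)
  for (i in 1:10) {
    s <- runif(3)
    expect_identical(add_stress(s), add_stress(rev(s)))
  }
})

test_that("SAM combination is symmetric, reduces to single stressors, and dominates Bliss", {
  d <- stress_capacity(3.2)
  set.seed(403)
  for (i in 1:20) {
    m <- runif(2)
    expect_identical(sam_combined_mortality(d, m),
                     sam_combined_mortality(d, rev(m)))
    expect_equal(sam_combined_mortality(d, c(m[1], 0)), m[1], tolerance = 1e-9)
    expect_gte(sam_combined_mortality(d, m), max(m) - 1e-12)
  }
  expect_equal(sam_combined_mortality(d, c(0.5, 0.5)), 1)  # quantiles sum to 1
  grid <- seq(0.01, 0.5, by = 0.01)
  for (m1 in seq(0.01, 0.5, by = 0.05))
    expect_true(all(sapply(grid, function(m2)
      sam_combined_mortality(d, c(m1, m2)) >=
        ea_combined_mortality(c(m1, m2)) - 1e-12)))
})

test_that("Monte-Carlo individual-based simulation matches the survival formula", {
  d <- stress_capacity(3.2)
  set.seed(404)
  n <- 1e6
  capacity <- rbeta(n, d$p, d$q)
  for (S in c(0.2, 0.45, 0.56, 0.8)) {
    p_hat <- mean(capacity > S)
    p_true <- survival_at_stress(d, S)
    se <- sqrt(p_true * (1 - p_true) / n)
    expect_lt(abs(p_hat - p_true), 3 * se)
  }
})

test_that("predicted combined curves anchor at the env-only control and dominate the toxicant alone", {
  d <- stress_capacity(3.2)
  curve <- ll5_params(b = 1.5, c = 0, d = 0.92, e = 20, f = 1.3)
  conc <- c(0, 10^seq(-1, 2.5, length.out = 40))
  # no environmental stress: exactly the toxicant curve
  expect_equal(predict_combined_curve(d, curve, 0, conc),
               ll5_survival(curve, conc), tolerance = 1e-12)
  pred <- predict_combined_curve(d, curve, 0.15, conc)
  expect_equal(pred[1], curve$d * (1 - 0.15), tolerance = 1e-12)
  expect_true(all(diff(pred) <= 1e-12))
  expect_true(all(pred <= ll5_survival(curve, conc) + 1e-12))
  expect_warning(out <- predict_combined_curve(d, curve, 1, conc), "m_env = 1")
  expect_equal(out, rep(0, length(conc)))
})

test_that("SAM lethal-concentration shifts match brute-force inversion and grow with stress", {
  d <- stress_capacity(3.2)
  curve <- ll5_params(b = 1.5, c = 0, d = 1, e = 20, f = 1.3)
  expect_equal(sam_lcx_shift(d, curve, 0, 50), 1)
  shift <- sam_lcx_shift(d, curve, 0.10, 50)
  oracle <- lc(curve, 50) / brute_force_sam_lcx_star(d, curve, 0.10, 50)
  expect_equal(shift, oracle, tolerance = 1e-6)
  shifts <- sapply(seq(0.01, 0.45, by = 0.02),
                   function(m) sam_lcx_shift(d, curve, m, 50))
  expect_true(all(diff(shifts) > 0))
  expect_true(all(shifts >= 1))
  expect_error(sam_lcx_shift(d, curve, 0.2, 10), "unreachable")
})
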