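test_that("a fixed seed reproduces the dataset byte for byte", {
  cfg <- sim_config(seed = 99, n_studies = 3)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_study_csv(generate_meta_dataset(cfg), f1)
  write_study_csv(generate_meta_dataset(cfg), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  ds_a <- generate_meta_dataset(sim_config(seed = 99, n_studies = 3))
  ds_b <- generate_meta_dataset(sim_config(seed = 100, n_studies = 3))
  expect_false(identical(ds_a$manifest$e, ds_b$manifest$e))
  unlink(c(f1, f2))
})

test_that("generation does not disturb the caller's random stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(generate_meta_dataset(sim_config(seed = 5, n_studies = 1)))
  expect_identical(runif(1), before)
})

test_that("without noise and without environmental stress the arms coincide", {
  ds <- generate_meta_dataset(sim_config(seed = 21, n_studies = 2,
                                         env_mortality_range = c(0, 0),
                                         noise = "none"))
  for (p in ds$pairs) {
    expect_equal(p$m_env, 0)
    expect_equal(p$combined_arm$concentrations, p$tox_arm$concentrations)
    expect_equal(p$combined_arm$survival, p$tox_arm$survival, tolerance = 1e-9)
    expect_equal(p$combined_arm$control_survival, p$tox_arm$control_survival)
  }
})

test_that("generated designs give every arm a partial response and a near-complete kill", {
  ds <- generate_meta_dataset(sim_config(seed = 31, n_studies = 5,
                                         noise = "none"))
  for (p in ds$pairs) {
    for (arm in list(p$tox_arm, p$combined_arm)) {
      m <- 1 - arm$survival / arm$control_survival
      expect_true(any(m > 0.01 & m < 0.99))
      expect_true(any(m > 0.99))
    }
  }
})

test_that("the EA ground-truth option scales the toxicant arm by the env survival", {
  ds <- generate_meta_dataset(sim_config(seed = 41, n_studies = 2,
                                         noise = "none", truth_model = "ea"))
  for (p in ds$pairs) {
    m_env <- attr(p, "truth")$m_env
    tox_at <- function(C) ll5_survival(attr(p, "truth")$params, C)
    expect_equal(p$combined_arm$survival,
                 (1 - m_env) * tox_at(p$combined_arm$concentrations),
                 tolerance = 1e-9)
  }
})

test_that("an empty configuration yields an empty dataset and manifest", {
  ds <- generate_meta_dataset(sim_config(seed = 1, n_studies = 0))
  expect_length(ds$pairs, 0)
  expect_equal(nrow(ds$manifest), 0)
})

test_that("noise-free pairs run through the pipeline match their own prediction", {
  ds <- generate_meta_dataset(sim_config(seed = 51, n_studies = 3,
                                         noise = "none"))
  d32 <- stress_capacity(3.2)
  for (p in ds$pairs) {
    fits <- fit_study_pair(p)
    obs <- observed_shift(fits, 50)
    pred <- predicted_shift(fits, d32, 50)
    if (is.finite(obs$shift) && is.finite(pred))
      expect_equal(obs$shift, pred, tolerance = 1e-3)
  }
})

test_that("doubling the organisms per concentration shrinks shift spread by about sqrt(2)", {
  base <- list(b = c(1.5, 1.5), d = c(0.95, 0.95), log10_e = c(1, 1),
               f = c(1.2, 1.2))
  spread <- function(n_org, reps) {
    shifts <- vapply(seq_len(reps), function(i) {
      cfg <- sim_config(seed = 7000 + i, n_studies = 1,
                        organisms_per_concentration = n_org,
                        env_mortality_range = c(0.2, 0.2),
                        curve_prior = base)
      p <- generate_study_pair(cfg, seed = 7000 + i)
      observed_shift(fit_study_pair(p), 50)$shift
    }, numeric(1))
    sd(log10(shifts), na.rm = TRUE)
  }
  ratio <- spread(500, 200) / spread(1000, 200)
  expect_gt(ratio, 1.15)
  expect_lt(ratio, 1.75)
})
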