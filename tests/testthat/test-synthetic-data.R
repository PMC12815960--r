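test_that("the generator is a pure function of its config", {
  a <- small_sim(seed = 3, n = 120)
  b <- small_sim(seed = 3, n = 120)
  expect_identical(a$stomachs, b$stomachs)
  expect_identical(a$sst, b$sst)
  expect_identical(a$effort, b$effort)
  d <- small_sim(seed = 4, n = 120)
  expect_false(identical(a$stomachs, d$stomachs))
  # presets are pure too
  expect_identical(ppmr_preset("paper_ppmr"), ppmr_preset("paper_ppmr"))
})

test_that("presets pin the calibrated coefficients", {
  expect_equal(ppmr_preset("paper_ppmr")$beta_T_ppmr, 0.041)
  expect_equal(ppmr_preset("paper_ppmr")$beta0_ppmr, 2.2)
  expect_equal(ppmr_preset("paper_predmass")$beta_T_pred, 0.0029)
  expect_equal(ppmr_preset("paper_preymass")$beta_T_prey, -0.0012)
  expect_equal(ppmr_preset("paper_preymass")$beta0_prey, -0.53)
  # interaction preset: conditional slopes at the tercile medians of
  # standardized log effort equal the calibrated low/high lines
  cfg <- ppmr_preset("paper_interaction")
  z <- qnorm(c(1 / 6, 5 / 6))
  expect_equal(cfg$beta_T_ppmr + cfg$beta_TxF_ppmr * z, c(0.03, 0.1))
  expect_equal(cfg$beta0_ppmr + cfg$beta_F_ppmr * z, c(2.2, 1.7))
  expect_error(ppmr_preset("nope"), "paper_interaction")
})

test_that("invalid configs are refused with a message", {
  expect_error(generator_config(sd_rect = -1), "sd_rect")
  expect_error(generator_config(temp_range = c(5, 4)), "increasing")
  expect_error(generator_config(n_rectangles = 0), "below 1")
  expect_error(generator_config(months = 13), "months")
})

test_that("noise-free generation is the exact inverse of the PPMR model", {
  cfg <- ppmr_preset("paper_ppmr", n_stomachs = 80, seed = 5,
                     sd_rect = 0, sd_season = 0, sd_species = 0, sd_resid = 0,
                     sd_prey_item = 0, sd_prey_taxon = 0, sd_prey_family = 0,
                     mean_prey_per_stomach = 1, frac_empty_stomachs = 0)
  sim <- simulate_ppmr_data(cfg)
  obs <- compute_ppmr(match_covariates(sim$stomachs, sim$sst, sim$effort))
  expect_equal(nrow(obs), 80)
  expect_equal(obs$ppmr,
               10^(cfg$beta0_ppmr + cfg$beta_T_ppmr * obs$sst_c),
               tolerance = 1e-12)
})

test_that("stomach counts and matching preconditions hold", {
  sim <- small_sim(seed = 9, n = 500)
  expect_equal(length(unique(sim$stomachs$stomach_id)), 500)
  m <- match_covariates(sim$stomachs, sim$sst, sim$effort)
  expect_true(all(m$sst_matched))
  expect_true(all(!is.na(m$effort_hours)))
  # matched temperature equals the generator's truth temperature
  tt <- sim$truth$stomachs
  one <- m[!duplicated(m$stomach_id), ]
  one <- one[match(tt$stomach_id, one$stomach_id), ]
  expect_equal(one$sst_c, tt$temp, tolerance = 1e-9)
  # truth record stores the drawn random effects
  expect_equal(nrow(sim$truth$rectangles), sim$truth$config$n_rectangles)
  expect_equal(nrow(sim$truth$species_effects), sim$truth$config$n_species)
})

test_that("prey-mass parameterisation derives consistent PPMR coefficients", {
  cfg <- ppmr_preset("paper_preymass")
  expect_equal(cfg$beta0_pred - cfg$beta0_ppmr, -0.53)
  expect_equal(cfg$beta_T_pred - cfg$beta_T_ppmr, -0.0012)
})
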