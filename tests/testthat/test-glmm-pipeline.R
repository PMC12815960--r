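test_that("zero-variance groupings leave fixed effects near the OLS oracle", {
  # true random-effect SDs all zero but groupings keep multiple levels:
  # the mixed fit must agree with closed-form OLS within statistical
  # tolerance, and exactly when every variance estimate is at the boundary
  cfg <- ppmr_preset("paper_ppmr", n_stomachs = 600, seed = 2,
                     sd_rect = 0, sd_season = 0, sd_species = 0,
                     sd_prey_item = 0, sd_prey_taxon = 0, sd_prey_family = 0,
                     mean_prey_per_stomach = 1, frac_empty_stomachs = 0)
  sim <- simulate_ppmr_data(cfg)
  obs <- compute_ppmr(match_covariates(sim$stomachs, sim$sst, sim$effort))
  fit <- suppressMessages(fit_ppmr_model(obs, "log10_ppmr"))
  ols <- lm(log10_ppmr ~ sst_c, data = obs)
  diff <- abs(fit$coefficients$estimate - coef(ols))
  se <- coef(summary(ols))[, "Std. Error"]
  expect_true(all(diff < se))
  if (all(fit$varcor$sd[fit$varcor$group != "Residual"] == 0)) {
    expect_lt(max(diff), 1e-6)
  }
})

test_that("collapsed groupings reduce the mixed surface to exact OLS", {
  cfg <- ppmr_preset("paper_ppmr", n_stomachs = 300, seed = 2,
                     sd_rect = 0, sd_season = 0, sd_species = 0,
                     sd_prey_item = 0, sd_prey_taxon = 0, sd_prey_family = 0,
                     mean_prey_per_stomach = 1, frac_empty_stomachs = 0,
                     n_rectangles = 1, n_species = 1, months = 3:5,
                     years = 2010L)
  sim <- simulate_ppmr_data(cfg)
  obs <- compute_ppmr(match_covariates(sim$stomachs, sim$sst, sim$effort))
  expect_message(fit <- fit_ppmr_model(obs, "log10_ppmr"), "dropped")
  expect_s3_class(fit$model, "lm")
  ols <- lm(log10_ppmr ~ sst_c, data = obs)
  expect_lt(max(abs(fit$coefficients$estimate - coef(ols))), 1e-6)
})

test_that("temperature coefficient is recovered within Monte-Carlo error", {
  r <- run_recovery("paper_ppmr", n_stomachs = 1500, seeds = 1:3)
  expect_true(all(abs(r$temp_slope - 0.041) < 3 * r$temp_slope_se))
  expect_true(all(abs(r$intercept - 2.2) < 3 * r$intercept_se))
})

test_that("refitting on permuted rows returns identical coefficients", {
  obs <- compute_ppmr(small_matched(seed = 13, n = 400))
  set.seed(1)
  perm <- obs[sample(nrow(obs)), ]
  f1 <- suppressMessages(fit_ppmr_model(obs, "log10_ppmr"))
  f2 <- suppressMessages(fit_ppmr_model(perm, "log10_ppmr"))
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-8)
})

test_that("AIC selection distinguishes linear from quadratic signals", {
  obs <- compute_ppmr(small_matched(seed = 21, n = 800))
  lin <- compare_linear_polynomial(obs, "log10_ppmr")
  expect_equal(lin$choice, "linear")
  expect_equal(nrow(lin$comparison), 2)
  # plant a strong curvature and the quadratic must win
  bent <- obs
  bent$log10_ppmr <- bent$log10_ppmr + 0.02 * (bent$sst_c - 11)^2
  quad <- compare_linear_polynomial(bent, "log10_ppmr")
  expect_equal(quad$choice, "quadratic")
  expect_true("I(temp^2)" %in% quad$selected$coefficients$term)
  # AIC identity for the fitted parameter count
  f <- lin$selected
  k <- attr(logLik(f$model), "df")
  expect_equal(f$aic, 2 * k - 2 * f$loglik, tolerance = 1e-8)
})

test_that("stratified trend lines evaluate conditional slopes at medians", {
  m <- small_matched(seed = 31, n = 800)
  obs <- compute_ppmr(m)
  fit <- suppressMessages(fit_ppmr_model(obs, "log10_ppmr", fishing = TRUE))
  terc <- effort_terciles(fit$data$effort_hours)
  lines <- stratified_trendlines(fit, terc)
  expect_equal(nrow(lines), 3)
  cf <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  m_std <- (log10(terc$median) - fit$effort_scaling$mean_log10) /
    fit$effort_scaling$sd_log10
  # slope at median effort m equals beta_T + beta_TxF * m by construction
  expect_equal(lines$slope, unname(cf["temp"] + cf["temp:effort_std"] * m_std))
  # no interaction term -> refusal
  plain <- suppressMessages(fit_ppmr_model(obs, "log10_ppmr"))
  expect_error(stratified_trendlines(plain, terc), class = "ppmr_error")
})

test_that("degenerate and irrelevant structures are handled explicitly", {
  obs <- compute_ppmr(small_matched(seed = 41, n = 200))
  flat <- obs
  flat$log10_ppmr <- 1.5
  fit <- suppressWarnings(suppressMessages(fit_ppmr_model(flat, "log10_ppmr")))
  expect_true(fit$degenerate)
  expect_equal(unname(fit$coefficients$estimate[2]), 0, tolerance = 1e-12)

  # adding an irrelevant random grouping (true SD 0) barely moves estimates
  f_with <- suppressMessages(fit_ppmr_model(obs, "log10_ppmr"))
  f_wo <- suppressMessages(
    fit_ppmr_model(obs, "log10_ppmr",
                   random = c("rectangle", "predator_species"))
  )
  se <- f_wo$coefficients$std_error
  expect_true(all(abs(f_with$coefficients$estimate -
                        f_wo$coefficients$estimate) < se))
})

test_that("prey count and richness models run at size-class granularity", {
  m <- small_matched(seed = 51, n = 500)
  tab <- prey_sizeclass_table(m, empirical_size_scheme(m$prey_indiv_mass_g,
                                                       m$prey_count))
  expect_true(all(c("size_class", "n_prey", "prey_richness") %in% names(tab)))
  fit <- suppressMessages(
    fit_ppmr_model(tab, "log10_prey_count", size_class = TRUE)
  )
  expect_true(any(grepl("size_class", fit$coefficients$term)))
  # stomach-level random intercept engaged (multiple rows per stomach)
  expect_true("stomach_id" %in% fit$random_used)
})
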