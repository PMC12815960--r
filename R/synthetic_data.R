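# Synthetic stomach / SST / effort tables with known ground truth.
#
# The generative model mirrors the analysis model it is meant to test:
#   log10 M_pred  = b0_pred + bT_pred * T + species effect + noise
#   log10 PPMR    = b0 + bT * T + bF * F + bTxF * T * F
#                   + rectangle + season + species effects + noise
# with T the previous-month SST of the stomach's grid cell and F the
# standardized log10 annual fishing effort of its rectangle-year. The target
# log10 mean prey mass of each stomach is log10 M_pred - log10 PPMR, and
# individual prey items are drawn around that target (log-normal, mean-
# corrected so the abundance-weighted arithmetic mean is unbiased), so the
# per-stomach PPMR statistic composed with the generator inverts the true
# model up to sampling noise -- and exactly, when all SDs are zero.

#' Configuration for the synthetic stomach-content generator
#'
#' All slopes and SDs are on the log10 scale. `beta0_prey` / `beta_T_prey`
#' are an alternative parameterisation: when supplied, the PPMR coefficients
#' are derived as `beta_pred - beta_prey` so that the marginal individual
#' prey-mass model has exactly the requested intercept and slope.
#'
#' @param n_stomachs Number of predator stomachs.
#' @param temp_range Annual range of SST across the domain, degrees C.
#' @param seasonal_amplitude Half-amplitude of the within-year SST cycle.
#' @param lat_range,lon_range Spatial extent of the sampled rectangles.
#' @param years Sampling years (effort coverage matches these).
#' @param months Calendar months stomachs may be sampled in (default all).
#' @param beta0_ppmr,beta_T_ppmr Intercept and temperature slope of the true
#'   log10 PPMR model.
#' @param beta_F_ppmr,beta_TxF_ppmr Main and interactive effect of
#'   standardized log10 fishing effort on log10 PPMR.
#' @param beta0_pred,beta_T_pred Intercept/slope of the log10 predator-mass
#'   model.
#' @param beta0_prey,beta_T_prey Optional target intercept/slope of the
#'   marginal log10 individual prey-mass model (overrides the PPMR
#'   coefficients, see above).
#' @param sd_rect,sd_season,sd_species,sd_resid Random-effect and residual
#'   SDs of the PPMR model.
#' @param sd_species_pred,sd_pred_resid Species and residual SDs of the
#'   predator-mass model.
#' @param sd_prey_item Within-stomach dispersion of individual prey masses.
#' @param sd_prey_taxon,sd_prey_family Between-taxon and between-family
#'   offsets of prey mass.
#' @param n_species,n_prey_taxa,n_prey_families,n_rectangles Pool sizes.
#' @param effort_meanlog,effort_sdlog Log-normal (natural log) parameters of
#'   annual effort hours per rectangle-year. Defaults are calibrated so the
#'   effort terciles match the observed visualisation strata (45-566,
#'   576-878, 903-3479 h per year).
#' @param mean_prey_per_stomach Mean total prey abundance per stomach.
#' @param frac_empty_stomachs Fraction of stomachs with no prey.
#' @param frac_taxa_decreasing Fraction of prey taxa given an additional
#'   (negative) temperature slope on individual mass.
#' @param taxon_decline_slope That additional slope, log10 g per degree C.
#' @param seed Integer seed; the whole simulation is a pure function of the
#'   config.
#' @return An object of class `ppmr_config` (a validated list).
#' @export
generator_config <- function(
    n_stomachs = 5000,
    temp_range = c(4, 19),
    seasonal_amplitude = 2.5,
    lat_range = c(49, 63),
    lon_range = c(-2, 8),
    years = 2002:2016,
    months = 1:12,
    beta0_ppmr = 2.2, beta_T_ppmr = 0.041,
    beta_F_ppmr = 0, beta_TxF_ppmr = 0,
    beta0_pred = 2.3, beta_T_pred = 0.0029,
    beta0_prey = NULL, beta_T_prey = NULL,
    sd_rect = 0.08, sd_season = 0.04, sd_species = 0.12, sd_resid = 0.25,
    sd_species_pred = 0.15, sd_pred_resid = 0.10,
    sd_prey_item = 0.15, sd_prey_taxon = 0.25, sd_prey_family = 0.15,
    n_species = 20, n_prey_taxa = 40, n_prey_families = 10,
    n_rectangles = 30,
    effort_meanlog = NULL, effort_sdlog = NULL,
    mean_prey_per_stomach = 4,
    frac_empty_stomachs = 0.02,
    frac_taxa_decreasing = 0,
    taxon_decline_slope = -0.02,
    seed = 1) {

  if (is.null(effort_meanlog) || is.null(effort_sdlog)) {
    # boundaries between the observed effort strata: 566|576 and 878|903 h
    b1 <- (566 + 576) / 2
    b2 <- (878 + 903) / 2
    effort_meanlog <- effort_meanlog %||% mean(log(c(b1, b2)))
    effort_sdlog <- effort_sdlog %||% ((log(b2) - log(b1)) / (2 * qnorm(2 / 3)))
  }
  if (!is.null(beta0_prey)) beta0_ppmr <- beta0_pred - beta0_prey
  if (!is.null(beta_T_prey)) beta_T_ppmr <- beta_T_pred - beta_T_prey

  cfg <- list(
    n_stomachs = as.integer(n_stomachs), temp_range = temp_range,
    seasonal_amplitude = seasonal_amplitude,
    lat_range = lat_range, lon_range = lon_range, years = as.integer(years),
    months = as.integer(months),
    beta0_ppmr = beta0_ppmr, beta_T_ppmr = beta_T_ppmr,
    beta_F_ppmr = beta_F_ppmr, beta_TxF_ppmr = beta_TxF_ppmr,
    beta0_pred = beta0_pred, beta_T_pred = beta_T_pred,
    beta0_prey = beta0_pred - beta0_ppmr, beta_T_prey = beta_T_pred - beta_T_ppmr,
    sd_rect = sd_rect, sd_season = sd_season, sd_species = sd_species,
    sd_resid = sd_resid, sd_species_pred = sd_species_pred,
    sd_pred_resid = sd_pred_resid, sd_prey_item = sd_prey_item,
    sd_prey_taxon = sd_prey_taxon, sd_prey_family = sd_prey_family,
    n_species = as.integer(n_species), n_prey_taxa = as.integer(n_prey_taxa),
    n_prey_families = as.integer(n_prey_families),
    n_rectangles = as.integer(n_rectangles),
    effort_meanlog = effort_meanlog, effort_sdlog = effort_sdlog,
    mean_prey_per_stomach = mean_prey_per_stomach,
    frac_empty_stomachs = frac_empty_stomachs,
    frac_taxa_decreasing = frac_taxa_decreasing,
    taxon_decline_slope = taxon_decline_slope,
    seed = as.integer(seed)
  )
  validate_generator_config(cfg)
  structure(cfg, class = "ppmr_config")
}

validate_generator_config <- function(cfg) {
  sds <- c("sd_rect", "sd_season", "sd_species", "sd_resid",
           "sd_species_pred", "sd_pred_resid", "sd_prey_item",
           "sd_prey_taxon", "sd_prey_family")
  bad <- sds[vapply(sds, function(s) cfg[[s]] < 0, logical(1))]
  if (length(bad) > 0) stop_ppmr("negative SD(s): ", paste(bad, collapse = ", "))
  if (diff(cfg$temp_range) <= 0) stop_ppmr("temp_range must be increasing")
  if (diff(cfg$temp_range) < 2 * cfg$seasonal_amplitude) {
    stop_ppmr("temp_range must span at least twice the seasonal amplitude")
  }
  ns <- c("n_stomachs", "n_species", "n_prey_taxa", "n_prey_families",
          "n_rectangles")
  bad <- ns[vapply(ns, function(s) cfg[[s]] < 1, logical(1))]
  if (length(bad) > 0) stop_ppmr("pool size(s) below 1: ", paste(bad, collapse = ", "))
  if (cfg$mean_prey_per_stomach < 1) stop_ppmr("mean_prey_per_stomach must be >= 1")
  if (!all(cfg$months %in% 1:12)) stop_ppmr("months must be within 1..12")
  if (cfg$frac_empty_stomachs < 0 || cfg$frac_empty_stomachs >= 1) {
    stop_ppmr("frac_empty_stomachs must be in [0, 1)")
  }
  invisible(cfg)
}

#' Paper-calibrated generator presets
#'
#' Each preset pins the true coefficients of one response model to the values
#' of the corresponding fitted line reported for the empirical Northeast
#' Atlantic data, so recovery of those values from simulated data is a
#' meaningful end-to-end test:
#' \describe{
#'   \item{`paper_ppmr`}{log10 PPMR = 2.2 + 0.041 T, no fishing effect.}
#'   \item{`paper_interaction`}{conditional PPMR-temperature lines
#'     2.2 + 0.03 T at the low fishing-effort tercile median and
#'     1.7 + 0.1 T at the high tercile median; the four coefficients are
#'     solved from those two lines, placing the tercile medians at the
#'     normal quantiles of standardized log effort.}
#'   \item{`paper_preymass`}{marginal log10 individual prey mass
#'     = -0.53 - 0.0012 T.}
#'   \item{`paper_predmass`}{log10 predator mass = 2.3 + 0.0029 T.}
#' }
#' All presets share `temp_range = c(4, 19)`, moderate variance components,
#' and `seed = 1`.
#'
#' @param name Preset name.
#' @param ... Overrides passed on to [generator_config()] (e.g. `seed`,
#'   `n_stomachs`).
#' @return A `ppmr_config`.
#' @export
#' @examples
#' ppmr_preset("paper_ppmr")$beta_T_ppmr  # 0.041
ppmr_preset <- function(name = c("paper_ppmr", "paper_interaction",
                                 "paper_preymass", "paper_predmass"), ...) {
  if (is.character(name) && length(name) == 1 &&
      !name %in% c("paper_ppmr", "paper_interaction", "paper_preymass",
                   "paper_predmass")) {
    stop_ppmr("unknown preset '", name, "'; available: paper_ppmr, ",
              "paper_interaction, paper_preymass, paper_predmass")
  }
  name <- match.arg(name)
  args <- switch(name,
    paper_ppmr = list(beta0_ppmr = 2.2, beta_T_ppmr = 0.041),
    paper_interaction = {
      # large-sample medians of the lower/upper effort terciles on the
      # standardized log-effort scale (log-normal effort => normal log effort)
      z_lo <- qnorm(1 / 6)
      z_hi <- qnorm(5 / 6)
      bTxF <- (0.1 - 0.03) / (z_hi - z_lo)
      bF <- (1.7 - 2.2) / (z_hi - z_lo)
      list(beta_T_ppmr = 0.03 - bTxF * z_lo,
           beta0_ppmr = 2.2 - bF * z_lo,
           beta_TxF_ppmr = bTxF, beta_F_ppmr = bF)
    },
    paper_preymass = list(beta0_prey = -0.53, beta_T_prey = -0.0012),
    paper_predmass = list(beta0_pred = 2.3, beta_T_pred = 0.0029)
  )
  do.call(generator_config, utils::modifyList(args, list(...)))
}

#' Simulate stomach, SST, and effort tables with known ground truth
#'
#' Deterministic given the config (including its seed): the same config gives
#' byte-identical tables. Rectangles are real ICES cells spread across the
#' latitude range; their annual mean SST follows a latitudinal gradient
#' spanning `temp_range` (inclusive of the seasonal cycle), and monthly cell
#' means add a sinusoidal seasonal cycle peaking in August. Effort is drawn
#' log-normally per rectangle-year. The SST and effort tables always cover
#' the stomach records, so the matching step finds every record.
#'
#' @param config A `ppmr_config` from [generator_config()] or
#'   [ppmr_preset()].
#' @return A list of class `ppmr_simulation` with elements `stomachs` (one
#'   row per prey item, empty stomachs as all-`NA` prey rows), `sst`,
#'   `effort`, and `truth` (every drawn parameter and random effect; its
#'   `stomachs` element holds the per-stomach true temperature, standardized
#'   effort, and true log10 PPMR).
#' @export
simulate_ppmr_data <- function(config) {
  if (!inherits(config, "ppmr_config")) {
    config <- do.call(generator_config, as.list(config))
  }
  validate_generator_config(config)
  cfg <- config
  set.seed(cfg$seed)

  ## --- rectangles on the real ICES grid, lat-major so latitudes spread ----
  n_lat <- max(1L, floor(diff(cfg$lat_range) / 0.5))
  n_lon <- max(1L, floor(diff(cfg$lon_range) / 1))
  if (cfg$n_rectangles > n_lat * n_lon) {
    stop_ppmr("n_rectangles exceeds the available grid cells in lat/lon range")
  }
  cell <- unique(round(seq(1, n_lat * n_lon, length.out = cfg$n_rectangles)))
  rect <- tibble(
    rect_id = seq_along(cell),
    lat0 = cfg$lat_range[1] + ((cell - 1L) %% n_lat) * 0.5,
    lon0 = cfg$lon_range[1] + ((cell - 1L) %/% n_lat) * 1
  )
  rect$code <- ices_rectangle(rect$lat0 + 0.25, rect$lon0 + 0.5)
  amp <- cfg$seasonal_amplitude
  lat_span <- max(diff(range(rect$lat0)), 0.5)
  rect$annual_mean <- cfg$temp_range[1] + amp +
    (diff(cfg$temp_range) - 2 * amp) * (max(rect$lat0) - rect$lat0) / lat_span

  cell_sst <- function(annual_mean, month) {
    annual_mean + amp * cos(2 * pi * (month - 8) / 12)
  }

  ## --- SST table: covers the year before the first sampling year ---------
  yrs <- c(min(cfg$years) - 1L, cfg$years)
  sst <- tidyr::expand_grid(year = yrs, month = 1:12, rect_id = rect$rect_id) |>
    left_join(rect, by = "rect_id") |>
    transmute(
      year = .data$year, month = .data$month,
      lat = .data$lat0, lon = .data$lon0,
      sst_c = cell_sst(.data$annual_mean, .data$month)
    )
  sst <- validate_sst_table(sst, resolution = c(0.5, 1))

  ## --- effort table -------------------------------------------------------
  effort <- tidyr::expand_grid(year = cfg$years, rect_id = rect$rect_id)
  effort$effort_hours <- rlnorm(nrow(effort), cfg$effort_meanlog,
                                cfg$effort_sdlog)
  effort <- effort |>
    left_join(rect[c("rect_id", "code")], by = "rect_id") |>
    transmute(year = .data$year, ices_rectangle = .data$code,
              effort_hours = round(.data$effort_hours, 2))

  ## --- random effects ------------------------------------------------------
  b_rect <- rnorm(nrow(rect), 0, cfg$sd_rect)
  b_season <- setNames(rnorm(4, 0, cfg$sd_season),
                       c("winter", "spring", "summer", "autumn"))
  species <- sprintf("predator_%02d", seq_len(cfg$n_species))
  b_sp_ppmr <- rnorm(cfg$n_species, 0, cfg$sd_species)
  b_sp_pred <- rnorm(cfg$n_species, 0, cfg$sd_species_pred)

  ## --- prey taxon pool -----------------------------------------------------
  taxa <- sprintf("taxon_%02d", seq_len(cfg$n_prey_taxa))
  fam_of <- ((seq_len(cfg$n_prey_taxa) - 1L) %% cfg$n_prey_families) + 1L
  families <- sprintf("family_%02d", seq_len(cfg$n_prey_families))
  fam_off <- rnorm(cfg$n_prey_families, 0, cfg$sd_prey_family)
  tax_off <- rnorm(cfg$n_prey_taxa, 0, cfg$sd_prey_taxon) + fam_off[fam_of]
  n_dec <- round(cfg$frac_taxa_decreasing * cfg$n_prey_taxa)
  dec_idx <- if (n_dec > 0) sample(cfg$n_prey_taxa, n_dec) else integer(0)
  tax_slope <- numeric(cfg$n_prey_taxa)
  tax_slope[dec_idx] <- cfg$taxon_decline_slope
  # latitudinal habitat preference drives community turnover between cells
  tax_pref <- seq(cfg$lat_range[1], cfg$lat_range[2],
                  length.out = cfg$n_prey_taxa)
  tax_abund <- rlnorm(cfg$n_prey_taxa, 0, 0.5)
  w <- outer(rect$lat0, tax_pref,
             function(lat, pref) exp(-0.5 * ((lat - pref) / 5)^2))
  w <- sweep(w, 2, tax_abund, `*`)

  ## --- stomachs -------------------------------------------------------------
  n <- cfg$n_stomachs
  s_rect <- sample(nrow(rect), n, replace = TRUE)
  # sample.int avoids the scalar pitfall of sample() when only one
  # year/month is configured
  s_year <- cfg$years[sample.int(length(cfg$years), n, replace = TRUE)]
  s_month <- cfg$months[sample.int(length(cfg$months), n, replace = TRUE)]
  s_species <- sample(cfg$n_species, n, replace = TRUE)
  s_lat <- rect$lat0[s_rect] + runif(n) * 0.5
  s_lon <- rect$lon0[s_rect] + runif(n) * 1

  # truth temperature = previous-month cell mean (the value matching returns)
  temp <- cell_sst(rect$annual_mean[s_rect], s_month - 1)

  eff_key <- paste(effort$year,
                   rect$rect_id[match(effort$ices_rectangle, rect$code)])
  s_effort <- effort$effort_hours[match(paste(s_year, s_rect), eff_key)]
  l10e <- log10(s_effort)
  eff_mean <- mean(l10e)
  eff_sd <- if (n > 1 && sd(l10e) > 0) sd(l10e) else 1
  f_std <- (l10e - eff_mean) / eff_sd

  seas <- as.character(season_from_month(s_month))
  l10_pred <- cfg$beta0_pred + cfg$beta_T_pred * temp +
    b_sp_pred[s_species] + rnorm(n, 0, cfg$sd_pred_resid)
  l10_ppmr_true <- cfg$beta0_ppmr + cfg$beta_T_ppmr * temp +
    cfg$beta_F_ppmr * f_std + cfg$beta_TxF_ppmr * temp * f_std +
    b_rect[s_rect] + b_season[seas] + b_sp_ppmr[s_species] +
    rnorm(n, 0, cfg$sd_resid)
  target <- l10_pred - l10_ppmr_true

  ## --- prey items -----------------------------------------------------------
  n_empty <- round(cfg$frac_empty_stomachs * n)
  empty <- if (n_empty > 0) sample(n, n_empty) else integer(0)
  filled <- setdiff(seq_len(n), empty)
  n_ind <- 1L + rpois(n, cfg$mean_prey_per_stomach - 1)
  item_stomach <- rep(filled, n_ind[filled])
  item_taxon <- integer(length(item_stomach))
  for (r in seq_len(nrow(rect))) {
    idx <- which(s_rect[item_stomach] == r)
    if (length(idx) > 0) {
      item_taxon[idx] <- sample.int(cfg$n_prey_taxa, length(idx),
                                    replace = TRUE, prob = w[r, ])
    }
  }
  rows <- tibble(stomach = item_stomach, taxon = item_taxon) |>
    count(.data$stomach, .data$taxon, name = "prey_count")
  # log-normal around the stomach target. Two mean corrections keep the
  # abundance-weighted arithmetic mean of item masses unbiased for
  # 10^target: the usual log-normal half-variance term, and a per-stomach
  # recentring of the taxon mixture under its rectangle's selection
  # probabilities -- without it, spatial turnover in taxon composition
  # would leak a temperature-dependent bias into the measured PPMR.
  pw <- sweep(w, 1, rowSums(w), "/")
  mix <- sweep(pw, 2, 10^tax_off, `*`)
  mix2 <- sweep(pw, 2, 10^(2 * tax_off), `*`)
  sig2_ln <- (cfg$sd_prey_item * log(10))^2
  if (any(tax_slope != 0)) {
    pow_slope <- 10^outer(temp, tax_slope)
    m1 <- rowSums(mix[s_rect, , drop = FALSE] * pow_slope)
    m2 <- rowSums(mix2[s_rect, , drop = FALSE] * pow_slope^2) * exp(sig2_ln)
  } else {
    m1 <- rowSums(mix)[s_rect]
    m2 <- (rowSums(mix2) * exp(sig2_ln))[s_rect]
  }
  c_mix <- log10(m1)
  # second-order correction for the concavity of log10 applied to the
  # finite-sample mean: E[log10 Xbar] ~ log10 E[Xbar] - relvar/(2 n_eff ln10),
  # with n_eff accounting for individuals of one taxon sharing a mass draw
  relvar <- pmax(m2 / m1^2 - 1, 0)
  n_eff <- vapply(split(rows$prey_count, rows$stomach),
                  function(k) sum(k)^2 / sum(k^2), numeric(1))
  n_eff_full <- rep(1, n)
  n_eff_full[as.integer(names(n_eff))] <- n_eff
  jensen <- relvar / (2 * n_eff_full * log(10))
  mu <- target[rows$stomach] + tax_off[rows$taxon] +
    tax_slope[rows$taxon] * temp[rows$stomach] -
    c_mix[rows$stomach] + jensen[rows$stomach]
  corr <- cfg$sd_prey_item^2 * log(10) / 2
  rows$l10_mass <- rnorm(nrow(rows), mu - corr, cfg$sd_prey_item)

  stomach_id <- sprintf("s%06d", seq_len(n))
  prey_rows <- tibble(
    stomach_id = stomach_id[rows$stomach],
    prey_taxon = taxa[rows$taxon],
    prey_family = families[fam_of[rows$taxon]],
    prey_count = as.integer(rows$prey_count),
    prey_indiv_mass_g = 10^rows$l10_mass,
    .idx = rows$stomach
  )
  if (length(empty) > 0) {
    prey_rows <- bind_rows(prey_rows, tibble(
      stomach_id = stomach_id[empty], prey_taxon = NA_character_,
      prey_family = NA_character_, prey_count = NA_integer_,
      prey_indiv_mass_g = NA_real_, .idx = empty
    ))
  }
  stomachs <- prey_rows |>
    mutate(
      haul_id = sprintf("h_%s_%d_%02d", rect$code[s_rect[.data$.idx]],
                        s_year[.data$.idx], s_month[.data$.idx]),
      predator_species = species[s_species[.data$.idx]],
      predator_mass_g = 10^l10_pred[.data$.idx],
      lat = s_lat[.data$.idx], lon = s_lon[.data$.idx],
      year = s_year[.data$.idx], month = s_month[.data$.idx]
    ) |>
    arrange(.data$stomach_id, .data$prey_taxon) |>
    select("stomach_id", "haul_id", "predator_species", "predator_mass_g",
           "prey_taxon", "prey_family", "prey_count", "prey_indiv_mass_g",
           "lat", "lon", "year", "month")

  truth <- list(
    config = cfg,
    coefficients = cfg[c("beta0_ppmr", "beta_T_ppmr", "beta_F_ppmr",
                         "beta_TxF_ppmr", "beta0_pred", "beta_T_pred",
                         "beta0_prey", "beta_T_prey")],
    effort_scaling = list(mean_log10 = eff_mean, sd_log10 = eff_sd),
    rectangles = mutate(rect, effect = b_rect),
    season_effects = tibble(season = names(b_season), effect = unname(b_season)),
    species_effects = tibble(species = species, effect_ppmr = b_sp_ppmr,
                             effect_pred = b_sp_pred),
    taxon_effects = tibble(taxon = taxa, family = families[fam_of],
                           offset = tax_off, slope = tax_slope,
                           lat_pref = tax_pref, abundance_weight = tax_abund),
    stomachs = tibble(
      stomach_id = stomach_id, ices_rectangle = rect$code[s_rect],
      year = s_year, month = s_month, temp = temp,
      effort_hours = s_effort, effort_std = f_std,
      l10_pred_mass = l10_pred, l10_ppmr_true = l10_ppmr_true,
      target_l10_prey_mass = target, empty = seq_len(n) %in% empty
    )
  )
  structure(list(stomachs = stomachs, sst = sst, effort = effort,
                 truth = truth),
            class = "ppmr_simulation")
}

#' @export
print.ppmr_simulation <- function(x, ...) {
  cat("<ppmr_simulation>\n")
  cat("  stomachs:", length(unique(x$stomachs$stomach_id)), "stomachs,",
      nrow(x$stomachs), "prey rows\n")
  cat("  sst:", nrow(x$sst), "cell-months | effort:", nrow(x$effort),
      "rectangle-years\n")
  cat("  true beta_T (PPMR):", x$truth$coefficients$beta_T_ppmr, "\n")
  invisible(x)
}
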