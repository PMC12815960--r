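# The defining statistic: biomass-weighted predator-prey mass ratio per
# stomach, PPMR = M_pred / ((1/n) * sum over prey individuals of their mass),
# where n is the total prey abundance in the stomach. Every prey individual
# counts once, so a row (count k, mass m) contributes k individuals of mass m.

#' Per-stomach predator-prey mass ratio
#'
#' Collapses a prey-item-level table to one observation per stomach. The mean
#' prey mass is the abundance-weighted arithmetic mean of individual prey
#' masses, so PPMR is invariant to how prey individuals are partitioned into
#' rows. Empty stomachs (no prey rows) are dropped. Two alternative
#' conventions are available for comparison but are never the default:
#' `"geometric"` (abundance-weighted geometric mean prey mass) and
#' `"biomass_weighted"` (each individual weighted by its own mass).
#'
#' @param stomachs Prey-item-level tibble, e.g. from [match_covariates()].
#'   Must carry `stomach_id`, `predator_mass_g`, `prey_count`,
#'   `prey_indiv_mass_g`; per-stomach covariate columns (species,
#'   coordinates, matched SST/effort, ...) are carried through.
#' @param convention Prey-mass averaging convention; the default
#'   `"abundance"` is the biomass-weighted PPMR definition above.
#' @return A tibble with one row per non-empty stomach: `ppmr`, `log10_ppmr`,
#'   `mean_prey_mass`, `n_prey` (total abundance), `prey_richness` (distinct
#'   taxa), plus carried covariates.
#' @export
#' @examples
#' x <- tibble::tibble(
#'   stomach_id = "s1", predator_species = "Gadus morhua",
#'   predator_mass_g = 100, prey_taxon = c("a", "b"), prey_family = "f",
#'   prey_count = c(2, 3), prey_indiv_mass_g = c(0.5, 1.0),
#'   lat = 55, lon = 2, year = 1995, month = 5
#' )
#' compute_ppmr(x)$ppmr  # 125
compute_ppmr <- function(stomachs,
                         convention = c("abundance", "geometric",
                                        "biomass_weighted")) {
  convention <- match.arg(convention)
  x <- as_tibble(stomachs)
  need <- c("stomach_id", "predator_mass_g", "prey_count", "prey_indiv_mass_g")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    stop_ppmr("compute_ppmr needs column(s): ", paste(missing, collapse = ", "))
  }
  x <- x[!is.na(x$prey_count) & !is.na(x$prey_indiv_mass_g), , drop = FALSE]
  if (any(x$prey_indiv_mass_g <= 0) || any(x$predator_mass_g <= 0)) {
    stop_ppmr("non-positive mass encountered; validate the table first")
  }

  carry <- intersect(
    c("haul_id", "predator_species", "predator_mass_g", "lat", "lon", "year",
      "month", "ices_rectangle", "season", "years_since_start", "sst_c",
      "sst_matched", "effort_hours", "chlorophyll_ugl", "salinity_psu",
      "depth_m"),
    names(x)
  )

  mean_mass <- function(count, mass) {
    switch(convention,
      abundance = sum(count * mass) / sum(count),
      geometric = 10^(sum(count * log10(mass)) / sum(count)),
      biomass_weighted = sum(count * mass^2) / sum(count * mass)
    )
  }

  obs <- x |>
    group_by(.data$stomach_id) |>
    summarise(
      across(all_of(carry), ~ .x[1]),
      mean_prey_mass = mean_mass(.data$prey_count, .data$prey_indiv_mass_g),
      n_prey = sum(.data$prey_count),
      prey_richness = n_distinct(.data$prey_taxon),
      .groups = "drop"
    ) |>
    mutate(
      ppmr = .data$predator_mass_g / .data$mean_prey_mass,
      log10_ppmr = log10(.data$ppmr)
    )
  obs
}

#' Percent change in PPMR per degree Celsius
#'
#' Back-transforms a slope `b` on the log10 scale: a one-degree warming
#' multiplies the response by `10^b`, i.e. changes it by `(10^b - 1) * 100`
#' percent.
#'
#' @param b Slope of a log10-scale response per degree Celsius.
#' @return Percent change per degree.
#' @export
#' @examples
#' pct_change_per_degree(0.041)  # ~9.9
pct_change_per_degree <- function(b) {
  stopifnot(is.numeric(b), all(is.finite(b)))
  (10^b - 1) * 100
}

#' Percent change compounded across a temperature gradient
#'
#' `(10^(b * delta_t) - 1) * 100`; satisfies the compounding identity
#' `pct_change_over_gradient(b, d) ==
#'  ((1 + pct_change_per_degree(b)/100)^d - 1) * 100`.
#'
#' @inheritParams pct_change_per_degree
#' @param delta_t Temperature span in degrees Celsius (> 0).
#' @return Percent change across the gradient.
#' @export
pct_change_over_gradient <- function(b, delta_t) {
  stopifnot(is.numeric(b), all(is.finite(b)), all(delta_t > 0))
  (10^(b * delta_t) - 1) * 100
}
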