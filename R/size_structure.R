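# Prey size-class schemes, fishing-effort terciles, and the species-level
# body-size response classification (percent of species / percent of biomass
# in the no-change / increase / decrease categories).

#' Prey size-class scheme
#'
#' Two cut points (grams) partition prey individual mass into small, medium,
#' and large classes on half-open intervals: small is `(0, cut1)`, medium
#' `[cut1, cut2)`, large `[cut2, Inf)`. The shipped default boundaries are
#' 0.072 g and 1.25 g.
#'
#' @param boundaries Numeric length-2, increasing, positive.
#' @param provenance Label recording where the cuts came from.
#' @return A `size_class_scheme` object.
#' @export
size_class_scheme <- function(boundaries = c(0.072, 1.25),
                              provenance = "paper-default") {
  stopifnot(length(boundaries) == 2, boundaries[1] > 0,
            boundaries[1] < boundaries[2])
  structure(list(boundaries = boundaries, provenance = provenance),
            class = "size_class_scheme")
}

#' Empirical size-class scheme from abundance terciles
#'
#' Recomputes the two cut points as abundance-weighted terciles of prey
#' individual mass, for use when data-derived boundaries are preferred over
#' the shipped defaults.
#'
#' @param mass Prey individual masses (g).
#' @param count Prey abundances (weights); defaults to 1 per row.
#' @return A `size_class_scheme` with provenance `"empirical-terciles"`.
#' @export
empirical_size_scheme <- function(mass, count = NULL) {
  count <- count %||% rep(1, length(mass))
  ok <- !is.na(mass) & !is.na(count)
  x <- rep(mass[ok], count[ok])
  size_class_scheme(unname(quantile(x, c(1 / 3, 2 / 3))),
                    provenance = "empirical-terciles")
}

#' Assign prey size classes
#'
#' @param mass Positive masses in grams.
#' @param scheme A [size_class_scheme()].
#' @return Factor with levels `small`, `medium`, `large`. A mass exactly on a
#'   boundary goes to the larger class.
#' @export
#' @examples
#' assign_size_class(c(0.05, 0.072, 10))
assign_size_class <- function(mass, scheme = size_class_scheme()) {
  if (any(is.na(mass)) || any(mass <= 0)) {
    stop_ppmr("assign_size_class requires positive masses")
  }
  b <- scheme$boundaries
  cls <- ifelse(mass < b[1], "small", ifelse(mass < b[2], "medium", "large"))
  factor(cls, levels = c("small", "medium", "large"))
}

#' Equal-count tercile bins of fishing effort
#'
#' Splits the sorted values into three bins of equal count; when the count is
#' not divisible by 3, the extra members go to the lower bins. Returns the
#' count, min, max, and median of each bin.
#'
#' @param efforts Numeric vector of effort values (>= 3 of them).
#' @return A tibble with columns `bin` (`low`, `medium`, `high`), `n`,
#'   `min`, `max`, `median`.
#' @export
#' @examples
#' effort_terciles(1:9)$median  # 2 5 8
effort_terciles <- function(efforts) {
  efforts <- efforts[!is.na(efforts)]
  n <- length(efforts)
  if (n < 3) stop_ppmr("need at least 3 effort values for terciles")
  x <- sort(efforts)
  base <- n %/% 3L
  rem <- n %% 3L
  sizes <- base + c(rem >= 1L, rem >= 2L, FALSE)
  idx <- rep(1:3, times = sizes)
  if (length(unique(x)) == 1) {
    inform("effort_terciles: all values identical; bins are degenerate")
  }
  tibble(
    bin = factor(c("low", "medium", "high"),
                 levels = c("low", "medium", "high")),
    n = as.integer(sizes),
    min = tapply(x, idx, min),
    max = tapply(x, idx, max),
    median = as.numeric(tapply(x, idx, median))
  )
}

#' Per-stomach, per-size-class prey counts and richness
#'
#' Expands the matched prey-item table to stomach-by-size-class granularity
#' so models with size-class interactions can be fitted for prey count and
#' prey richness. Cells with no prey of a class are absent (dropped, not
#' zero-filled, since the responses are log-transformed).
#'
#' @param matched Matched prey-item-level tibble.
#' @param scheme A [size_class_scheme()].
#' @return A tibble with one row per (stomach, size class): `n_prey`,
#'   `prey_richness`, `size_class`, plus carried covariates.
#' @export
prey_sizeclass_table <- function(matched, scheme = size_class_scheme()) {
  x <- as_tibble(matched)
  x <- x[!is.na(x$prey_count) & !is.na(x$prey_indiv_mass_g), ]
  x$size_class <- assign_size_class(x$prey_indiv_mass_g, scheme)
  carry <- intersect(
    c("predator_species", "predator_mass_g", "lat", "lon", "year", "month",
      "ices_rectangle", "season", "years_since_start", "sst_c", "sst_matched",
      "effort_hours"),
    names(x)
  )
  x |>
    group_by(.data$stomach_id, .data$size_class) |>
    summarise(
      across(all_of(carry), ~ .x[1]),
      n_prey = sum(.data$prey_count),
      prey_richness = n_distinct(.data$prey_taxon),
      .groups = "drop"
    )
}

#' Classify species-level body-size responses to temperature
#'
#' For every species with at least `min_n` observations, fits log10
#' individual body mass against temperature -- a mixed model with an ICES
#' rectangle random intercept where at least two rectangles are present,
#' otherwise a simple regression (the fallback is recorded per species). A
#' species is classified `no_change` when the slope's p-value is at least
#' `alpha`, otherwise `increase` or `decrease` by the slope's sign. Category
#' shares are reported both as percent of classified species and as percent
#' of total biomass.
#'
#' @param data Matched table. For `role = "prey"`, prey-item rows are used
#'   (mass `prey_indiv_mass_g` weighted by `prey_count`, species =
#'   `prey_taxon`, biomass = count x mass). For `role = "predator"`,
#'   per-stomach rows are used (one mass per stomach, biomass = summed
#'   predator mass).
#' @param role `"prey"` or `"predator"`.
#' @param alpha Two-sided significance level (default 0.05).
#' @param min_n Minimum observations per species to attempt classification.
#' @param use_mixed Use the rectangle random intercept when possible.
#' @return A list of class `species_response_table`: `summary` (percent of
#'   species and of biomass per category), `species` (per-species slope,
#'   p-value, biomass, category, model used), and `excluded` (species below
#'   `min_n`).
#' @export
classify_species_responses <- function(data, role = c("prey", "predator"),
                                       alpha = 0.05, min_n = 30,
                                       use_mixed = TRUE) {
  role <- match.arg(role)
  x <- as_tibble(data)
  if ("sst_matched" %in% names(x)) x <- x[x$sst_matched %in% TRUE, ]
  x <- x[!is.na(x$sst_c), ]

  if (role == "prey") {
    x <- x[!is.na(x$prey_indiv_mass_g) & !is.na(x$prey_count), ]
    obs <- tibble(
      species = x$prey_taxon,
      mass = x$prey_indiv_mass_g,
      w = x$prey_count,
      temp = x$sst_c,
      rectangle = x$ices_rectangle %||% ices_rectangle(x$lat, x$lon),
      biomass = x$prey_count * x$prey_indiv_mass_g
    )
  } else {
    # one observation per stomach
    x <- x[!duplicated(x$stomach_id), ]
    obs <- tibble(
      species = x$predator_species,
      mass = x$predator_mass_g,
      w = 1,
      temp = x$sst_c,
      rectangle = x$ices_rectangle %||% ices_rectangle(x$lat, x$lon),
      biomass = x$predator_mass_g
    )
  }
  obs$l10_mass <- log10(obs$mass)

  counts <- obs |> count(.data$species, name = "n_obs")
  excluded <- counts$species[counts$n_obs < min_n]
  keep <- setdiff(counts$species, excluded)

  fit_one <- function(d) {
    mixed_ok <- use_mixed && length(unique(d$rectangle)) >= 2
    if (mixed_ok) {
      m <- tryCatch(
        suppressWarnings(suppressMessages(
          lme4::lmer(l10_mass ~ temp + (1 | rectangle), data = d,
                     weights = w, REML = TRUE)
        )),
        error = function(e) NULL
      )
      if (!is.null(m)) {
        cf <- coef(summary(m))
        df <- nrow(d) - nrow(cf)
        return(tibble(slope = cf["temp", "Estimate"],
                      p_value = 2 * pt(-abs(cf["temp", "t value"]), df),
                      model = "mixed"))
      }
    }
    m <- lm(l10_mass ~ temp, data = d, weights = w)
    cf <- coef(summary(m))
    if (!"temp" %in% rownames(cf) || is.na(cf["temp", "Estimate"])) {
      return(tibble(slope = NA_real_, p_value = NA_real_, model = "degenerate"))
    }
    tibble(slope = cf["temp", "Estimate"], p_value = cf["temp", "Pr(>|t|)"],
           model = "ols")
  }

  per_species <- obs |>
    filter(.data$species %in% keep) |>
    group_by(.data$species) |>
    group_modify(~ bind_cols(
      fit_one(.x),
      tibble(n_obs = nrow(.x), biomass = sum(.x$biomass))
    )) |>
    ungroup() |>
    mutate(category = case_when(
      is.na(.data$p_value) | .data$p_value >= alpha ~ "no_change",
      .data$slope > 0 ~ "increase",
      TRUE ~ "decrease"
    ))

  lev <- c("no_change", "increase", "decrease")
  summary <- per_species |>
    mutate(category = factor(.data$category, levels = lev)) |>
    group_by(.data$category, .drop = FALSE) |>
    summarise(n_species = n(), biomass = sum(.data$biomass),
              .groups = "drop") |>
    mutate(
      pct_species = 100 * .data$n_species / sum(.data$n_species),
      pct_biomass = 100 * .data$biomass / sum(.data$biomass)
    )

  structure(list(summary = summary, species = per_species,
                 excluded = excluded, role = role, alpha = alpha,
                 min_n = min_n),
            class = "species_response_table")
}

#' @export
print.species_response_table <- function(x, ...) {
  cat("<species_response_table>", x$role, "| alpha =", x$alpha, "\n")
  print(x$summary)
  if (length(x$excluded) > 0) {
    cat("  excluded (n <", x$min_n, "):", length(x$excluded), "species\n")
  }
  invisible(x)
}
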