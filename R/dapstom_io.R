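# Readers and spatiotemporal matching for DAPSTOM-style stomach tables,
# gridded monthly SST, and annual fishing effort per ICES rectangle.

.stomach_required <- c(
  "stomach_id", "predator_species", "predator_mass_g", "prey_taxon",
  "prey_family", "prey_count", "prey_indiv_mass_g", "lat", "lon",
  "year", "month"
)

#' Read a stomach-content table
#'
#' Reads a CSV with one row per prey item (rows sharing `stomach_id` belong to
#' one predator stomach). Rows violating basic invariants (non-positive
#' masses, zero prey counts, coordinates off the globe) are rejected and
#' returned in the `"rejected"` attribute with a reason, never silently
#' dropped. A row whose prey fields are all `NA` represents an empty stomach
#' and is retained (it is excluded later when PPMR is computed).
#'
#' @param path Path to a CSV file with columns `stomach_id`, `haul_id`
#'   (optional), `predator_species`, `predator_mass_g`, `prey_taxon`,
#'   `prey_family`, `prey_count`, `prey_indiv_mass_g`, `lat`, `lon`, `year`,
#'   `month`, and optionally `chlorophyll_ugl`, `salinity_psu`, `depth_m`.
#' @return A tibble of validated prey-item rows; rejected rows (with a
#'   `reason` column) are attached as `attr(x, "rejected")`.
#' @export
read_stomach_table <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(.stomach_required, names(raw))
  if (length(missing) > 0) {
    stop_ppmr("stomach table is missing mandatory column(s): ",
              paste(missing, collapse = ", "))
  }
  validate_stomach_table(raw)
}

#' @rdname read_stomach_table
#' @param x A data frame already holding stomach rows (e.g. from
#'   [simulate_ppmr_data()]); validated in place.
#' @export
validate_stomach_table <- function(x) {
  x <- as_tibble(x)
  empty <- is.na(x$prey_taxon) & is.na(x$prey_count) & is.na(x$prey_indiv_mass_g)
  reason <- rep(NA_character_, nrow(x))
  bad <- function(cond, why) ifelse(is.na(reason) & cond, why, reason)
  reason <- bad(is.na(x$predator_mass_g) | x$predator_mass_g <= 0,
                "non-positive predator mass")
  reason <- bad(!empty & (is.na(x$prey_count) | x$prey_count < 1),
                "prey count below 1")
  reason <- bad(!empty & (is.na(x$prey_indiv_mass_g) | x$prey_indiv_mass_g <= 0),
                "non-positive prey mass")
  reason <- bad(is.na(x$lat) | x$lat < -90 | x$lat > 90, "latitude out of range")
  reason <- bad(is.na(x$lon) | x$lon <= -180 | x$lon > 180, "longitude out of range")
  reason <- bad(is.na(x$month) | !(x$month %in% 1:12), "month out of range")
  rejected <- x[!is.na(reason), , drop = FALSE]
  if (nrow(rejected) > 0) {
    rejected$reason <- reason[!is.na(reason)]
    inform(sprintf("read_stomach_table: rejected %d row(s); see attr(, 'rejected')",
                   nrow(rejected)))
  }
  out <- x[is.na(reason), , drop = FALSE]
  attr(out, "rejected") <- as_tibble(rejected)
  out
}

#' Read a gridded monthly sea-surface temperature table
#'
#' @param path CSV with columns `year`, `month`, `lat`, `lon`, `sst_c`; at
#'   most one value per (year, month, cell).
#' @param resolution Optional numeric of length 2, the grid step in degrees
#'   `c(lat, lon)`. Inferred from the coordinate spacing when omitted.
#' @return A tibble with a `"resolution"` attribute used for cell lookup.
#' @export
read_sst_table <- function(path, resolution = NULL) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_sst_table(x, resolution)
}

#' @rdname read_sst_table
#' @param x A data frame of SST records.
#' @export
validate_sst_table <- function(x, resolution = NULL) {
  x <- as_tibble(x)
  need <- c("year", "month", "lat", "lon", "sst_c")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    stop_ppmr("sst table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(x[c("year", "month", "lat", "lon")]) > 0) {
    stop_ppmr("sst table has duplicate (year, month, cell) records")
  }
  if (is.null(resolution)) {
    step <- function(v) {
      u <- sort(unique(round(v, 6)))
      if (length(u) < 2) return(0.5)
      min(diff(u))
    }
    resolution <- c(step(x$lat), step(x$lon))
  }
  stopifnot(length(resolution) == 2, all(resolution > 0))
  attr(x, "resolution") <- resolution
  x
}

#' Read an annual fishing-effort table
#'
#' @param path CSV with columns `year`, `ices_rectangle`, `effort_hours`.
#' @return A validated tibble (one record per year x rectangle, effort >= 0).
#' @export
read_effort_table <- function(path) {
  validate_effort_table(readr::read_csv(path, show_col_types = FALSE,
                                        progress = FALSE))
}

#' @rdname read_effort_table
#' @param x A data frame of effort records.
#' @export
validate_effort_table <- function(x) {
  x <- as_tibble(x)
  need <- c("year", "ices_rectangle", "effort_hours")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    stop_ppmr("effort table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (any(x$effort_hours < 0, na.rm = TRUE)) stop_ppmr("negative fishing effort")
  if (anyDuplicated(x[c("year", "ices_rectangle")]) > 0) {
    stop_ppmr("effort table has duplicate (year, rectangle) records")
  }
  x
}

#' Match previous-month sea-surface temperature to stomach records
#'
#' Each record is matched to the monthly mean SST of the grid cell containing
#' its coordinates for the *previous* calendar month (a stomach sampled in
#' May 1992 gets the April 1992 mean; January records roll back to December
#' of the previous year). Cell lookup floors the coordinate to the grid cell
#' containing the point; no interpolation is performed. Records with no
#' covering cell/month get `sst_c = NA` and `sst_matched = FALSE` rather than
#' a silent zero.
#'
#' @param stomachs A stomach tibble (prey-item rows or any table with `lat`,
#'   `lon`, `year`, `month`).
#' @param sst An SST tibble from [read_sst_table()] / [validate_sst_table()].
#' @return `stomachs` with `sst_c` and `sst_matched` columns added.
#' @export
match_temperature <- function(stomachs, sst) {
  res <- attr(sst, "resolution") %||% attr(validate_sst_table(sst), "resolution")
  origin <- c(min(sst$lat), min(sst$lon))
  pm <- previous_month(stomachs$year, stomachs$month)
  key <- tibble(
    .row = seq_len(nrow(stomachs)),
    year = pm$year,
    month = pm$month,
    lat = snap_to_grid(stomachs$lat, origin[1], res[1]),
    lon = snap_to_grid(stomachs$lon, origin[2], res[2])
  )
  sst_key <- sst |>
    mutate(lat = round(.data$lat, 6), lon = round(.data$lon, 6)) |>
    select("year", "month", "lat", "lon", "sst_c")
  hit <- left_join(key, sst_key, by = c("year", "month", "lat", "lon"))
  hit <- hit[order(hit$.row), ]
  out <- stomachs
  out$sst_c <- hit$sst_c
  out$sst_matched <- !is.na(hit$sst_c)
  out
}

#' Match annual fishing effort to stomach records
#'
#' Joins effort hours on (sampling year, ICES rectangle). Absence of effort
#' is a valid outcome: unmatched records keep `effort_hours = NA` and remain
#' in the temperature-only dataset; downstream fishing-effect models use only
#' the matched subset.
#'
#' @param stomachs A table with `lat`, `lon`, `year` (an `ices_rectangle`
#'   column is reused when already present).
#' @param effort An effort tibble from [read_effort_table()].
#' @param multi_year_mean If `TRUE`, match the across-year mean effort of the
#'   rectangle instead of the sampling year's value.
#' @return `stomachs` with `ices_rectangle` and `effort_hours` columns.
#' @export
match_effort <- function(stomachs, effort, multi_year_mean = FALSE) {
  effort <- validate_effort_table(effort)
  out <- stomachs
  if (!"ices_rectangle" %in% names(out)) {
    out$ices_rectangle <- ices_rectangle(out$lat, out$lon)
  }
  if (multi_year_mean) {
    eff <- effort |>
      group_by(.data$ices_rectangle) |>
      summarise(effort_hours = mean(.data$effort_hours), .groups = "drop")
    out <- left_join(out, eff, by = "ices_rectangle")
  } else {
    out <- left_join(out, effort[c("year", "ices_rectangle", "effort_hours")],
                     by = c("year", "ices_rectangle"))
  }
  out
}

#' Build the analysis-ready matched table
#'
#' Assigns ICES rectangles and seasons, matches previous-month SST and annual
#' fishing effort, and adds `years_since_start`. Records without SST are
#' flagged (`sst_matched = FALSE`) and excluded from model fitting
#' downstream; records without effort stay in the temperature-only dataset.
#'
#' @param stomachs Stomach tibble (prey-item rows).
#' @param sst SST tibble.
#' @param effort Optional effort tibble.
#' @param start_year Year zero for `years_since_start`; defaults to the
#'   earliest sampling year present.
#' @param multi_year_mean Passed to [match_effort()].
#' @return The matched prey-item-level tibble.
#' @export
match_covariates <- function(stomachs, sst, effort = NULL,
                             start_year = NULL, multi_year_mean = FALSE) {
  out <- stomachs
  out$ices_rectangle <- ices_rectangle(out$lat, out$lon)
  out$season <- season_from_month(out$month)
  start_year <- start_year %||% min(out$year)
  out$years_since_start <- out$year - start_year
  out <- match_temperature(out, sst)
  if (!is.null(effort)) out <- match_effort(out, effort, multi_year_mean)
  out
}
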