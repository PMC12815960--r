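# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# one small stomach table: two stomachs, one with two prey rows
tiny_stomachs <- function() {
  tibble::tibble(
    stomach_id = c("s1", "s1", "s2"),
    haul_id = "h1",
    predator_species = c("Gadus morhua", "Gadus morhua", "Merlangius merlangus"),
    predator_mass_g = c(100, 100, 10),
    prey_taxon = c("Ammodytes", "Sprattus", "Crangon"),
    prey_family = c("Ammodytidae", "Clupeidae", "Crangonidae"),
    prey_count = c(2L, 3L, 1L),
    prey_indiv_mass_g = c(0.5, 1.0, 10),
    lat = c(55.2, 55.2, 51.2),
    lon = c(2.1, 2.1, 4.3),
    year = 1995L,
    month = 5L
  )
}

# a one-cell SST layer covering 1994-1995, value = year + month / 100
tiny_sst <- function(lat0 = 55, lon0 = 2, res = c(0.5, 1)) {
  g <- expand.grid(year = 1994:1995, month = 1:12)
  x <- tibble::tibble(year = g$year, month = g$month, lat = lat0, lon = lon0,
                      sst_c = g$year - 1990 + g$month / 100)
  validate_sst_table(x, resolution = res)
}

tiny_effort <- function() {
  tibble::tibble(
    year = c(1995L, 2005L, 2005L),
    ices_rectangle = c("39F2", "31F4", "39F2"),
    effort_hours = c(500, 812, 120)
  )
}

# small simulation shared by several files (cheap, deterministic)
small_sim <- function(seed = 7, n = 600, ...) {
  simulate_ppmr_data(ppmr_preset("paper_ppmr", n_stomachs = n, seed = seed,
                                 ...))
}

small_matched <- function(seed = 7, n = 600, ...) {
  sim <- small_sim(seed, n, ...)
  match_covariates(sim$stomachs, sim$sst, sim$effort)
}

# independent brute-force oracle for the published ICES rectangle coding
# rule, written as an explicit enumeration (not shared with the package
# implementation): rows count 0.5-degree bands up from 36N; column A covers
# 44W-40W with digits 0-3; letters B..M (no I) then cover 10 degrees each
# with a digit per degree.
oracle_rectangle <- function(lat, lon) {
  rows <- sprintf("%02d", seq_len(99))
  row <- rows[findInterval(lat, seq(36, 85.5, by = 0.5))]
  letters_tbl <- data.frame(
    letter = c("A", "B", "C", "D", "E", "F", "G", "H", "J", "K", "L", "M"),
    west = c(-44, -40, -30, -20, -10, 0, 10, 20, 30, 40, 50, 60),
    east = c(-40, -30, -20, -10, 0, 10, 20, 30, 40, 50, 60, 70)
  )
  i <- which(lon >= letters_tbl$west & lon < letters_tbl$east)
  digit <- floor(lon - letters_tbl$west[i])
  paste0(row, letters_tbl$letter[i], digit)
}
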