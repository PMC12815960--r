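#' Meteorological season from calendar month
#'
#' Dec--Feb are winter, Mar--May spring, Jun--Aug summer, Sep--Nov autumn.
#'
#' @param month Integer vector of calendar months (1--12).
#' @return A factor with levels `winter`, `spring`, `summer`, `autumn`.
#' @export
#' @examples
#' season_from_month(c(1, 4, 7, 10))
season_from_month <- function(month) {
  stopifnot(is.numeric(month), all(month %in% 1:12))
  s <- c("winter", "winter", "spring", "spring", "spring",
         "summer", "summer", "summer", "autumn", "autumn", "autumn", "winter")
  factor(s[month], levels = c("winter", "spring", "summer", "autumn"))
}

# previous calendar month, rolling the year back over January
previous_month <- function(year, month) {
  prev <- month - 1L
  year <- ifelse(prev == 0L, year - 1L, year)
  prev <- ifelse(prev == 0L, 12L, prev)
  list(year = as.integer(year), month = as.integer(prev))
}

# snap a coordinate to the lower edge of its grid cell
snap_to_grid <- function(x, origin, res) {
  round(origin + floor((x - origin) / res + 1e-9) * res, 6)
}

stop_ppmr <- function(...) abort(paste0(...), class = "ppmr_error")
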