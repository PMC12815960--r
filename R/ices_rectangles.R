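# ICES statistical rectangles: 0.5 deg latitude bands numbered "01", "02", ...
# from 36 degN, and longitude columns lettered from 44 degW. Column "A" is the
# special four-cell block 44-40 degW (A0-A3); from 40 degW each letter B..M
# (skipping I) spans 10 degrees with a trailing digit per 1 degree.
# All bands are half-open [low, high): a point on a boundary belongs to the
# higher band.

.ices_letters <- c("B", "C", "D", "E", "F", "G", "H", "J", "K", "L", "M")

#' Band indices of an ICES statistical rectangle
#'
#' @param lat,lon Numeric vectors of decimal degrees (west negative).
#' @return A tibble with `lat_band` (0-based index of the 0.5 degree band from
#'   36 degN) and `lon_band` (0-based index of the 1 degree band from 44 degW).
#' @export
ices_rectangle_bands <- function(lat, lon) {
  stopifnot(length(lat) == length(lon))
  if (any(lat < 36, na.rm = TRUE)) {
    stop_ppmr("latitude below 36 degN is outside the ICES rectangle domain")
  }
  if (any(lon < -44 | lon > 68.5, na.rm = TRUE)) {
    stop_ppmr("longitude outside the ICES rectangle domain (44 degW to 68.5 degE)")
  }
  tibble(
    lat_band = as.integer(floor((lat - 36) / 0.5 + 1e-9)),
    lon_band = as.integer(floor(lon + 44 + 1e-9))
  )
}

#' ICES statistical rectangle code for a coordinate
#'
#' Assigns the standard ICES alphanumeric rectangle label (e.g. `"31F4"`) for
#' points on the 0.5 degree latitude by 1 degree longitude reporting grid.
#' Band intervals are half-open, so a point on a boundary falls in the
#' higher rectangle.
#'
#' @inheritParams ices_rectangle_bands
#' @return Character vector of rectangle codes.
#' @export
#' @examples
#' ices_rectangle(51.2, 4.3)  # "31F4"
ices_rectangle <- function(lat, lon) {
  b <- ices_rectangle_bands(lat, lon)
  row <- sprintf("%02d", b$lat_band + 1L)
  col <- character(length(b$lon_band))
  a <- b$lon_band < 4L
  col[a] <- paste0("A", b$lon_band[a])
  if (any(!a)) {
    off <- b$lon_band[!a] - 4L
    col[!a] <- paste0(.ices_letters[off %/% 10L + 1L], off %% 10L)
  }
  paste0(row, col)
}

#' Parse an ICES rectangle code back to its grid cell
#'
#' @param code Character vector of rectangle codes such as `"31F4"`.
#' @return A tibble with `lat_band`, `lon_band`, and the south-west corner
#'   `lat0`, `lon0` of the rectangle (0.5 x 1 degree cell).
#' @export
parse_ices_rectangle <- function(code) {
  ok <- grepl("^[0-9]{2}[A-HJ-M][0-9]$", code)
  if (!all(ok)) {
    stop_ppmr("malformed ICES rectangle code(s): ",
              paste(unique(code[!ok]), collapse = ", "))
  }
  row <- as.integer(substr(code, 1, 2))
  letter <- substr(code, 3, 3)
  digit <- as.integer(substr(code, 4, 4))
  lon_band <- ifelse(
    letter == "A", digit,
    4L + (match(letter, .ices_letters) - 1L) * 10L + digit
  )
  if (any(letter == "A" & digit > 3L)) {
    stop_ppmr("column A only has digits 0-3 (44-40 degW)")
  }
  tibble(
    lat_band = row - 1L,
    lon_band = as.integer(lon_band),
    lat0 = 36 + (row - 1L) * 0.5,
    lon0 = -44 + as.integer(lon_band)
  )
}
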