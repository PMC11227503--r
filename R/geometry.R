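# Plot geometry: each 4-ha plot is a 200 m x 200 m square in a local frame
# whose (0;0) corner sits at the georeferenced South-West pit. GeoJSON layers
# store WGS84 coordinates; the mapping between the local metric frame and
# lon/lat is a documented affine (local equirectangular tangent plane at the
# reference corner), which is accurate to well under 0.01% at plot scale.

# meters per degree of longitude/latitude on the WGS84 ellipsoid (standard
# truncated series)
meters_per_degree <- function(lat) {
  phi <- lat * pi / 180
  m_lat <- 111132.92 - 559.82 * cos(2 * phi) + 1.175 * cos(4 * phi) -
    0.0023 * cos(6 * phi)
  m_lon <- 111412.84 * cos(phi) - 93.5 * cos(3 * phi) + 0.118 * cos(5 * phi)
  c(lon = m_lon, lat = m_lat)
}

#' Convert local plot coordinates to WGS84
#'
#' The affine anchored at the plot's (0;0) reference corner: x runs East,
#' y runs North, both in meters.
#'
#' @param x_m,y_m Coordinates in the 0-200 m plot frame.
#' @param ref_lon,ref_lat WGS84 position of the (0;0) corner.
#' @return A two-column matrix `lon`, `lat` (rounded to 1e-8 degree, ~1 mm).
#' @export
local_to_lonlat <- function(x_m, y_m, ref_lon, ref_lat) {
  mpd <- meters_per_degree(ref_lat)
  cbind(lon = round(ref_lon + x_m / mpd[["lon"]], 8),
        lat = round(ref_lat + y_m / mpd[["lat"]], 8))
}

#' Convert WGS84 to local plot coordinates
#'
#' @param lon,lat WGS84 coordinates.
#' @inheritParams local_to_lonlat
#' @return A two-column matrix `x_m`, `y_m`.
#' @export
lonlat_to_local <- function(lon, lat, ref_lon, ref_lat) {
  mpd <- meters_per_degree(ref_lat)
  cbind(x_m = (lon - ref_lon) * mpd[["lon"]],
        y_m = (lat - ref_lat) * mpd[["lat"]])
}

square_ring <- function(x0, y0, size, ref_lon, ref_lat) {
  xs <- c(x0, x0 + size, x0 + size, x0, x0)
  ys <- c(y0, y0, y0 + size, y0 + size, y0)
  local_to_lonlat(xs, ys, ref_lon, ref_lat)
}

# planar shoelace area (m^2) of a lon/lat ring via the inverse affine
ring_area_m2 <- function(ring, ref_lon, ref_lat) {
  xy <- lonlat_to_local(ring[, 1], ring[, 2], ref_lon, ref_lat)
  x <- xy[, 1]; y <- xy[, 2]
  n <- nrow(xy)
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}

#' Build the geometry rows for one 4-ha plot
#'
#' Produces one `plots` feature (the 200 m square) and its four 1-ha subplot
#' features (100 m squares; subplot 1 = SW, 2 = SE, 3 = NW, 4 = NE).
#'
#' @param plot_no Plot number in `c(11:16, 21:24)`.
#' @param treatment One of `"control"`, `"logging"`, `"logging_thinning"`.
#' @param ref_lon,ref_lat WGS84 position of the plot's (0;0) corner.
#' @return List with tibbles `plots` (1 row) and `subplots` (4 rows), each
#'   with a `geometry` list-column of closed lon/lat rings.
#' @export
plot_geometry <- function(plot_no, treatment, ref_lon, ref_lat) {
  stopifnot(plot_no %in% valid_plot_nos())
  ring <- square_ring(0, 0, 200, ref_lon, ref_lat)
  plots <- tibble::tibble(
    plot_no = as.integer(plot_no), treatment = treatment,
    block = block_for_plot(plot_no), area_ha = 4,
    ref_lon = round(ref_lon, 8), ref_lat = round(ref_lat, 8),
    geometry = list(ring)
  )
  corners <- list(`1` = c(0, 0), `2` = c(100, 0), `3` = c(0, 100),
                  `4` = c(100, 100))
  subplots <- tibble::tibble(
    plot_no = as.integer(plot_no),
    subplot_no = 1:4,
    area_ha = 1,
    geometry = lapply(corners, function(cc) {
      square_ring(cc[1], cc[2], 100, ref_lon, ref_lat)
    })
  )
  subplots$geometry <- unname(subplots$geometry)
  list(plots = plots, subplots = subplots)
}
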