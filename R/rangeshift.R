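#' Great-circle distance and initial bearing
#'
#' `haversineKm` is the haversine distance on a sphere of radius
#' 6371.0088 km (delegated to geosphere); `initialBearing` the initial
#' great-circle bearing in degrees clockwise from north, `[0, 360)`,
#' from the standard spherical atan2 form. Both are vectorized.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees.
#' @return numeric km (distance) or degrees (bearing; `NA` for
#'   coincident points).
#' @export
haversineKm <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_KM * 1000) / 1000
}

#' @rdname haversineKm
#' @export
initialBearing <- function(lon1, lat1, lon2, lat2) {
  p <- pi / 180
  y <- sin((lon2 - lon1) * p) * cos(lat2 * p)
  x <- cos(lat1 * p) * sin(lat2 * p) -
    sin(lat1 * p) * cos(lat2 * p) * cos((lon2 - lon1) * p)
  out <- (atan2(y, x) / p) %% 360
  out[lon1 == lon2 & lat1 == lat2] <- NA_real_
  out
}

#' Eight-way compass label of a bearing
#'
#' Nearest of N, NE, E, SE, S, SW, W, NW (45-degree sectors centered on
#' the cardinal and intercardinal directions).
#'
#' @param azimuth degrees clockwise from north.
#' @return character label(s).
#' @export
compassLabel <- function(azimuth) {
  labs <- c("N", "NE", "E", "SE", "S", "SW", "W", "NW")
  labs[(floor(((azimuth %% 360) + 22.5) / 45) %% 8) + 1]
}

#' Suitability-weighted centroid of a probability layer
#'
#' Weighted mean center over the cells with `P >= threshold`, with
#' weight `P x cell area`; coordinates are averaged in lon/lat directly
#' (the planar mean-center convention).
#'
#' @param pLayer suitability matrix.
#' @param grid the [GridDef-class].
#' @param threshold suitable-cell cutoff (default 0.1).
#' @param weighted use `P x area` weights (`FALSE`: area only).
#' @return named numeric `c(lon, lat)`.
#' @export
weightedCentroid <- function(pLayer, grid, threshold = 0.1, weighted = TRUE) {
  sel <- which(!is.na(pLayer) & pLayer >= threshold, arr.ind = TRUE)
  if (!nrow(sel)) stop("no cells at or above the threshold")
  w <- cellAreaKm2(grid, sel[, 1])
  if (weighted) w <- w * pLayer[sel]
  c(lon = sum(w * cellCenterLon(grid, sel[, 2])) / sum(w),
    lat = sum(w * cellCenterLat(grid, sel[, 1])) / sum(w))
}

#' Centroid migration track
#'
#' Consecutive segments between period-ordered centroids: haversine
#' distance, initial bearing with its 8-way compass label, and velocity
#' `distance / yearsBetween`. The cumulative baseline displacement is
#' the great-circle distance from the first centroid to the last.
#'
#' @param centroids data.frame with `period`, `lon`, `lat` (ordered by
#'   period; optionally `scenario`, carried through).
#' @param yearsBetween years separating consecutive periods (default
#'   20).
#' @return list of class `CentroidTrack`: `segments` (data.frame
#'   `fromPeriod`, `toPeriod`, `distanceKm`, `azimuth`, `compass`,
#'   `velocityKmYr`), `cumulativeKm`, `centroids`.
#' @export
buildTrack <- function(centroids, yearsBetween = 20) {
  stopifnot(nrow(centroids) >= 2, yearsBetween > 0)
  n <- nrow(centroids)
  i <- seq_len(n - 1)
  d <- haversineKm(centroids$lon[i], centroids$lat[i],
                   centroids$lon[i + 1], centroids$lat[i + 1])
  az <- initialBearing(centroids$lon[i], centroids$lat[i],
                       centroids$lon[i + 1], centroids$lat[i + 1])
  seg <- data.frame(
    fromPeriod = centroids$period[i], toPeriod = centroids$period[i + 1],
    distanceKm = d, azimuth = az,
    compass = ifelse(is.na(az), NA_character_, compassLabel(az)),
    velocityKmYr = d / yearsBetween, stringsAsFactors = FALSE)
  if ("scenario" %in% names(centroids)) seg$scenario <- centroids$scenario[i + 1]
  structure(list(segments = seg,
                 cumulativeKm = haversineKm(centroids$lon[1], centroids$lat[1],
                                            centroids$lon[n], centroids$lat[n]),
                 centroids = centroids),
            class = "CentroidTrack")
}

#' @export
print.CentroidTrack <- function(x, ...) {
  cat(sprintf("CentroidTrack: %d segment(s); cumulative displacement %.2f km\n",
              nrow(x$segments), x$cumulativeKm))
  print(x$segments, digits = 4)
  invisible(x)
}
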