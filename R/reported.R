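#' Reported switchgrass habitat figures for China
#'
#' Published headline numbers from the switchgrass (*Panicum virgatum*)
#' distribution assessment for China that this package's machinery is
#' designed to reproduce arithmetically: per-scenario habitat-change
#' areas, per-class suitability areas, and suitable-habitat centroids.
#' All areas are in units of 10^4 km^2; coordinates in WGS84 decimal
#' degrees. These tables are consumed by the package's validation
#' checks (rate arithmetic, area closure, centroid geodesy) — they are
#' inputs, not outputs, of this package.
#'
#' @format
#' `switchgrassChangeAreas`: one row per period x scenario with
#' `retained`, `lost`, `gained` areas (10^4 km^2) and the reported
#' `retentionRate`, `lossRate`, `gainRate` (percent).
#'
#' `switchgrassClassAreas`: per period x scenario `high`, `medium`,
#' `low` class areas (10^4 km^2; `NA` where not reported) and the
#' reported suitable `total`.
#'
#' `switchgrassCentroids`: per scenario the period-ordered centroid
#' `lon`/`lat` plus the reported segment `distanceKm` (from the previous
#' period) and `velocityKmYr`.
#' @name reportedSwitchgrass
NULL

#' @rdname reportedSwitchgrass
#' @export
switchgrassChangeAreas <- data.frame(
  period = rep(c("2050s", "2070s", "2090s"), 3),
  scenario = rep(c("SSP1-2.6", "SSP3-7.0", "SSP5-8.5"), each = 3),
  retained = c(681.69, 688.59, 681.64, 681.31, 669.81, 658.47,
               674.97, 654.93, 644.91),
  lost = c(32.01, 25.14, 32.05, 32.41, 43.92, 55.24,
           38.74, 58.78, 68.79),
  gained = c(115.66, 63.65, 129.24, 144.98, 228.50, 252.12,
             165.15, 242.78, 261.53),
  retentionRate = c(82.19, 88.58, 80.87, 79.34, 71.09, 68.18,
                    76.80, 68.47, 66.13),
  lossRate = c(3.86, 3.23, 3.80, 3.77, 4.66, 5.72, 4.41, 6.14, 7.05),
  gainRate = c(13.95, 8.19, 15.33, 16.88, 24.25, 26.10,
               18.79, 25.38, 26.82),
  stringsAsFactors = FALSE)

#' @rdname reportedSwitchgrass
#' @export
switchgrassClassAreas <- data.frame(
  period = c("current", rep(c("2050s", "2070s", "2090s"), 3)),
  scenario = c("current", rep(c("SSP1-2.6", "SSP3-7.0", "SSP5-8.5"),
                              each = 3)),
  high = c(96.21, 139.16, 146.10, 153.14, 150.39, 174.13, 209.79,
           167.40, 186.01, 229.44),
  medium = c(145.37, 138.38, 138.92, 141.54, 148.72, 150.99, 122.48,
             141.75, 137.58, 114.63),
  low = c(342.00, 374.54, 373.95, 368.50, 376.69, 409.58, 412.59,
          377.93, 410.64, NA),
  total = c(583.58, 652.09, 658.98, 663.17, 675.79, 734.70, 744.86,
            687.09, 734.23, 741.37),
  stringsAsFactors = FALSE)

#' @rdname reportedSwitchgrass
#' @export
switchgrassCentroids <- data.frame(
  scenario = rep(c("SSP1-2.6", "SSP3-7.0", "SSP5-8.5"), each = 4),
  period = rep(c("current", "2050s", "2070s", "2090s"), 3),
  lon = c(108.59, 107.93, 107.46, 107.53,
          108.59, 107.17, 106.39, 106.41,
          108.59, 107.14, 106.27, 106.39),
  lat = c(35.40, 36.64, 36.47, 36.72,
          35.40, 36.60, 37.13, 37.39,
          35.40, 36.94, 37.27, 37.58),
  distanceKm = c(NA, 150.00, 45.68, 29.15,
                 NA, 184.63, 91.68, 29.25,
                 NA, 215.61, 85.58, 35.53),
  velocityKmYr = c(NA, 7.5, 2.3, NA, NA, 9.2, 4.6, NA, NA, 10.8, NA, NA),
  stringsAsFactors = FALSE)
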