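#' Classify a suitability layer into the four standard classes
#'
#' Half-open probability bins: non-suitable `[0, 0.1)`, low
#' `[0.1, 0.3)`, medium `[0.3, 0.5)`, high `[0.5, 1]`. Masked (`NA`)
#' cells stay masked.
#'
#' @param pLayer numeric matrix of suitability probabilities in
#'   `[0, 1]`.
#' @param breaks ordered thresholds within (0,1); default
#'   `c(0.1, 0.3, 0.5)`.
#' @param labels class labels (length `length(breaks) + 1`).
#' @return integer matrix of class codes 0..3 with a `"labels"`
#'   attribute.
#' @export
classifySuitability <- function(pLayer, breaks = c(0.1, 0.3, 0.5),
                                labels = c("non", "low", "medium", "high")) {
  stopifnot(all(diff(breaks) > 0), all(breaks > 0 & breaks < 1),
            length(labels) == length(breaks) + 1L)
  v <- pLayer[!is.na(pLayer)]
  if (any(v < 0 | v > 1)) stop("suitability values outside [0, 1]")
  cls <- matrix(NA_integer_, nrow(pLayer), ncol(pLayer))
  ok <- !is.na(pLayer)
  cls[ok] <- findInterval(pLayer[ok], breaks)
  attr(cls, "labels") <- labels
  cls
}

#' Per-class areas and percentages
#'
#' Sums the spherical cell areas of every class and reports the
#' percentage of the total valid area; the suitable total is the sum of
#' the non-"non" classes.
#'
#' @param classLayer classified matrix from [classifySuitability()].
#' @param grid the [GridDef-class].
#' @return data.frame with `class`, `areaKm2`, `percent`; attribute
#'   `"suitableKm2"` carries the suitable (low+medium+high) total.
#' @export
classAreas <- function(classLayer, grid) {
  labels <- attr(classLayer, "labels")
  if (is.null(labels)) labels <- c("non", "low", "medium", "high")
  areaM <- cellAreaMatrix(grid)
  ok <- !is.na(classLayer)
  tot <- sum(areaM[ok])
  areas <- vapply(seq_along(labels) - 1L, function(code)
    sum(areaM[ok & classLayer == code]), numeric(1))
  d <- data.frame(class = labels, areaKm2 = areas,
                  percent = 100 * areas / tot, stringsAsFactors = FALSE)
  attr(d, "suitableKm2") <- suitableArea(d)
  d
}

#' Suitable-habitat total of a class-area table
#'
#' Sum of the class areas other than the non-suitable class — the
#' "total potential suitable habitat" aggregation.
#'
#' @param areas data.frame with `class` and `areaKm2` (as from
#'   [classAreas()], or any table using the same labels).
#' @param nonClass label of the non-suitable class.
#' @return numeric km^2.
#' @export
suitableArea <- function(areas, nonClass = "non") {
  sum(areas$areaKm2[areas$class != nonClass])
}

#' Binary suitable/unsuitable layer
#'
#' `1` where the suitability probability is at or above the threshold
#' (the inclusive 10 percent rule), `0` below; `NA` cells preserved.
#'
#' @param pLayer suitability matrix in `[0, 1]`.
#' @param threshold inclusive threshold (default 0.1).
#' @return integer matrix of 0/1.
#' @export
binarizeSuitability <- function(pLayer, threshold = 0.1) {
  v <- pLayer[!is.na(pLayer)]
  if (any(v < 0 | v > 1)) stop("suitability values outside [0, 1]")
  out <- matrix(NA_integer_, nrow(pLayer), ncol(pLayer))
  ok <- !is.na(pLayer)
  out[ok] <- as.integer(pLayer[ok] >= threshold)
  out
}

#' Change-rate arithmetic
#'
#' Retention/loss/gain rates as percentages of the union of current and
#' future suitable area (`retained + lost + gained`) — the denominator
#' under which the three rates always sum to 100.
#'
#' @param retained,lost,gained areas (any common unit).
#' @return named numeric vector `retention`, `loss`, `gain` (percent).
#' @export
changeRates <- function(retained, lost, gained) {
  u <- retained + lost + gained
  c(retention = 100 * retained / u,
    loss = 100 * lost / u,
    gain = 100 * gained / u)
}

#' Habitat change between two binary suitability maps
#'
#' Per-cell transition of binary suitability between a current and a
#' future map: `0->1` gain (expansion), `1->0` loss (contraction),
#' `1->1` retention (stability), `0->0` never suitable. Areas are
#' spherical cell-area sums; rates use the union denominator
#' ([changeRates()]).
#'
#' @param current,future 0/1 matrices from [binarizeSuitability()] on
#'   the same grid and mask.
#' @param grid the shared [GridDef-class].
#' @return list of class `ChangeSummary`: `layer` (codes 0 never,
#'   1 gained, 2 lost, 3 retained, `NA` masked), `retainedKm2`,
#'   `lostKm2`, `gainedKm2`, `neverKm2`, `rates` (percent), `counts`.
#' @export
habitatChange <- function(current, future, grid) {
  if (!all(dim(current) == dim(future)) ||
      nrow(current) != grid@nRows || ncol(current) != grid@nCols)
    stop("grid mismatch between the two maps")
  if (!identical(is.na(current), is.na(future)))
    stop("mask mismatch between the two maps")
  code <- matrix(NA_integer_, nrow(current), ncol(current))
  ok <- !is.na(current)
  code[ok] <- current[ok] * 2L + future[ok]  # 0,1,2,3 = 0->0,0->1,1->0,1->1
  areaM <- cellAreaMatrix(grid)
  areaOf <- function(k) sum(areaM[ok & code == k])
  retained <- areaOf(3L); lost <- areaOf(2L); gained <- areaOf(1L)
  never <- areaOf(0L)
  layer <- matrix(NA_integer_, nrow(current), ncol(current))
  layer[ok] <- c(0L, 1L, 2L, 3L)[match(code[ok], c(0L, 1L, 2L, 3L))]
  structure(list(layer = layer, retainedKm2 = retained, lostKm2 = lost,
                 gainedKm2 = gained, neverKm2 = never,
                 rates = changeRates(retained, lost, gained),
                 counts = c(never = sum(code[ok] == 0L),
                            gained = sum(code[ok] == 1L),
                            lost = sum(code[ok] == 2L),
                            retained = sum(code[ok] == 3L))),
            class = "ChangeSummary")
}

#' @export
print.ChangeSummary <- function(x, ...) {
  cat(sprintf(
    "ChangeSummary: retained %.2f / lost %.2f / gained %.2f km^2 (%.2f%% / %.2f%% / %.2f%%)\n",
    x$retainedKm2, x$lostKm2, x$gainedKm2,
    x$rates["retention"], x$rates["loss"], x$rates["gain"]))
  invisible(x)
}

#' Jenks natural-breaks utility
#'
#' Exact Fisher-Jenks optimization by dynamic programming (minimum
#' within-class sum of squared deviations). Provided as an optional
#' classification utility; the operative pipeline classifier uses the
#' fixed 0.1/0.3/0.5 probability thresholds.
#'
#' @param x numeric values (large inputs are quantile-downsampled to
#'   `maxSample` points first).
#' @param k number of classes.
#' @param maxSample cap on the number of points optimized exactly.
#' @return numeric vector of `k - 1` interior break values.
#' @export
jenksBreaks <- function(x, k, maxSample = 2000) {
  x <- sort(x[!is.na(x)])
  stopifnot(k >= 2, length(x) >= k)
  if (length(x) > maxSample)
    x <- stats::quantile(x, probs = seq(0, 1, length.out = maxSample),
                         names = FALSE, type = 7)
  n <- length(x)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  ssd <- function(i, j) {  # within-class SSD of x[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  cost <- matrix(Inf, k, n)
  back <- matrix(0L, k, n)
  for (j in seq_len(n)) cost[1, j] <- ssd(1, j)
  for (c in 2:k) {
    for (j in c:n) {
      for (i in c:j) {
        v <- cost[c - 1, i - 1] + ssd(i, j)
        if (v < cost[c, j]) { cost[c, j] <- v; back[c, j] <- i }
      }
    }
  }
  breaks <- numeric(k - 1)
  j <- n
  for (c in k:2) {
    i <- back[c, j]
    breaks[c - 1] <- (x[i - 1] + x[i]) / 2
    j <- i - 1
  }
  breaks
}
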