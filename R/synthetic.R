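#' Synthetic environment stacks with controlled spatial autocorrelation
#'
#' Generates one spatially autocorrelated random field per layer name:
#' white Gaussian noise convolved with a Gaussian kernel of standard
#' deviation `corrLength` (in cells, separable convolution with
#' replicated edges; `corrLength = 0` leaves the noise unsmoothed), then
#' affinely rescaled to the requested `[min, max]` range. Deterministic
#' given `seed`.
#'
#' @param grid a [GridDef-class].
#' @param layerNames character vector of layer names.
#' @param corrLength smoothing scale in cells, `>= 0`.
#' @param seed integer seed.
#' @param ranges optional list (or single `c(min, max)`) of per-layer
#'   output ranges, so layers can mimic realistic predictor ranges
#'   (e.g. elevation 1-4178 m); default `[0, 1]`.
#' @param mask optional logical validity matrix.
#' @return an [EnvStack-class].
#' @export
generateEnvStack <- function(grid, layerNames, corrLength = 5, seed = 1,
                             ranges = c(0, 1), mask = NULL) {
  if (grid@nRows < 1L || grid@nCols < 1L)
    stop("invalid grid: non-positive dimensions")
  if (corrLength < 0) stop("corrLength must be >= 0")
  if (!is.list(ranges)) ranges <- rep(list(ranges), length(layerNames))
  ranges <- rep_len(ranges, length(layerNames))
  set.seed(as.integer(seed))
  layers <- lapply(seq_along(layerNames), function(i) {
    z <- matrix(stats::rnorm(grid@nRows * grid@nCols), grid@nRows)
    if (corrLength > 0) z <- gaussSmooth(z, corrLength)
    rescaleRange(z, ranges[[i]][1], ranges[[i]][2])
  })
  names(layers) <- layerNames
  EnvStack(grid, layers, mask)
}

# Separable Gaussian convolution with replicated-edge padding.
gaussSmooth <- function(z, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  smooth1 <- function(m) {  # along rows (each column convolved)
    n <- nrow(m)
    pad <- rbind(m[rep(1L, r), , drop = FALSE], m,
                 m[rep(n, r), , drop = FALSE])
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k))
      out <- out + k[j] * pad[j:(j + n - 1L), , drop = FALSE]
    out
  }
  t(smooth1(t(smooth1(z))))
}

rescaleRange <- function(z, lo, hi) {
  rng <- range(z, na.rm = TRUE)
  if (rng[1] == rng[2]) return(matrix(lo, nrow(z), ncol(z)))
  lo + (z - rng[1]) / (rng[2] - rng[1]) * (hi - lo)
}

#' Ground-truth Gibbs suitability surface
#'
#' Builds the simulation ground truth used for parameter-recovery
#' testing: a Gibbs density over the valid cells of a stack,
#' `suitability(cell) proportional to exp(sum_j lambda_j f_j(cell))`,
#' normalized to total mass 1. Features are the layers min-max scaled to
#' `[0, 1]` over valid cells ("linear"), optionally plus their squares
#' ("lq", coefficient names `<layer>^2`).
#'
#' @param stack an [EnvStack-class].
#' @param coefficients named numeric vector; names must be layer names
#'   (or `<layer>^2` when `featureForm = "lq"`).
#' @param featureForm `"linear"` or `"lq"`.
#' @return a `TruthModel` object.
#' @exportClass TruthModel
#' @aliases TruthModel makeTruth
setClass("TruthModel", representation(
  stack = "EnvStack", coefficients = "numeric", featureForm = "character",
  suitability = "matrix"
))

setValidity("TruthModel", function(object) {
  s <- object@suitability[validMask(object@stack)]
  if (any(s < 0)) return("suitability must be non-negative")
  if (abs(sum(s) - 1) > 1e-9) return("suitability must sum to 1 over valid cells")
  TRUE
})

setMethod("show", "TruthModel", function(object) {
  cat(sprintf("TruthModel (%s features) over %d valid cells\n",
              object@featureForm, sum(validMask(object@stack))))
  print(object@coefficients)
})

#' @rdname TruthModel-class
#' @export
makeTruth <- function(stack, coefficients, featureForm = c("linear", "lq")) {
  featureForm <- match.arg(featureForm)
  mask <- validMask(stack)
  if (!any(mask)) stop("empty domain: all cells are masked")
  base <- names(stack@layers)
  valid <- c(base, if (featureForm == "lq") paste0(base, "^2"))
  bad <- setdiff(names(coefficients), valid)
  if (length(bad))
    stop("unknown coefficient name(s): ", paste(bad, collapse = ", "))
  eta <- matrix(0, stack@grid@nRows, stack@grid@nCols)
  for (nm in names(coefficients)) {
    lyr <- sub("\\^2$", "", nm)
    f <- rescaleRange(getLayer(stack, lyr), 0, 1)
    if (grepl("\\^2$", nm)) f <- f^2
    eta <- eta + coefficients[[nm]] * f
  }
  eta[!mask] <- NA_real_
  mx <- max(eta, na.rm = TRUE)
  w <- exp(eta - mx)
  w[!mask] <- 0
  suit <- w / sum(w)
  suit[!mask] <- NA_real_
  new("TruthModel", stack = stack, coefficients = coefficients,
      featureForm = featureForm, suitability = suit)
}

#' @rdname TruthModel-class
#' @param truth a `TruthModel`.
#' @export
truthSuitability <- function(truth) truth@suitability

#' Sample clustered occurrence points from a truth surface
#'
#' Draws `n` cells with probability proportional to the truth
#' suitability; each draw emits `perCluster` points at the cell center
#' plus independent Gaussian jitter of standard deviation `clusterSd`
#' degrees (clipped to the grid extent), emulating the spatially
#' clustered raw records a herbarium/database search produces before
#' thinning.
#'
#' @param truth a [TruthModel-class].
#' @param n number of cell draws, `>= 1`.
#' @param clusterSd jitter scale in degrees (0 = points exactly at cell
#'   centers).
#' @param perCluster points emitted per draw.
#' @param seed integer seed.
#' @return an [OccurrenceSet-class] with `n * perCluster` records.
#' @export
sampleOccurrences <- function(truth, n, clusterSd = 0, perCluster = 1,
                              seed = 1) {
  stopifnot(n >= 1)
  grid <- gridDef(truth@stack)
  mask <- validMask(truth@stack)
  p <- truth@suitability[mask]
  if (!length(p) || sum(p) <= 0) stop("empty domain: truth has zero mass")
  idx <- which(mask, arr.ind = TRUE)
  set.seed(as.integer(seed))
  draws <- sample.int(nrow(idx), n, replace = TRUE, prob = p)
  rows <- rep(idx[draws, 1], each = perCluster)
  cols <- rep(idx[draws, 2], each = perCluster)
  lon <- cellCenterLon(grid, cols)
  lat <- cellCenterLat(grid, rows)
  if (clusterSd > 0) {
    lon <- lon + stats::rnorm(length(lon), sd = clusterSd)
    lat <- lat + stats::rnorm(length(lat), sd = clusterSd)
    e <- gridExtent(grid)
    eps <- grid@cellSize * 1e-6
    lon <- pmin(pmax(lon, e["west"] + eps), e["east"] - eps)
    lat <- pmin(pmax(lat, e["south"] + eps), e["north"] - eps)
  }
  OccurrenceSet(id = sprintf("occ%05d", seq_along(lon)),
                lon = lon, lat = lat, species = "synthetic")
}

#' Default synthetic study fixture
#'
#' One call that builds the package's reference simulation: a 60 x 90
#' grid at 2.5 arc-minutes, 8 autocorrelated predictor layers (one
#' rescaled to an elevation-like 1-4178 m range), a Gibbs truth surface
#' driven by three of the layers, and a clustered raw occurrence sample
#' sized so that grid thinning leaves roughly 50 spatially independent
#' points.
#'
#' @param seed integer master seed.
#' @param nDraws number of occurrence cell draws.
#' @param perCluster points per draw (raw records = nDraws x
#'   perCluster).
#' @return list with `stack`, `truth`, `occ` (raw occurrences), `grid`.
#' @export
syntheticStudy <- function(seed = 1, nDraws = 50, perCluster = 3) {
  grid <- GridDef(60, 90, west = 100, south = 30)
  nms <- c("bio3", "bio11", "bio13", "bio15", "bio19",
           "elevation", "slope", "aspect")
  ranges <- list(c(22, 51), c(-16, 16), c(50, 316), c(50, 149), c(2, 201),
                 c(1, 4178), c(0, 3.1), c(0, 360))
  stack <- generateEnvStack(grid, nms, corrLength = 6, seed = seed,
                            ranges = ranges)
  truth <- makeTruth(stack,
                     c(bio11 = 5, bio13 = 3, elevation = -4),
                     featureForm = "linear")
  occ <- sampleOccurrences(truth, n = nDraws, clusterSd = 0.005,
                           perCluster = perCluster, seed = seed + 1000L)
  list(grid = grid, stack = stack, truth = truth, occ = occ)
}
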