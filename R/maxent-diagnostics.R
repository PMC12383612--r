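#' Per-variable percent contribution
#'
#' During fitting, every accepted coordinate update's increase in the
#' penalized objective is credited to the variable underlying the
#' updated feature (product features split the credit equally between
#' their two variables). Credits are normalized to percentages summing
#' to 100.
#'
#' @param model a [MaxEntModel-class].
#' @return data.frame with `variable` and `contribution` (percent),
#'   sorted decreasing.
#' @export
percentContribution <- function(model) {
  cv <- model@creditByVar
  tot <- sum(cv)
  if (tot <= 0) {
    warning("zero total gain: all contributions are 0")
    pct <- cv * 0
  } else {
    pct <- 100 * cv / tot
  }
  d <- data.frame(variable = names(cv), contribution = as.numeric(pct),
                  stringsAsFactors = FALSE, row.names = NULL)
  d[order(-d$contribution, d$variable), , drop = FALSE]
}

#' Background sampling
#'
#' Uniform random sample of valid cells, without replacement, capped at
#' `n` (cells are not excluded for containing presences).
#'
#' @param stack an [EnvStack-class].
#' @param n cap on the number of background cells (default 10,000).
#' @param seed integer seed.
#' @return data.frame of sampled `row`, `col`.
#' @export
sampleBackground <- function(stack, n = 10000, seed = 1) {
  mask <- validMask(stack)
  idx <- which(mask, arr.ind = TRUE)
  set.seed(as.integer(seed))
  take <- sample.int(nrow(idx), min(n, nrow(idx)))
  data.frame(row = idx[take, 1], col = idx[take, 2])
}

#' Fit a model directly from a stack and occurrence set
#'
#' Convenience stage wrapper: samples background cells, extracts raw
#' predictor values at presence and background cells, builds feature
#' matrices on the background scaling (presence values clamped into the
#' background range, which is also the training range), and fits.
#'
#' @param stack an [EnvStack-class].
#' @param occ an [OccurrenceSet-class] (typically thinned).
#' @param fc feature classes (string like `"LQH"`).
#' @param rm regularization multiplier.
#' @param nBackground background cap.
#' @param seed seed for background sampling.
#' @param hingeKnots,thresholdKnots knots per variable.
#' @param variables predictor subset (default: all layers).
#' @param ... passed to [fitMaxent()].
#' @return list: `model`, `presence`/`background` feature matrices,
#'   `bgCells`, `presCells`.
#' @export
fitOnStack <- function(stack, occ, fc = "LQH", rm = 1, nBackground = 10000,
                       seed = 1, hingeKnots = 10, thresholdKnots = 10,
                       variables = NULL, ...) {
  if (is.null(variables)) variables <- layerNames(stack)
  spec <- featureSpec(fc, variables, hingeKnots, thresholdKnots)
  bgCells <- sampleBackground(stack, nBackground, seed)
  bgVals <- extractValues(stack, bgCells)
  asg <- assignCells(occ, gridDef(stack))
  keep <- asg$inside & validMask(stack)[cbind(asg$row, asg$col)]
  if (!any(keep)) stop("no presence points fall on valid cells")
  presCells <- asg[keep, c("row", "col")]
  presVals <- extractValues(stack, presCells)
  bgFM <- buildFeatures(bgVals, spec)
  for (i in seq_along(variables))
    presVals[, i] <- pmin(pmax(presVals[, i], bgFM$scaling$min[i]),
                          bgFM$scaling$max[i])
  presFM <- buildFeatures(presVals, spec, scaling = bgFM$scaling)
  model <- fitMaxent(presFM, bgFM, rm = rm, ...)
  list(model = model, presence = presFM, background = bgFM,
       bgCells = bgCells, presCells = presCells)
}

#' Jackknife test of regularized training gain
#'
#' Refits the model with each variable alone and with all variables but
#' that one, reporting the regularized training gain of every fit next
#' to the full-model gain.
#'
#' @param presValues,bgValues raw predictor matrices (samples x
#'   variables, shared column names).
#' @param fc feature classes.
#' @param rm regularization multiplier.
#' @param hingeKnots,thresholdKnots knots per variable.
#' @param ... passed to [fitMaxent()].
#' @return data.frame with `variable`, `gainOnly`, `gainWithout`, and
#'   the full-model `gainFull` attached to every row.
#' @export
jackknifeGain <- function(presValues, bgValues, fc = "LQH", rm = 1,
                          hingeKnots = 10, thresholdKnots = 10, ...) {
  vars <- colnames(bgValues)
  if (length(vars) < 2) stop("jackknife needs at least 2 variables")
  gainFor <- function(sub) {
    spec <- featureSpec(fc, sub, hingeKnots, thresholdKnots)
    bgFM <- buildFeatures(bgValues[, sub, drop = FALSE], spec)
    pv <- presValues[, sub, drop = FALSE]
    for (i in seq_along(sub))
      pv[, i] <- pmin(pmax(pv[, i], bgFM$scaling$min[i]),
                      bgFM$scaling$max[i])
    presFM <- buildFeatures(pv, spec, scaling = bgFM$scaling)
    model <- fitMaxent(presFM, bgFM, rm = rm, ...)
    trainingGain(model, presFM)
  }
  full <- gainFor(vars)
  data.frame(
    variable = vars,
    gainOnly = vapply(vars, function(v) gainFor(v), numeric(1)),
    gainWithout = vapply(vars, function(v) gainFor(setdiff(vars, v)),
                         numeric(1)),
    gainFull = full, row.names = NULL, stringsAsFactors = FALSE)
}

#' Marginal response curve
#'
#' Logistic suitability as the target variable sweeps its training
#' range while every other variable is held at its background mean.
#'
#' @param model a [MaxEntModel-class].
#' @param variable variable name.
#' @param n number of grid points.
#' @return data.frame with `value` and `suitability`.
#' @export
responseCurve <- function(model, variable, n = 100) {
  vars <- model@spec$variableNames
  if (!variable %in% vars) stop("variable not in model: ", variable)
  i <- match(variable, vars)
  grid <- seq(model@scaling$min[i], model@scaling$max[i], length.out = n)
  vals <- matrix(rep(model@bgMeans, each = n), nrow = n,
                 dimnames = list(NULL, vars))
  vals[, variable] <- grid
  data.frame(value = grid,
             suitability = predictMaxent(model, vals, type = "logistic"))
}

#' Optimal range of a response curve at a probability threshold
#'
#' Smallest and largest predictor values whose suitability reaches the
#' threshold, with linear interpolation at the crossings; `c(NA, NA)`
#' when the curve never reaches it.
#'
#' @param curve data.frame from [responseCurve()] (`value`,
#'   `suitability` on a dense grid).
#' @param threshold probability threshold (default 0.5).
#' @return numeric `c(low, high)`.
#' @export
optimalRange <- function(curve, threshold = 0.5) {
  v <- curve$value; s <- curve$suitability
  above <- s >= threshold
  if (!any(above)) return(c(low = NA_real_, high = NA_real_))
  first <- which(above)[1]
  last <- which(above)[sum(above)]
  interp <- function(i0, i1) {
    # crossing between grid points i0 (below) and i1 (above)
    v[i0] + (threshold - s[i0]) * (v[i1] - v[i0]) / (s[i1] - s[i0])
  }
  low <- if (first == 1) v[1] else interp(first - 1, first)
  high <- if (last == length(v)) v[length(v)] else interp(last + 1, last)
  c(low = low, high = high)
}
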