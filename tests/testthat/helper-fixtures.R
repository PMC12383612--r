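# Shared small fixtures for the test suite. Everything is generated in
# code under fixed seeds; nothing is read from disk.

# Small 2-layer stack with informative structure, for quick model fits.
smallStack <- function(seed = 11, nr = 30, nc = 40) {
  generateEnvStack(GridDef(nr, nc, west = 100, south = 30),
                   c("temp", "precip"), corrLength = 4, seed = seed)
}

# One-variable feature matrices from explicit values (L features only
# unless classes given).
fmPair <- function(presVals, bgVals, classes = "L", hingeKnots = 3,
                   thresholdKnots = 3) {
  vars <- colnames(bgVals)
  spec <- featureSpec(classes, vars, hingeKnots, thresholdKnots)
  bg <- buildFeatures(bgVals, spec)
  pv <- presVals
  for (i in seq_along(vars))
    pv[, i] <- pmin(pmax(pv[, i], bg$scaling$min[i]), bg$scaling$max[i])
  pres <- buildFeatures(pv, spec, scaling = bg$scaling)
  list(pres = pres, bg = bg)
}

# Independent haversine oracle (plain formula, not geosphere).
oracleHaversine <- function(lon1, lat1, lon2, lat2, R = 6371.0088) {
  p <- pi / 180
  h <- sin((lat2 - lat1) * p / 2)^2 +
    cos(lat1 * p) * cos(lat2 * p) * sin((lon2 - lon1) * p / 2)^2
  2 * R * asin(sqrt(pmin(1, h)))
}

# Independent initial-bearing oracle (spherical trigonometry atan2 form).
oracleBearing <- function(lon1, lat1, lon2, lat2) {
  p <- pi / 180
  y <- sin((lon2 - lon1) * p) * cos(lat2 * p)
  x <- cos(lat1 * p) * sin(lat2 * p) -
    sin(lat1 * p) * cos(lat2 * p) * cos((lon2 - lon1) * p)
  (atan2(y, x) / p) %% 360
}

# Penalized maxent objective evaluated directly from feature matrices.
oracleObjective <- function(lambda, presFM, bgFM, betas) {
  eta <- as.numeric(bgFM$values %*% lambda)
  mean(presFM$values %*% lambda) - (max(eta) + log(sum(exp(eta - max(eta))))) -
    sum(betas * abs(lambda))
}
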