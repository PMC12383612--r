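#' Feature specification for the maximum-entropy model
#'
#' Describes which feature classes are enabled and how many knots the
#' piecewise classes get. Classes follow the standard presence-background
#' vocabulary: linear (L), quadratic (Q), pairwise product (P), hinge
#' (H, forward and reverse ramps) and threshold (T, step indicators).
#'
#' @param classes feature classes, either a string like `"LQH"` or a
#'   character vector `c("L","Q","H")`.
#' @param variableNames predictor names the features are built over.
#' @param hingeKnots knots per variable per direction for H (interior,
#'   evenly spaced over the scaled range).
#' @param thresholdKnots knots per variable for T.
#' @return list of class `FeatureSpec`.
#' @export
featureSpec <- function(classes, variableNames, hingeKnots = 30,
                        thresholdKnots = 30) {
  if (length(classes) == 1L && nchar(classes) > 1L)
    classes <- strsplit(classes, "")[[1]]
  classes <- toupper(classes)
  bad <- setdiff(classes, c("L", "Q", "P", "H", "T"))
  if (length(bad)) stop("unknown feature class(es): ", paste(bad, collapse = ","))
  if (!length(classes)) stop("at least one feature class required")
  if ("H" %in% classes && hingeKnots < 1) stop("hingeKnots must be >= 1")
  if ("T" %in% classes && thresholdKnots < 1) stop("thresholdKnots must be >= 1")
  structure(list(classes = intersect(c("L", "Q", "P", "H", "T"), classes),
                 variableNames = variableNames,
                 hingeKnots = as.integer(hingeKnots),
                 thresholdKnots = as.integer(thresholdKnots)),
            class = "FeatureSpec")
}

#' @export
print.FeatureSpec <- function(x, ...) {
  cat(sprintf("FeatureSpec: FC=%s over %d variable(s); H knots %d, T knots %d\n",
              paste(x$classes, collapse = ""), length(x$variableNames),
              x$hingeKnots, x$thresholdKnots))
  invisible(x)
}

#' Build the feature matrix
#'
#' Each raw variable is affinely scaled to `[0, 1]` using min/max over
#' the background (stored in `scaling` and reused verbatim for presence
#' and projection data). Features, in deterministic (class, variable,
#' knot) order:
#' \itemize{
#'   \item L: the scaled value `x'`;
#'   \item Q: `x'^2`;
#'   \item P: all pairwise products `x'_i x'_j` (i < j);
#'   \item H: forward `max(0, (x'-k)/(1-k))` and reverse
#'     `max(0, (k-x')/k)` ramps at interior knots `k = i/(nk+1)`;
#'   \item T: step indicators `1[x' > k]` at interior knots.
#' }
#' Constant variables (zero background range) keep a zero linear column
#' but their Q/H/T features are dropped with a warning.
#'
#' @param values numeric matrix, samples x variables, with column names.
#' @param spec a [featureSpec()].
#' @param scaling optional scaling data.frame from a previous (background)
#'   call; when `NULL` it is computed from `values`.
#' @return list of class `FeatureMatrix`: `values` (samples x features),
#'   `names`, `class` and `vars` (per-feature metadata), `scaling`
#'   (data.frame `var`, `min`, `max`), `spec`, `rawMeans`.
#' @export
buildFeatures <- function(values, spec, scaling = NULL) {
  stopifnot(is.matrix(values), !is.null(colnames(values)))
  vars <- spec$variableNames
  miss <- setdiff(vars, colnames(values))
  if (length(miss)) stop("missing variable(s): ", paste(miss, collapse = ", "))
  values <- values[, vars, drop = FALSE]
  if (any(!is.finite(values))) stop("non-finite predictor values")
  if (is.null(scaling)) {
    scaling <- data.frame(var = vars,
                          min = apply(values, 2, min),
                          max = apply(values, 2, max),
                          stringsAsFactors = FALSE, row.names = NULL)
  }
  stopifnot(identical(scaling$var, vars))
  rng <- scaling$max - scaling$min
  constant <- rng <= 0
  denom <- ifelse(constant, 1, rng)
  xs <- sweep(sweep(values, 2, scaling$min), 2, denom, "/")
  if (any(constant) && length(intersect(spec$classes, c("Q", "H", "T"))))
    warning("constant variable(s) ", paste(vars[constant], collapse = ", "),
            ": Q/H/T features dropped")

  cols <- list(); nms <- character(); fcl <- character(); fvars <- list()
  addCol <- function(v, nm, cl, vs) {
    cols[[length(cols) + 1L]] <<- v
    nms[length(nms) + 1L] <<- nm
    fcl[length(fcl) + 1L] <<- cl
    fvars[[length(fvars) + 1L]] <<- vs
  }
  for (cl in spec$classes) {
    if (cl == "L") {
      for (i in seq_along(vars))
        addCol(xs[, i], paste0("L_", vars[i]), "L", vars[i])
    } else if (cl == "Q") {
      for (i in seq_along(vars)) {
        if (constant[i]) next
        addCol(xs[, i]^2, paste0("Q_", vars[i]), "Q", vars[i])
      }
    } else if (cl == "P") {
      if (length(vars) >= 2)
        for (i in seq_len(length(vars) - 1L))
          for (j in (i + 1L):length(vars))
            addCol(xs[, i] * xs[, j],
                   paste0("P_", vars[i], ".", vars[j]), "P",
                   c(vars[i], vars[j]))
    } else if (cl == "H") {
      knots <- seq_len(spec$hingeKnots) / (spec$hingeKnots + 1)
      for (i in seq_along(vars)) {
        if (constant[i]) next
        for (k in knots)
          addCol(pmax(0, (xs[, i] - k) / (1 - k)),
                 sprintf("HF_%s_%.4f", vars[i], k), "H", vars[i])
        for (k in knots)
          addCol(pmax(0, (k - xs[, i]) / k),
                 sprintf("HR_%s_%.4f", vars[i], k), "H", vars[i])
      }
    } else if (cl == "T") {
      knots <- seq_len(spec$thresholdKnots) / (spec$thresholdKnots + 1)
      for (i in seq_along(vars)) {
        if (constant[i]) next
        for (k in knots)
          addCol(as.numeric(xs[, i] > k),
                 sprintf("T_%s_%.4f", vars[i], k), "T", vars[i])
      }
    }
  }
  fm <- matrix(unlist(cols), nrow = nrow(values),
               dimnames = list(NULL, nms))
  structure(list(values = fm, names = nms, class = fcl, vars = fvars,
                 scaling = scaling, spec = spec,
                 rawMeans = colMeans(values)),
            class = "FeatureMatrix")
}

#' @export
print.FeatureMatrix <- function(x, ...) {
  cat(sprintf("FeatureMatrix: %d sample(s) x %d feature(s) [%s]\n",
              nrow(x$values), length(x$names),
              paste(x$spec$classes, collapse = "")))
  invisible(x)
}

#' Default per-feature L1 penalty weights
#'
#' The published class- and sample-size-dependent schedules, linearly
#' interpolated in the number of presence samples `m` and clamped at the
#' table ends: linear/quadratic 1.0 (m <= 10) to 0.05 (m >= 100); hinge
#' 0.5 throughout; threshold 2.0 to 1.0; product 2.6 to 0.25. The
#' per-feature weight is `rm * schedule(m) * sd_bg(f_j) / sqrt(m)`.
#'
#' @param fm background [buildFeatures()] result (sd is taken over it).
#' @param m number of presence samples.
#' @param rm regularization multiplier.
#' @return named numeric vector of penalty weights, one per feature.
#' @export
defaultBetas <- function(fm, m, rm = 1) {
  schedule <- function(cl) {
    switch(cl,
      L = , Q = stats::approx(c(10, 30, 100), c(1.0, 0.2, 0.05), m,
                              rule = 2)$y,
      H = 0.5,
      T = stats::approx(c(10, 100), c(2.0, 1.0), m, rule = 2)$y,
      P = stats::approx(c(0, 10, 17, 30, 100), c(2.6, 1.6, 0.9, 0.55, 0.25),
                        m, rule = 2)$y)
  }
  sds <- apply(fm$values, 2, stats::sd)
  base <- vapply(fm$class, schedule, numeric(1))
  stats::setNames(rm * base * pmax(sds, 1e-6) / sqrt(m), fm$names)
}
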