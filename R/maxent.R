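#' Fitted maximum-entropy presence-background model
#'
#' The Gibbs model `q(x) = exp(sum_j lambda_j f_j(x) - log Z)` with Z
#' the partition function over the training background, fitted by
#' maximizing the L1-penalized mean presence log-density (see
#' [fitMaxent()]). Stores everything prediction and diagnostics need:
#' coefficients, penalties, the feature spec and scaling, log Z, the
#' entropy of the fitted background distribution, training ranges for
#' clamping, and the per-variable objective-improvement credits that
#' drive [percentContribution()].
#'
#' @slot spec the `FeatureSpec` (as a list).
#' @slot featureNames,lambda,betas per-feature names, coefficients and
#'   penalty weights.
#' @slot featureVars list: variable(s) underlying each feature.
#' @slot rm regularization multiplier.
#' @slot scaling per-variable background min/max (also the clamp
#'   ranges).
#' @slot logZ log partition function over the training background.
#' @slot entropy entropy of the fitted background distribution.
#' @slot bgMeans raw per-variable background means (response curves).
#' @slot nPresence,nBackground sample sizes.
#' @slot creditByVar named objective-improvement credit per variable.
#' @slot objective final penalized objective value.
#' @slot converged,iterations solver status.
#' @export
#' @exportClass MaxEntModel
setClass("MaxEntModel", representation(
  spec = "list", featureNames = "character", lambda = "numeric",
  betas = "numeric", featureVars = "list", rm = "numeric",
  scaling = "data.frame", logZ = "numeric", entropy = "numeric",
  bgMeans = "numeric", nPresence = "integer", nBackground = "integer",
  creditByVar = "numeric", objective = "numeric", converged = "logical",
  iterations = "integer"
))

setMethod("show", "MaxEntModel", function(object) {
  cat(sprintf("MaxEntModel: FC=%s, RM=%.2g; %d/%d features nonzero\n",
              paste(object@spec$classes, collapse = ""), object@rm,
              sum(object@lambda != 0), length(object@lambda)))
  cat(sprintf("  m=%d presences, N=%d background; logZ=%.4f, H=%.4f%s\n",
              object@nPresence, object@nBackground, object@logZ,
              object@entropy,
              if (object@converged) "" else "  [not converged]"))
})

logSumExp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Fit the penalized maximum-entropy model
#'
#' Maximizes the convex objective
#' `(1/m) sum_presence eta(x_i) - log Z(lambda) - sum_j beta_j |lambda_j|`
#' with `eta = sum_j lambda_j f_j` and
#' `Z = sum_background exp(eta(x))` — the penalized-likelihood form of
#' the presence-background maximum-entropy problem — by cyclic
#' coordinate descent: each coordinate takes a Newton step on the smooth
#' part, soft-thresholded by its penalty, with exact-objective
#' backtracking so ascent is guaranteed. Convergence is declared when
#' the largest KKT violation falls below `tol`. Deterministic given its
#' inputs; `seed` is reserved for optional background subsampling.
#'
#' @param presence,background `FeatureMatrix` objects sharing names and
#'   scaling (see [buildFeatures()]).
#' @param rm regularization multiplier (>= 0) scaling the default
#'   penalties.
#' @param betas optional explicit per-feature penalty weights
#'   (overrides [defaultBetas()]).
#' @param tol KKT gradient tolerance.
#' @param maxit maximum number of full coordinate sweeps.
#' @param nBackgroundMax if the background has more rows, a uniform
#'   subsample of this size is taken (seeded).
#' @param seed seed used only if background subsampling triggers.
#' @return a [MaxEntModel-class].
#' @export
fitMaxent <- function(presence, background, rm = 1, betas = NULL,
                      tol = 1e-6, maxit = 200, nBackgroundMax = 10000,
                      seed = 1) {
  stopifnot(inherits(presence, "FeatureMatrix"),
            inherits(background, "FeatureMatrix"),
            identical(presence$names, background$names))
  if (!isTRUE(all.equal(presence$scaling, background$scaling)))
    stop("presence and background must share feature scaling")
  if (nrow(presence$values) < 1) stop("no presence points")
  if (any(!is.finite(presence$values)) || any(!is.finite(background$values)))
    stop("non-finite feature values")
  Xb <- background$values
  if (nrow(Xb) > nBackgroundMax) {
    set.seed(as.integer(seed))
    Xb <- Xb[sample.int(nrow(Xb), nBackgroundMax), , drop = FALSE]
  }
  Xp <- presence$values
  m <- nrow(Xp); n <- nrow(Xb); J <- ncol(Xb)
  pbar <- colMeans(Xp)
  if (is.null(betas)) {
    bgfm <- background
    bgfm$values <- Xb
    betas <- defaultBetas(bgfm, m, rm)
  }
  stopifnot(length(betas) == J, all(betas >= 0))

  lambda <- numeric(J)
  eta <- numeric(n)
  # maintain w = exp(eta - etaShift) incrementally; one exp per update
  etaShift <- 0
  w <- rep(1, n)
  sumW <- n
  logZ <- log(n)
  obj <- -logZ            # lambda = 0: linear term 0, penalty 0
  credit <- numeric(0)
  addCredit <- function(vars, gain) {
    share <- gain / length(vars)
    for (v in vars) {
      if (is.null(credit[v]) || is.na(credit[v])) credit[v] <<- 0
      credit[v] <<- credit[v] + share
    }
  }
  renorm <- function() {
    mx <- max(eta)
    etaShift <<- mx
    w <<- exp(eta - mx)
    sumW <<- sum(w)
    logZ <<- etaShift + log(sumW)
  }

  updateCoord <- function(j) {
    xj <- Xb[, j]
    wx <- w * xj
    Ef <- sum(wx) / sumW
    g <- pbar[j] - Ef
    viol <- if (lambda[j] == 0) max(abs(g) - betas[j], 0)
            else abs(g - betas[j] * sign(lambda[j]))
    if (viol <= tol) return(viol)
    h <- max(sum(wx * xj) / sumW - Ef^2, 1e-12)
    z <- lambda[j] + g / h
    lnew <- sign(z) * max(abs(z) - betas[j] / h, 0)
    delta <- lnew - lambda[j]
    if (delta == 0) return(viol)
    ex <- exp(delta * xj)
    for (try in 1:30) {
      wNew <- w * ex
      sumWNew <- sum(wNew)
      if (!is.finite(sumWNew)) {         # overflow: shrink the step
        delta <- delta / 2
        ex <- sqrt(ex)
        next
      }
      logZNew <- etaShift + log(sumWNew)
      lcand <- lambda[j] + delta
      objNew <- obj +
        pbar[j] * delta - (logZNew - logZ) -
        betas[j] * (abs(lcand) - abs(lambda[j]))
      if (objNew >= obj - 1e-12) {
        if (objNew > obj) addCredit(background$vars[[j]], objNew - obj)
        lambda[j] <<- lcand
        eta <<- eta + delta * xj
        w <<- wNew
        sumW <<- sumWNew
        logZ <<- logZNew
        obj <<- objNew
        break
      }
      delta <- delta / 2
      ex <- sqrt(ex)
    }
    if (sumW < 1e-8 * n || sumW > 1e8 * n) renorm()
    viol
  }

  converged <- FALSE
  it <- 0L
  objPrev <- obj
  stalled <- 0L
  while (it < maxit) {
    it <- it + 1L
    maxViol <- 0
    for (j in seq_len(J))
      maxViol <- max(maxViol, updateCoord(j))
    if (maxViol <= tol) { converged <- TRUE; break }
    # iterate on the active set until it is internally converged, then
    # re-check the full KKT conditions (glmnet-style working set)
    polish <- 0L
    repeat {
      act <- which(lambda != 0)
      polish <- polish + 1L
      if (!length(act) || polish > 30L) break
      vAct <- 0
      for (j in act) vAct <- max(vAct, updateCoord(j))
      if (vAct <= tol) break
    }
    # stop when the objective has stopped moving (flat KKT plateau)
    if (obj - objPrev < 1e-8) stalled <- stalled + 1L else stalled <- 0L
    if (stalled >= 2L) { converged <- TRUE; break }
    objPrev <- obj
  }

  renorm()
  q <- exp(eta - logZ)
  entropy <- -sum(q * ifelse(q > 0, log(q), 0))
  cv <- numeric(length(presence$spec$variableNames))
  names(cv) <- presence$spec$variableNames
  if (length(credit)) cv[names(credit)] <- credit
  new("MaxEntModel",
      spec = unclass(presence$spec), featureNames = background$names,
      lambda = stats::setNames(lambda, background$names),
      betas = betas, featureVars = background$vars, rm = rm,
      scaling = background$scaling, logZ = logZ, entropy = entropy,
      bgMeans = background$rawMeans, nPresence = as.integer(m),
      nBackground = as.integer(n), creditByVar = cv, objective = obj,
      converged = converged, iterations = it)
}

# Feature matrix for new raw data under the model's spec and scaling,
# optionally clamped to the training ranges.
modelFeatures <- function(model, values, clamp = FALSE) {
  spec <- structure(model@spec, class = "FeatureSpec")
  vars <- spec$variableNames
  miss <- setdiff(vars, colnames(values))
  if (length(miss))
    stop("prediction data lacks variable(s): ", paste(miss, collapse = ", "))
  values <- values[, vars, drop = FALSE]
  if (clamp) {
    for (i in seq_along(vars))
      values[, i] <- pmin(pmax(values[, i], model@scaling$min[i]),
                          model@scaling$max[i])
  }
  buildFeatures(values, spec, scaling = model@scaling)
}

modelEta <- function(model, fm) as.numeric(fm$values %*% model@lambda)

#' Predict suitability from a fitted model
#'
#' Evaluates the model on new data in one of three output formats:
#' \itemize{
#'   \item `raw`: the Gibbs density renormalized over the prediction
#'     domain's valid cells (sums to 1);
#'   \item `logistic`: the standard 0-1 suitability index at prevalence
#'     0.5, `1/(1 + exp(-(eta - logZ + H)))` with `logZ` and entropy `H`
#'     fixed at their training-background values;
#'   \item `cumulative`: 100 times the fraction of domain raw mass at or
#'     below the cell's raw value.
#' }
#' With `clamp = TRUE`, each variable is truncated to its training range
#' before features are built (recommended when projecting onto future
#' scenario layers).
#'
#' @param model a [MaxEntModel-class].
#' @param newdata an [EnvStack-class] (predicts over its valid cells and
#'   returns a matrix layer) or a numeric matrix of raw predictor
#'   columns (returns a vector).
#' @param type `"logistic"`, `"raw"` or `"cumulative"`.
#' @param clamp truncate predictors to training ranges first.
#' @return matrix layer (stack input) or numeric vector (matrix input).
#' @export
predictMaxent <- function(model, newdata, type = c("logistic", "raw",
                                                   "cumulative"),
                          clamp = FALSE) {
  type <- match.arg(type)
  isStack <- is(newdata, "EnvStack")
  vals <- if (isStack) extractValues(newdata) else newdata
  fm <- modelFeatures(model, vals, clamp = clamp)
  eta <- modelEta(model, fm)
  out <- switch(type,
    raw = {
      w <- exp(eta - max(eta))
      w / sum(w)
    },
    logistic = stats::plogis(eta - model@logZ + model@entropy),
    cumulative = {
      w <- exp(eta - max(eta))
      p <- w / sum(w)
      ord <- order(eta)
      cum <- cumsum(p[ord])
      # ties share the highest cumulative value of their group
      cumTie <- stats::ave(cum, eta[ord], FUN = max)
      res <- numeric(length(eta))
      res[ord] <- 100 * cumTie
      res
    })
  if (!isStack) return(out)
  layer <- matrix(NA_real_, nRows(gridDef(newdata)), nCols(gridDef(newdata)))
  cells <- attr(vals, "cells")
  layer[cbind(cells$row, cells$col)] <- out
  layer
}

#' @describeIn predictMaxent standard S4 `predict` interface.
#' @param object a [MaxEntModel-class].
#' @param ... passed to `predictMaxent`.
#' @export
setMethod("predict", "MaxEntModel", function(object, ...)
  predictMaxent(object, ...))

#' Regularized training gain
#'
#' `gain = (1/m) sum log q(x_i) + log N - penalty`: the improvement of
#' the (penalized) mean presence log-probability over the uniform
#' background model, which has gain exactly 0.
#'
#' @param model a [MaxEntModel-class].
#' @param presence the presence `FeatureMatrix` the model was trained
#'   on (same scaling).
#' @param regularized subtract the L1 penalty term (the convention of
#'   jackknife gain plots); `FALSE` gives the unpenalized gain.
#' @return numeric scalar.
#' @export
trainingGain <- function(model, presence, regularized = TRUE) {
  eta <- modelEta(model, presence)
  g <- mean(eta) - model@logZ + log(model@nBackground)
  if (regularized) g <- g - sum(model@betas * abs(model@lambda))
  g
}
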