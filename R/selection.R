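#' Presence partitions for evaluation
#'
#' Fold assignments for cross-validated tuning: `random_kfold` assigns
#' every presence to one of `k` folds at random; `subsample_75_25`
#' draws `k` independent random 75/25 train/test splits (the replicate
#' scheme of the final model).
#'
#' @param m number of presence points.
#' @param scheme `"random_kfold"` or `"subsample_75_25"`.
#' @param k folds / replicates.
#' @param seed integer seed.
#' @param split training fraction for the subsample scheme.
#' @return list of class `Partition`: `scheme`, `k`, and either
#'   `assignments` (fold label per presence) or `trainSets` (list of
#'   training index vectors).
#' @export
makePartition <- function(m, scheme = c("random_kfold", "subsample_75_25"),
                          k = 5, seed = 1, split = 0.75) {
  scheme <- match.arg(scheme)
  if (k > m) stop("more folds than presences")
  set.seed(as.integer(seed))
  out <- list(scheme = scheme, k = k, seed = seed)
  if (scheme == "random_kfold") {
    out$assignments <- sample(rep_len(seq_len(k), m))
  } else {
    nTrain <- max(1L, round(split * m))
    if (nTrain >= m) nTrain <- m - 1L
    out$trainSets <- lapply(seq_len(k), function(i) sort(sample.int(m, nTrain)))
  }
  structure(out, class = "Partition")
}

#' Small-sample-corrected AIC of a fitted model
#'
#' `AICc = 2k - 2L + 2k(k+1)/(m-k-1)` with `L` the sum of presence
#' log-densities `log q(x_i)` (raw output normalized over the training
#' background) and `k` the number of nonzero coefficients. Undefined
#' (`NA`) when `m - k - 1 <= 0`.
#'
#' @param model a [MaxEntModel-class].
#' @param presence the presence `FeatureMatrix`.
#' @param landscape optional feature matrix (samples x features) over
#'   which the raw output is normalized instead of the training
#'   background — pass the cells of the full study landscape (or the
#'   union of background and presence rows) for the convention that
#'   bounds presence densities by 1.
#' @return numeric, or `NA` when undefined.
#' @export
aiccMaxent <- function(model, presence, landscape = NULL) {
  m <- nrow(presence$values)
  k <- sum(model@lambda != 0)
  if (m - k - 1 <= 0) return(NA_real_)
  logZ <- if (is.null(landscape)) model@logZ
          else logSumExp(as.numeric(landscape %*% model@lambda))
  L <- sum(modelEta(model, presence) - logZ)
  2 * k - 2 * L + 2 * k * (k + 1) / (m - k - 1)
}

#' 10-percentile training omission rate
#'
#' Threshold = the `ceiling(0.1 * n_train)`-th smallest training
#' presence score; the rate is the fraction of test scores strictly
#' below that threshold.
#'
#' @param trainScores,testScores numeric presence scores.
#' @return omission rate in `[0, 1]`, `NA` if the test set is empty.
#' @export
or10 <- function(trainScores, testScores) {
  stopifnot(length(trainScores) > 0)
  if (!length(testScores)) return(NA_real_)
  thr <- sort(trainScores)[ceiling(0.1 * length(trainScores))]
  mean(testScores < thr)
}

#' Rank-based AUC and ROC curve
#'
#' `aucScore` is the Mann-Whitney estimator with half credit for ties
#' (average ranks), equivalent to exhaustive pair counting; identical
#' scores give 0.5. `rocCurve` sweeps all score thresholds and returns
#' the (FPR, TPR) points.
#'
#' @param posScores,negScores scores of the positive (presence) and
#'   negative (background) class.
#' @return `aucScore`: numeric in `[0, 1]`; `rocCurve`: data.frame
#'   `threshold`, `fpr`, `tpr`.
#' @export
aucScore <- function(posScores, negScores) {
  stopifnot(length(posScores) > 0, length(negScores) > 0)
  np <- length(posScores); nn <- length(negScores)
  r <- rank(c(posScores, negScores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' @rdname aucScore
#' @export
rocCurve <- function(posScores, negScores) {
  thr <- c(Inf, sort(unique(c(posScores, negScores)), decreasing = TRUE))
  data.frame(
    threshold = thr,
    fpr = vapply(thr, function(t) mean(negScores >= t), numeric(1)),
    tpr = vapply(thr, function(t) mean(posScores >= t), numeric(1)))
}

#' Accuracy class of an AUC value
#'
#' The conventional five-band reading of a presence-background AUC:
#' 0.5-0.6 no better than random, 0.6-0.7 low reliability, 0.7-0.8
#' effective discrimination, 0.8-0.9 high prediction accuracy, 0.9-1.0
#' excellent.
#'
#' @param auc numeric AUC.
#' @return character label.
#' @export
aucAccuracyClass <- function(auc) {
  stopifnot(auc >= 0, auc <= 1)
  labels <- c("ineffective", "low reliability", "effective",
              "high prediction accuracy", "excellent")
  if (auc < 0.5) return(labels[1])
  labels[min(findInterval(auc, c(0.5, 0.6, 0.7, 0.8, 0.9)), 5)]
}

candidateGrid <- function(fcGrid, rmGrid)
  expand.grid(fc = fcGrid, rm = rmGrid, stringsAsFactors = FALSE)

#' Tune the RM x FC grid
#'
#' ENMeval-style model selection. For every candidate (feature
#' combination, regularization multiplier): a full-data fit yields AICc
#' (likelihood normalized over the union of background and presence
#' rows, the study-landscape convention) and the nonzero-coefficient
#' count; cross-validated fits under the
#' partition yield the mean 10-percentile omission rate (OR10) and the
#' mean train-minus-test AUC (AUC.diff, background cells as negatives).
#' `delta_aicc = AICc - min(AICc)` over candidates with defined AICc.
#' The selected best candidate minimizes Delta.AICc, with ties broken by
#' lower OR10, then lower AUC.diff, then fewer parameters.
#'
#' @param presValues,bgValues raw predictor matrices (samples x
#'   variables, shared column names).
#' @param fcGrid character vector of feature combinations; default the
#'   standard nine.
#' @param rmGrid numeric multipliers; default 0.5 to 4.0 by 0.5.
#' @param partition a [makePartition()] result (default: 5-fold random
#'   k-fold under `seed`).
#' @param seed seed for the default partition.
#' @param hingeKnots,thresholdKnots knots per variable.
#' @param ... passed to [fitMaxent()].
#' @return list of class `TuningResult`: `results` (one row per
#'   candidate: `fc`, `rm`, `aicc`, `delta_aicc`, `or10`, `auc_diff`,
#'   `auc_train`, `n_params`) and `best` (the selected row).
#' @export
tuneMaxent <- function(presValues, bgValues,
                       fcGrid = c("L", "H", "LQ", "LQH", "LQHP", "LQHPT",
                                  "QHP", "QHPT", "HPT"),
                       rmGrid = seq(0.5, 4, by = 0.5),
                       partition = NULL, seed = 1,
                       hingeKnots = 10, thresholdKnots = 10, ...) {
  stopifnot(length(fcGrid) > 0, length(rmGrid) > 0)
  m <- nrow(presValues)
  if (is.null(partition))
    partition <- makePartition(m, "random_kfold", k = min(5, m), seed = seed)
  trainSets <- if (partition$scheme == "random_kfold") {
    lapply(seq_len(partition$k), function(f) which(partition$assignments != f))
  } else partition$trainSets
  cand <- candidateGrid(fcGrid, rmGrid)
  vars <- colnames(bgValues)
  rows <- lapply(seq_len(nrow(cand)), function(ci) {
    fc <- cand$fc[ci]; rm <- cand$rm[ci]
    spec <- featureSpec(fc, vars, hingeKnots, thresholdKnots)
    bgFM <- buildFeatures(bgValues, spec)
    clampP <- function(pv) {
      for (i in seq_along(vars))
        pv[, i] <- pmin(pmax(pv[, i], bgFM$scaling$min[i]),
                        bgFM$scaling$max[i])
      pv
    }
    presFM <- buildFeatures(clampP(presValues), spec, scaling = bgFM$scaling)
    full <- fitMaxent(presFM, bgFM, rm = rm, ...)
    land <- rbind(bgFM$values, presFM$values)
    ors <- numeric(0); dAuc <- numeric(0); trAuc <- numeric(0)
    for (tr in trainSets) {
      te <- setdiff(seq_len(m), tr)
      if (!length(te)) next
      pf <- presFM; pf$values <- presFM$values[tr, , drop = FALSE]
      fitCv <- fitMaxent(pf, bgFM, rm = rm, ...)
      sTrain <- modelEta(fitCv, presFM)[tr]
      sTest <- modelEta(fitCv, presFM)[te]
      sBg <- as.numeric(bgFM$values %*% fitCv@lambda)
      ors <- c(ors, or10(sTrain, sTest))
      a1 <- aucScore(sTrain, sBg); a2 <- aucScore(sTest, sBg)
      trAuc <- c(trAuc, a1)
      dAuc <- c(dAuc, a1 - a2)
    }
    data.frame(fc = fc, rm = rm, aicc = aiccMaxent(full, presFM, land),
               or10 = mean(ors), auc_diff = mean(dAuc),
               auc_train = mean(trAuc),
               n_params = sum(full@lambda != 0),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  ok <- !is.na(res$aicc)
  res$delta_aicc <- NA_real_
  if (any(ok)) res$delta_aicc[ok] <- res$aicc[ok] - min(res$aicc[ok])
  res <- res[c("fc", "rm", "aicc", "delta_aicc", "or10", "auc_diff",
               "auc_train", "n_params")]
  pool <- res[!is.na(res$delta_aicc), , drop = FALSE]
  if (!nrow(pool)) stop("AICc undefined for every candidate")
  best <- pool[order(pool$delta_aicc, pool$or10, pool$auc_diff,
                     pool$n_params), ][1, ]
  structure(list(results = res, best = best, partition = partition),
            class = "TuningResult")
}

#' @export
print.TuningResult <- function(x, ...) {
  cat(sprintf("TuningResult: %d candidate(s); best FC=%s RM=%.2g (Delta.AICc=%.3f, OR10=%.3f, AUC.diff=%.3f)\n",
              nrow(x$results), x$best$fc, x$best$rm, x$best$delta_aicc,
              x$best$or10, x$best$auc_diff))
  invisible(x)
}

#' Replicated train/test runs and averaged prediction
#'
#' The final-model protocol: `nRep` random 75/25 presence splits; per
#' replicate a fit on the training share, train/test AUC against the
#' background, and a logistic prediction over the stack; the reported
#' suitability layer is the cell-wise mean of the replicate layers.
#'
#' @param stack an [EnvStack-class] (training domain).
#' @param occ a thinned [OccurrenceSet-class].
#' @param fc,rm final feature combination and multiplier.
#' @param nRep number of replicates (default 10).
#' @param split training fraction (default 0.75).
#' @param seed integer seed (controls splits and background).
#' @param nBackground background cap.
#' @param hingeKnots,thresholdKnots knots per variable.
#' @param variables predictor subset (default all layers).
#' @param ... passed to [fitMaxent()].
#' @return list of class `ReplicateRuns`: `meanLayer` (matrix),
#'   `aucs` (per-replicate train/test AUC data.frame), `aucTrainMean`,
#'   `aucTrainSd`, `accuracyClass`, `models`.
#' @export
replicateRuns <- function(stack, occ, fc, rm, nRep = 10, split = 0.75,
                          seed = 1, nBackground = 10000, hingeKnots = 10,
                          thresholdKnots = 10, variables = NULL, ...) {
  stopifnot(nRep >= 1)
  if (is.null(variables)) variables <- layerNames(stack)
  base <- fitOnStack(stack, occ, fc = fc, rm = rm,
                     nBackground = nBackground, seed = seed,
                     hingeKnots = hingeKnots,
                     thresholdKnots = thresholdKnots,
                     variables = variables, ...)
  presFM <- base$presence; bgFM <- base$background
  m <- nrow(presFM$values)
  part <- makePartition(m, "subsample_75_25", k = nRep, seed = seed,
                        split = split)
  layers <- vector("list", nRep)
  aucs <- data.frame(rep = seq_len(nRep), aucTrain = NA_real_,
                     aucTest = NA_real_)
  models <- vector("list", nRep)
  for (i in seq_len(nRep)) {
    tr <- part$trainSets[[i]]
    te <- setdiff(seq_len(m), tr)
    pf <- presFM; pf$values <- presFM$values[tr, , drop = FALSE]
    fit <- fitMaxent(pf, bgFM, rm = rm, ...)
    sBg <- as.numeric(bgFM$values %*% fit@lambda)
    etaAll <- modelEta(fit, presFM)
    aucs$aucTrain[i] <- aucScore(etaAll[tr], sBg)
    aucs$aucTest[i] <- if (length(te)) aucScore(etaAll[te], sBg) else NA_real_
    layers[[i]] <- predictMaxent(fit, stack, type = "logistic")
    models[[i]] <- fit
  }
  meanLayer <- Reduce(`+`, layers) / nRep
  mu <- mean(aucs$aucTrain)
  structure(list(meanLayer = meanLayer, aucs = aucs,
                 aucTrainMean = mu,
                 aucTrainSd = stats::sd(aucs$aucTrain),
                 accuracyClass = aucAccuracyClass(mu),
                 models = models, background = bgFM, presence = presFM),
            class = "ReplicateRuns")
}

#' @export
print.ReplicateRuns <- function(x, ...) {
  cat(sprintf("ReplicateRuns: %d replicate(s); train AUC %.3f +/- %.3f (%s)\n",
              nrow(x$aucs), x$aucTrainMean,
              if (is.na(x$aucTrainSd)) 0 else x$aucTrainSd,
              x$accuracyClass))
  invisible(x)
}
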