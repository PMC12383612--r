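#' Spearman correlation matrix of predictor layers
#'
#' Rank correlation (average-rank tie handling, as in
#' `cor(method = "spearman")`) between all pairs of layers, computed on
#' the layer values at occurrence cells (the default, the presence-side
#' convention) or over all valid cells.
#'
#' @param stack an [EnvStack-class].
#' @param occ optional [OccurrenceSet-class]; when `NULL` all valid
#'   cells are used.
#' @return symmetric correlation matrix with unit diagonal. Pairs
#'   involving a constant layer are `NA` (undefined rank correlation).
#' @export
spearmanMatrix <- function(stack, occ = NULL) {
  if (is.null(occ)) {
    vals <- extractValues(stack)
  } else {
    asg <- assignCells(occ, gridDef(stack))
    asg <- asg[asg$inside, , drop = FALSE]
    vals <- extractValues(stack, asg[c("row", "col")])
  }
  if (nrow(vals) < 3) stop("need at least 3 sample points")
  suppressWarnings(m <- stats::cor(vals, method = "spearman",
                                   use = "pairwise.complete.obs"))
  diag(m) <- 1
  m
}

#' Prune collinear predictors by contribution
#'
#' Iterative greedy reduction: while any retained pair has `|r|`
#' strictly greater than `threshold`, take the pair with the largest
#' `|r|` (ties broken by lexicographic pair-name order) and drop the
#' member with the lower model contribution (contribution ties drop the
#' lexicographically later name). Undefined correlations (constant
#' layers) are treated as `|r| = 0`.
#'
#' @param corr symmetric correlation matrix with dimnames.
#' @param contributions named percentages (one per candidate), e.g. from
#'   [percentContribution()] of a preliminary all-variable model.
#' @param threshold pruning threshold on `|r|` (default 0.75).
#' @return list of class `ScreeningResult`: `correlation`,
#'   `contributions`, `retained` (names), `dropped` (data.frame with
#'   `name`, `partner`, `r`, `reason`), `threshold`.
#' @export
pruneCollinear <- function(corr, contributions, threshold = 0.75) {
  vars <- colnames(corr)
  stopifnot(!is.null(vars), all(vars %in% names(contributions)))
  a <- abs(corr)
  a[is.na(a)] <- 0
  diag(a) <- 0
  retained <- sort(vars)
  dropped <- data.frame(name = character(), partner = character(),
                        r = numeric(), reason = character(),
                        stringsAsFactors = FALSE)
  repeat {
    sub <- a[retained, retained, drop = FALSE]
    if (max(sub) <= threshold) break
    hits <- which(sub == max(sub), arr.ind = TRUE)
    pairs <- t(apply(hits, 1, function(ij)
      sort(retained[ij])))
    pairs <- unique(pairs)
    ord <- order(pairs[, 1], pairs[, 2])
    v1 <- pairs[ord[1], 1]; v2 <- pairs[ord[1], 2]
    c1 <- contributions[[v1]]; c2 <- contributions[[v2]]
    loser <- if (c1 < c2) v1 else if (c2 < c1) v2 else max(v1, v2)
    winner <- setdiff(c(v1, v2), loser)
    dropped <- rbind(dropped, data.frame(
      name = loser, partner = winner, r = corr[v1, v2],
      reason = sprintf("|r|=%.3f>%.2f with %s, lower contribution (%.3g vs %.3g)",
                       abs(corr[v1, v2]), threshold, winner,
                       contributions[[loser]], contributions[[winner]]),
      stringsAsFactors = FALSE))
    retained <- setdiff(retained, loser)
  }
  structure(list(correlation = corr, contributions = contributions,
                 retained = retained, dropped = dropped,
                 threshold = threshold),
            class = "ScreeningResult")
}

#' @export
print.ScreeningResult <- function(x, ...) {
  cat(sprintf("ScreeningResult: %d retained / %d dropped (|r| > %.2f)\n",
              length(x$retained), nrow(x$dropped), x$threshold))
  cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  if (nrow(x$dropped)) {
    cat("  dropped:\n")
    for (i in seq_len(nrow(x$dropped)))
      cat("   -", x$dropped$name[i], "—", x$dropped$reason[i], "\n")
  }
  invisible(x)
}

#' Full predictor screening stage
#'
#' Computes the Spearman matrix at occurrence cells, obtains per-variable
#' contributions from a preliminary maximum-entropy fit on all candidate
#' layers (default features LQH, RM 1), and prunes collinear pairs.
#'
#' @param stack an [EnvStack-class].
#' @param occ a thinned [OccurrenceSet-class].
#' @param threshold pruning threshold on `|r|`.
#' @param nBackground background sample size for the preliminary fit.
#' @param seed seed for background sampling.
#' @param fc feature classes of the preliminary fit.
#' @param rm regularization multiplier of the preliminary fit.
#' @param hingeKnots hinge knots per variable per direction.
#' @return a `ScreeningResult` (see [pruneCollinear()]).
#' @export
screenPredictors <- function(stack, occ, threshold = 0.75,
                             nBackground = 10000, seed = 1,
                             fc = "LQH", rm = 1, hingeKnots = 10) {
  corr <- spearmanMatrix(stack, occ)
  fitd <- fitOnStack(stack, occ, fc = fc, rm = rm,
                     nBackground = nBackground, seed = seed,
                     hingeKnots = hingeKnots)
  contrib <- percentContribution(fitd$model)
  cvec <- stats::setNames(contrib$contribution, contrib$variable)
  missing <- setdiff(layerNames(stack), names(cvec))
  cvec[missing] <- 0
  pruneCollinear(corr, cvec, threshold)
}
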