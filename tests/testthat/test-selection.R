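test_that("AICc matches its closed form and boundary behaviour", {
  # uniform model (k = 0), m = 10 presences, N = 100 background
  bgv <- matrix(runif(100), ncol = 1, dimnames = list(NULL, "v"))
  prv <- matrix(runif(10), ncol = 1, dimnames = list(NULL, "v"))
  p <- fmPair(prv, bgv)
  fit <- fitMaxent(p$pres, p$bg, rm = 1e9)   # forces all-zero lambda
  expect_equal(sum(fit@lambda != 0), 0L)
  expect_equal(aiccMaxent(fit, p$pres), -2 * 10 * log(1 / 100),
               tolerance = 1e-12)
  expect_equal(aiccMaxent(fit, p$pres), 92.10340, tolerance = 1e-6)
  # independent evaluation of the formula on a nontrivial model
  fit2 <- fitMaxent(p$pres, p$bg, betas = 0.001)
  k <- sum(fit2@lambda != 0); m <- 10
  L <- sum(p$pres$values %*% fit2@lambda - fit2@logZ)
  expect_equal(aiccMaxent(fit2, p$pres),
               2 * k - 2 * L + 2 * k * (k + 1) / (m - k - 1))
  # m = 5, k = 4: denominator zero -> undefined marker
  prv5 <- matrix(runif(5), ncol = 1, dimnames = list(NULL, "v"))
  p5 <- fmPair(prv5, bgv, classes = "LQH")
  f5 <- fitMaxent(p5$pres, p5$bg, betas = rep(1e-9, ncol(p5$bg$values)))
  expect_gte(sum(f5@lambda != 0), 4)
  expect_true(is.na(aiccMaxent(f5, p5$pres)))
})

test_that("OR10 uses the ceiling rank threshold and strict omission", {
  # all test scores above all training scores -> 0
  expect_equal(or10(1:10, 11:20), 0)
  # test identical to train, n = 10: threshold met, not strictly below
  expect_equal(or10(1:10, 1:10), 0.0)
  # random scores: equals a direct count
  set.seed(31)
  for (i in 1:20) {
    tr <- runif(sample(5:40, 1)); te <- runif(sample(3:30, 1))
    thr <- sort(tr)[ceiling(0.1 * length(tr))]
    expect_equal(or10(tr, te), sum(te < thr) / length(te))
  }
  expect_true(is.na(or10(1:5, numeric(0))))
  # on the training set itself: about 0.10 within one rank step
  tr <- runif(100)
  expect_lt(abs(or10(tr, tr) - 0.10), 1 / 100 + 1e-12)
})

test_that("AUC is the Mann-Whitney estimator with tie half-credit", {
  # perfectly separated
  expect_equal(aucScore(6:10, 1:5), 1)
  expect_equal(aucScore(1:5, 6:10), 0)
  # all identical scores -> 0.5
  expect_equal(aucScore(rep(1, 5), rep(1, 7)), 0.5)
  # exhaustive pair-counting oracle with ties
  set.seed(17)
  for (i in 1:20) {
    pos <- sample(1:8, 5, replace = TRUE)
    neg <- sample(1:8, 5, replace = TRUE)
    pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(aucScore(pos, neg), mean(pairs))
  }
  # invariance under strictly monotone transforms
  pos <- rnorm(30); neg <- rnorm(40, -0.5)
  expect_equal(aucScore(pos, neg), aucScore(exp(pos), exp(neg)))
  expect_equal(aucScore(pos, neg), aucScore(qlogis(plogis(pos)),
                                            qlogis(plogis(neg))))
  # labels independent of scores: near 0.5 at large n
  set.seed(55)
  sc <- rnorm(20000)
  expect_lt(abs(aucScore(sc[1:10000], sc[10001:20000]) - 0.5), 0.02)
  # ROC endpoints
  roc <- rocCurve(pos, neg)
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
})

test_that("AUC accuracy bands follow the five-level convention", {
  expect_equal(aucAccuracyClass(0.55), "ineffective")
  expect_equal(aucAccuracyClass(0.65), "low reliability")
  expect_equal(aucAccuracyClass(0.75), "effective")
  expect_equal(aucAccuracyClass(0.856), "high prediction accuracy")
  expect_equal(aucAccuracyClass(0.95), "excellent")
})

test_that("tuning computes Delta.AICc relative to the grid minimum with stated tie-breaks", {
  s <- smallStack(seed = 16)
  tr <- makeTruth(s, c(temp = 3.5, precip = -2))
  occ <- thinOccurrences(sampleOccurrences(tr, 60, seed = 3), gridDef(s))
  bgv <- extractValues(s, sampleBackground(s, 400, seed = 4))
  asg <- assignCells(occ, gridDef(s))
  pv <- extractValues(s, asg[c("row", "col")])

  # single-candidate grid: its delta is 0
  t1 <- tuneMaxent(pv, bgv, fcGrid = "L", rmGrid = 1, seed = 9)
  expect_equal(t1$results$delta_aicc, 0)

  t2 <- tuneMaxent(pv, bgv, fcGrid = c("L", "LQ", "LQH"),
                   rmGrid = c(1, 4), seed = 9)
  expect_equal(min(t2$results$delta_aicc, na.rm = TRUE), 0)
  expect_equal(t2$best$delta_aicc, 0)
  # best row equals argmin under the tie-break chain
  ord <- with(t2$results[!is.na(t2$results$delta_aicc), ],
              order(delta_aicc, or10, auc_diff, n_params))
  expect_equal(t2$best$fc,
               t2$results[!is.na(t2$results$delta_aicc), ][ord[1], "fc"])
  # determinism under the same seed/partition
  t3 <- tuneMaxent(pv, bgv, fcGrid = c("L", "LQ", "LQH"),
                   rmGrid = c(1, 4), seed = 9)
  expect_identical(t2$results, t3$results)
})

test_that("a smoothness-favoring fixture selects the simpler, stronger-penalty candidate", {
  # presences drawn from a smooth linear-Gibbs truth: heavily
  # parameterized low-penalty candidates overfit and lose on AICc
  s <- smallStack(seed = 26)
  tr <- makeTruth(s, c(temp = 3, precip = 2))
  occ <- thinOccurrences(sampleOccurrences(tr, 55, seed = 6), gridDef(s))
  bgv <- extractValues(s, sampleBackground(s, 400, seed = 7))
  asg <- assignCells(occ, gridDef(s))
  pv <- extractValues(s, asg[c("row", "col")])
  tt <- tuneMaxent(pv, bgv, fcGrid = c("LQH", "LQHP"), rmGrid = c(1, 4),
                   seed = 10)
  res <- tt$results
  dOpt <- res$delta_aicc[res$fc == "LQH" & res$rm == 4]
  dDef <- res$delta_aicc[res$fc == "LQHP" & res$rm == 1]
  expect_lt(dOpt, dDef)   # the optimized cell beats the default cell
  expect_equal(min(res$delta_aicc), 0)
})

test_that("replicated runs average prediction layers and report AUC bands", {
  s <- smallStack(seed = 20)
  tr <- makeTruth(s, c(temp = 4, precip = -2.5))
  occ <- thinOccurrences(sampleOccurrences(tr, 80, seed = 2), gridDef(s))
  r1 <- replicateRuns(s, occ, fc = "LQ", rm = 1, nRep = 1, seed = 3,
                      nBackground = 400)
  # single replicate: mean layer equals that run's prediction
  lay1 <- predictMaxent(r1$models[[1]], s, type = "logistic")
  expect_equal(r1$meanLayer, lay1)
  r <- replicateRuns(s, occ, fc = "LQ", rm = 1, nRep = 5, seed = 3,
                     nBackground = 400)
  expect_true(all(r$meanLayer >= 0 & r$meanLayer <= 1, na.rm = TRUE))
  expect_equal(nrow(r$aucs), 5)
  # the label matches the band the mean train AUC falls in
  expect_equal(r$accuracyClass, aucAccuracyClass(r$aucTrainMean))
  # determinism
  r2 <- replicateRuns(s, occ, fc = "LQ", rm = 1, nRep = 5, seed = 3,
                      nBackground = 400)
  expect_identical(r$meanLayer, r2$meanLayer)
  expect_identical(r$aucs, r2$aucs)
})
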