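test_that("total shrinkage limit: huge RM gives the uniform model", {
  set.seed(3)
  bg <- matrix(runif(200), ncol = 2, dimnames = list(NULL, c("a", "b")))
  pr <- matrix(runif(40, 0.4, 1), ncol = 2, dimnames = list(NULL, c("a", "b")))
  p <- fmPair(pr, bg, classes = "LQH")
  fit <- fitMaxent(p$pres, p$bg, rm = 1e6)
  expect_true(all(fit@lambda == 0))
  expect_equal(trainingGain(fit, p$pres), 0)
  expect_equal(fit@entropy, log(fit@nBackground))
  # raw output is uniform, logistic constant 0.5
  expect_equal(unique(round(predictMaxent(fit, bg, "logistic"), 12)), 0.5)
  raw <- predictMaxent(fit, bg, "raw")
  expect_equal(raw, rep(1 / 100, 100))
})

test_that("1- and 2-feature fits match dense grid search of the objective", {
  # one binary feature, presence mean 0.8, background half 1
  bgv <- matrix(c(rep(0, 50), rep(1, 50)), ncol = 1,
                dimnames = list(NULL, "v"))
  prv <- matrix(c(rep(1, 16), rep(0, 4)), ncol = 1,
                dimnames = list(NULL, "v"))
  p <- fmPair(prv, bgv)
  for (beta in c(0.01, 0.1)) {
    fit <- fitMaxent(p$pres, p$bg, betas = beta)
    grid <- seq(-2, 6, by = 1e-4)
    objs <- vapply(grid, function(l) oracleObjective(l, p$pres, p$bg, beta),
                   numeric(1))
    expect_equal(unname(fit@lambda), grid[which.max(objs)], tolerance = 2e-3)
    # fitted objective at least the grid optimum (up to grid resolution)
    expect_gte(oracleObjective(unname(fit@lambda), p$pres, p$bg, beta),
               max(objs) - 1e-6)
  }
  # two continuous features against a 2-D grid oracle
  set.seed(14)
  bg2 <- matrix(runif(300), ncol = 2, dimnames = list(NULL, c("a", "b")))
  pr2 <- cbind(a = rbeta(30, 4, 2), b = rbeta(30, 2, 4))
  p2 <- fmPair(pr2, bg2)
  fit2 <- fitMaxent(p2$pres, p2$bg, betas = c(0.02, 0.02))
  # coarse-to-fine dense grid search
  coarse <- expand.grid(l1 = seq(-6, 6, 0.1), l2 = seq(-6, 6, 0.1))
  co <- apply(coarse, 1, function(l)
    oracleObjective(c(l[1], l[2]), p2$pres, p2$bg, c(0.02, 0.02)))
  c0 <- as.numeric(coarse[which.max(co), ])
  fine <- expand.grid(l1 = seq(c0[1] - 0.15, c0[1] + 0.15, 0.002),
                      l2 = seq(c0[2] - 0.15, c0[2] + 0.15, 0.002))
  fo <- apply(fine, 1, function(l)
    oracleObjective(c(l[1], l[2]), p2$pres, p2$bg, c(0.02, 0.02)))
  f0 <- as.numeric(fine[which.max(fo), ])
  expect_equal(unname(fit2@lambda), f0, tolerance = 5e-3)
  expect_gte(oracleObjective(unname(fit2@lambda), p2$pres, p2$bg,
                             c(0.02, 0.02)), max(fo) - 1e-8)
})

test_that("raw output sums to 1 over the training background and RM increases sparsity", {
  s <- smallStack(seed = 6)
  tr <- makeTruth(s, c(temp = 3, precip = -2))
  occ <- sampleOccurrences(tr, 200, seed = 2)
  fLow <- fitOnStack(s, occ, fc = "LQH", rm = 0.5, nBackground = 500,
                     seed = 3)
  fHigh <- fitOnStack(s, occ, fc = "LQH", rm = 4, nBackground = 500,
                      seed = 3)
  # normalization invariant over the training background
  rawBg <- predictMaxent(fLow$model, extractValues(s, fLow$bgCells), "raw")
  expect_equal(sum(rawBg), 1, tolerance = 1e-8)
  etaBg <- as.numeric(fLow$background$values %*% fLow$model@lambda)
  expect_equal(sum(exp(etaBg - fLow$model@logZ)), 1, tolerance = 1e-8)
  # sparsity is monotone in RM on this fixture
  expect_lte(sum(fHigh$model@lambda != 0), sum(fLow$model@lambda != 0))
  # penalized optimum non-increasing in RM
  expect_lte(fHigh$model@objective, fLow$model@objective + 1e-10)
})

test_that("parameter recovery: fitted suitability correlates with a known Gibbs truth", {
  s <- smallStack(seed = 10)
  tr <- makeTruth(s, c(temp = 2.5, precip = -1.5))
  occ <- sampleOccurrences(tr, 5000, seed = 4)
  f <- fitOnStack(s, occ, fc = "L", rm = 0.01, nBackground = 1200, seed = 5)
  raw <- predictMaxent(f$model, s, type = "raw")
  m <- validMask(s)
  expect_gt(cor(raw[m], truthSuitability(tr)[m]), 0.95)
})

test_that("prediction formats obey their identities on a 3x3 toy", {
  g <- GridDef(3, 3, 0, 0, 1)
  lay <- matrix(seq(0, 1, length.out = 9), 3)
  st <- EnvStack(g, list(v = lay))
  bgv <- matrix(as.vector(lay), ncol = 1, dimnames = list(NULL, "v"))
  prv <- matrix(c(0.75, 1), ncol = 1, dimnames = list(NULL, "v"))
  p <- fmPair(prv, bgv)
  fit <- fitMaxent(p$pres, p$bg, betas = 0.05)
  lam <- unname(fit@lambda)
  # hand computation through q, Z, H
  eta <- as.vector(lay) * lam            # scaled v equals v here
  Z <- sum(exp(eta))
  q <- exp(eta) / Z
  H <- -sum(q * log(q))
  expect_equal(fit@logZ, log(Z), tolerance = 1e-10)
  expect_equal(fit@entropy, H, tolerance = 1e-10)
  logi <- predictMaxent(fit, st, type = "logistic")
  expect_equal(as.vector(logi), q * exp(H) / (1 + q * exp(H)),
               tolerance = 1e-10)
  expect_true(all(logi >= 0 & logi <= 1))
  # cumulative: percentile of raw mass at or below the cell's raw value
  cum <- predictMaxent(fit, st, type = "cumulative")
  ord <- order(eta)
  expect_equal(sort(as.vector(cum)), 100 * cumsum(q[ord]), tolerance = 1e-9)
  expect_equal(max(cum), 100)
  # clamping truncates beyond-training values
  st2 <- EnvStack(g, list(v = lay * 3))
  lc <- predictMaxent(fit, st2, type = "logistic", clamp = TRUE)
  expect_lte(max(lc), max(logi) + 1e-12)
  # missing variable errors by name
  expect_error(predictMaxent(fit, EnvStack(g, list(w = lay))), "v")
})

test_that("training gain matches its formula and is nonnegative at the optimum", {
  set.seed(8)
  bg <- matrix(runif(300), ncol = 2, dimnames = list(NULL, c("a", "b")))
  pr <- cbind(a = rbeta(40, 3, 1.5), b = rbeta(40, 1.5, 3))
  p <- fmPair(pr, bg, classes = "LQ")
  fit <- fitMaxent(p$pres, p$bg, rm = 1)
  # brute-force evaluation of the formula
  eta <- as.numeric(p$pres$values %*% fit@lambda)
  gHand <- mean(eta) - fit@logZ + log(nrow(bg)) -
    sum(fit@betas * abs(fit@lambda))
  expect_equal(trainingGain(fit, p$pres), gHand, tolerance = 1e-12)
  expect_gte(trainingGain(fit, p$pres), 0)
  expect_gte(trainingGain(fit, p$pres, regularized = FALSE),
             trainingGain(fit, p$pres))
})

test_that("percent contribution credits the informative variable and sums to 100", {
  set.seed(12)
  n <- 400
  bg <- cbind(sig = runif(n), noise = runif(n))
  pr <- cbind(sig = rbeta(60, 5, 1.5), noise = runif(60))
  p <- fmPair(pr, bg, classes = "LQ")
  fit <- fitMaxent(p$pres, p$bg, rm = 1)
  ct <- percentContribution(fit)
  expect_equal(sum(ct$contribution), 100, tolerance = 0.1)
  expect_equal(ct$variable[1], "sig")
  expect_gt(ct$contribution[ct$variable == "sig"], 90)
  # one active variable -> 100%
  bg1 <- matrix(runif(n), ncol = 1, dimnames = list(NULL, "x"))
  pr1 <- matrix(rbeta(50, 4, 1), ncol = 1, dimnames = list(NULL, "x"))
  p1 <- fmPair(pr1, bg1)
  f1 <- fitMaxent(p1$pres, p1$bg, rm = 1)
  c1 <- percentContribution(f1)
  expect_equal(c1$contribution, 100)
  # symmetric two-variable truth (mirrored samples): about 50/50
  set.seed(33)
  a <- rbeta(400, 4, 2); b <- rbeta(400, 4, 2)
  prs <- rbind(cbind(u = a, v = b), cbind(u = b, v = a))
  x <- runif(300); y <- runif(300)
  bg2 <- rbind(cbind(u = x, v = y), cbind(u = y, v = x))
  p2 <- fmPair(prs, bg2)
  f2 <- fitMaxent(p2$pres, p2$bg, rm = 0.5)
  c2 <- percentContribution(f2)
  expect_lt(abs(diff(c2$contribution)), 5)
})

test_that("jackknife gains isolate a planted signal", {
  set.seed(19)
  n <- 300
  bgv <- cbind(sig = runif(n), n1 = runif(n), n2 = runif(n))
  prv <- cbind(sig = rbeta(50, 6, 1.5), n1 = runif(50), n2 = runif(50))
  jk <- jackknifeGain(prv, bgv, fc = "LQ", rm = 1)
  expect_true(all(jk$gainOnly >= 0))
  expect_true(all(jk$gainWithout >= 0))
  expect_equal(jk$variable[which.max(jk$gainOnly)], "sig")
  # duplicated variable: dropping one copy barely changes the gain
  bgd <- cbind(a = bgv[, "sig"], b = bgv[, "sig"], c = bgv[, "n1"])
  prd <- cbind(a = prv[, "sig"], b = prv[, "sig"], c = prv[, "n1"])
  jkd <- jackknifeGain(prd, bgd, fc = "L", rm = 1)
  expect_equal(jkd$gainWithout[jkd$variable == "a"],
               jkd$gainFull[1], tolerance = 0.05)
})

test_that("response curves recover planted monotone and unimodal responses", {
  set.seed(23)
  n <- 600
  bg <- cbind(x = runif(n), z = runif(n))
  # monotone: presences biased to high x
  prM <- cbind(x = rbeta(150, 5, 1.5), z = runif(150))
  pM <- fmPair(prM, bg, classes = "L")
  fM <- fitMaxent(pM$pres, pM$bg, rm = 1)
  cv <- responseCurve(fM, "x", n = 50)
  expect_true(all(diff(cv$suitability) > -1e-12))
  expect_true(all(cv$suitability >= 0 & cv$suitability <= 1))
  # unimodal: presences peaked at x ~ 0.6, LQ features
  prU <- cbind(x = pmin(pmax(rnorm(300, 0.6, 0.08), 0), 1), z = runif(300))
  pU <- fmPair(prU, bg, classes = "LQ")
  fU <- fitMaxent(pU$pres, pU$bg, rm = 0.5)
  cu <- responseCurve(fU, "x", n = 200)
  peak <- cu$value[which.max(cu$suitability)]
  expect_lt(abs(peak - 0.6), 0.05)
})

test_that("optimal range interpolates threshold crossings like hand algebra", {
  # piecewise-linear toy curve
  curve <- data.frame(value = c(0, 1, 2, 3, 4),
                      suitability = c(0.2, 0.4, 0.8, 0.6, 0.1))
  r <- optimalRange(curve, 0.5)
  # crossing between (1,0.4) and (2,0.8): 1 + 0.1/0.4 = 1.25
  expect_equal(r[["low"]], 1.25)
  # crossing between (3,0.6) and (4,0.1): 3 + 0.1/0.5 = 3.2
  expect_equal(r[["high"]], 3.2)
  # curve always below threshold: empty marker
  expect_true(all(is.na(optimalRange(
    data.frame(value = 0:3, suitability = rep(0.3, 4)), 0.5))))
  # symmetric unimodal curve: range symmetric about the peak
  v <- seq(0, 1, length.out = 201)
  sym <- data.frame(value = v, suitability = exp(-((v - 0.5) / 0.15)^2))
  rs <- optimalRange(sym, 0.5)
  expect_equal(mean(rs), 0.5, tolerance = 0.005)
})
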