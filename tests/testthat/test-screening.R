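test_that("Horn terrain derivation matches analytic planes and a per-cell oracle", {
  g <- GridDef(5, 5, west = 0, south = 0, cellSize = 0.01)
  # constant elevation: slope 0, aspect sentinel -1
  flat <- deriveTerrain(matrix(100, 5, 5), g)
  expect_true(all(flat$slope == 0))
  expect_true(all(flat$aspect == -1))

  # plane rising due north: downhill faces south -> aspect 180
  latRise <- 10  # metres per row going north
  z <- matrix(rev(seq_len(5)) * latRise, 5, 5)  # row 1 (north) highest
  tn <- deriveTerrain(z, g)
  expect_true(all(abs(tn$aspect - 180) < 1e-9))
  dy <- 0.01 * 111195
  expect_equal(tn$slope[3, 3], atan(latRise / dy) * 180 / pi,
               tolerance = 1e-9)

  # plane rising due east: downhill faces west -> aspect 270
  ze <- matrix(seq_len(5) * 5, 5, 5, byrow = TRUE)
  te <- deriveTerrain(ze, g)
  expect_true(all(abs(te$aspect - 270) < 1e-9))

  # random surface: interior cells match an independent Horn oracle
  set.seed(9)
  zr <- matrix(runif(25, 0, 50), 5, 5)
  tr <- deriveTerrain(zr, g)
  for (r in 2:4) for (c in 2:4) {
    dxm <- 0.01 * 111195 * cos(cellCenterLat(g, r) * pi / 180)
    gx <- ((zr[r - 1, c + 1] + 2 * zr[r, c + 1] + zr[r + 1, c + 1]) -
           (zr[r - 1, c - 1] + 2 * zr[r, c - 1] + zr[r + 1, c - 1])) / (8 * dxm)
    gy <- ((zr[r - 1, c - 1] + 2 * zr[r - 1, c] + zr[r - 1, c + 1]) -
           (zr[r + 1, c - 1] + 2 * zr[r + 1, c] + zr[r + 1, c + 1])) / (8 * dy)
    expect_equal(tr$slope[r, c], atan(sqrt(gx^2 + gy^2)) * 180 / pi,
                 tolerance = 1e-9)
    expect_equal(tr$aspect[r, c], (atan2(-gx, -gy) * 180 / pi) %% 360,
                 tolerance = 1e-9)
  }
  expect_true(all(tr$aspect >= -1 & tr$aspect < 360))
})

test_that("Spearman matrix has rank-correlation semantics", {
  st <- smallStack(seed = 2)
  m <- spearmanMatrix(st)
  expect_equal(diag(m), c(temp = 1, precip = 1))
  expect_equal(m, t(m))
  # monotone invariance: exp of a layer correlates 1 with it
  st2 <- addLayers(st, list(expTemp = exp(getLayer(st, "temp"))))
  m2 <- spearmanMatrix(st2)
  expect_equal(m2["temp", "expTemp"], 1)
  # brute-force oracle on a 10-point table: rank then Pearson
  set.seed(5)
  x <- rnorm(10); y <- x^3 + rnorm(10, sd = 2)
  g <- GridDef(1, 10, 0, 0, 1)
  stp <- EnvStack(g, list(a = matrix(x, 1), b = matrix(y, 1)))
  mp <- spearmanMatrix(stp)
  expect_equal(mp["a", "b"], cor(rank(x), rank(y)), tolerance = 1e-12)
  # constant layer: undefined correlations reported as NA
  stc <- addLayers(st, list(k = matrix(5, nRows(gridDef(st)),
                                       nCols(gridDef(st)))))
  mc <- spearmanMatrix(stc)
  expect_true(is.na(mc["k", "temp"]))
  expect_equal(mc["k", "k"], 1)
})

test_that("collinearity pruning drops the lower-contribution member, strictly above threshold", {
  corr <- diag(3)
  dimnames(corr) <- list(c("a", "b", "c"), c("a", "b", "c"))
  corr["a", "b"] <- corr["b", "a"] <- 0.80
  corr["a", "c"] <- corr["c", "a"] <- 0.10
  res <- pruneCollinear(corr, c(a = 10, b = 5, c = 1), threshold = 0.75)
  expect_setequal(res$retained, c("a", "c"))
  expect_equal(res$dropped$name, "b")
  # boundary: |r| = 0.75 exactly -> both retained (strict inequality)
  corr["a", "b"] <- corr["b", "a"] <- 0.75
  res2 <- pruneCollinear(corr, c(a = 10, b = 5, c = 1), threshold = 0.75)
  expect_setequal(res2$retained, c("a", "b", "c"))
  # contribution tie: lexicographically later name dropped
  corr["a", "b"] <- corr["b", "a"] <- 0.9
  res3 <- pruneCollinear(corr, c(a = 5, b = 5, c = 1), threshold = 0.75)
  expect_false("b" %in% res3$retained)
})

test_that("greedy pruning equals a direct re-execution oracle and is threshold-monotone", {
  set.seed(21)
  nms <- letters[1:6]
  for (rep in 1:20) {
    L <- matrix(rnorm(36), 6)
    S <- cov2cor(crossprod(L) + diag(6) * 0.5)
    dimnames(S) <- list(nms, nms)
    contrib <- setNames(round(runif(6), 3) * 100, nms)
    got <- pruneCollinear(S, contrib, threshold = 0.6)

    # direct independent re-execution of the stated iteration
    retained <- sort(nms)
    repeat {
      pairs <- t(combn(retained, 2))
      rs <- abs(S[pairs])
      over <- rs > 0.6
      if (!any(over)) break
      mx <- max(rs[over])
      cand <- pairs[over & rs == mx, , drop = FALSE]
      cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
      v1 <- cand[1, 1]; v2 <- cand[1, 2]
      c1 <- contrib[v1]; c2 <- contrib[v2]
      loser <- if (c1 < c2) v1 else if (c2 < c1) v2 else max(c(v1, v2))
      retained <- setdiff(retained, loser)
    }
    expect_setequal(got$retained, retained)
    # post-condition: no retained pair above threshold
    sub <- abs(S[got$retained, got$retained])
    diag(sub) <- 0
    expect_lte(max(sub), 0.6)
    # monotonicity: higher threshold never shrinks the retained set
    looser <- pruneCollinear(S, contrib, threshold = 0.8)
    expect_true(all(got$retained %in% looser$retained))
  }
})

test_that("screening can reproduce an 8-variable non-redundant panel", {
  vars <- c("bio3", "bio11", "bio13", "bio15", "bio19",
            "elevation", "aspect", "slope",
            "bio1", "bio6", "bio12", "bio16")
  k <- length(vars)
  S <- diag(k)
  dimnames(S) <- list(vars, vars)
  setR <- function(a, b, r) S[a, b] <<- S[b, a] <<- r
  # redundant partners of the kept panel, higher |r| than 0.75
  setR("bio1", "bio11", 0.92)
  setR("bio6", "bio11", 0.88)
  setR("bio12", "bio13", 0.90)
  setR("bio16", "bio13", 0.95)
  contrib <- c(bio3 = 0.4, bio11 = 18.2, bio13 = 18.1, bio15 = 19.9,
               bio19 = 10.6, elevation = 9.8, aspect = 3.6, slope = 4.8,
               bio1 = 4.1, bio6 = 0.1, bio12 = 0, bio16 = 0)
  res <- pruneCollinear(S, contrib, threshold = 0.75)
  expect_setequal(res$retained,
                  c("bio3", "bio11", "bio13", "bio15", "bio19",
                    "elevation", "aspect", "slope"))
  expect_equal(length(res$retained), 8L)
})
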