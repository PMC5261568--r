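randomSet <- function(n, p, seed = 1, grid = NULL) {
  set.seed(seed)
  if (is.null(grid)) grid <- 1000 + 4 * seq_len(p)
  spectraSet(matrix(rnorm(n * p), nrow = p), grid)
}

test_that("PCA matches the covariance-eigendecomposition oracle", {
  ss <- randomSet(5, 4, seed = 3)
  mod <- pcaFit(ss, nComponents = 3L, orientWavenumber = NA)
  X <- t(spectraMatrix(ss))
  ev <- eigen(cov(X), symmetric = TRUE)
  for (k in 1:3) {
    # loadings agree up to sign
    expect_equal(abs(mod@loadings[k, ]), abs(ev$vectors[, k]),
                 tolerance = 1e-8, ignore_attr = TRUE)
    # explained variance ratios agree
    expect_equal(mod@explainedVarPct[k],
                 100 * ev$values[k] / sum(ev$values), tolerance = 1e-8)
  }
  expect_true(all(diff(mod@explainedVarPct) <= 1e-12))
  expect_lte(sum(mod@explainedVarPct), 100 + 1e-9)
})

test_that("PCA reconstructs centred data and handles rank-1 input", {
  ss <- randomSet(6, 5, seed = 4)
  mod <- pcaFit(ss, nComponents = 5L, orientWavenumber = NA)
  X <- t(spectraMatrix(ss))
  Xc <- sweep(X, 2, colMeans(X))
  expect_lt(max(abs(Xc - mod@scores %*% mod@loadings)), 1e-9)
  # rank-1 data: one component explains ~100%
  v <- rnorm(4); grid <- 1000 + 4 * (1:4)
  X1 <- rbind(v, 2 * v, 3 * v, -v, 0.5 * v)
  r1 <- pcaFit(spectraSet(t(X1), grid), nComponents = 1L,
               orientWavenumber = NA)
  expect_equal(r1@explainedVarPct[1], 100, tolerance = 1e-8)
  expect_error(pcaFit(ss, nComponents = 6L), "exceeds")
})

test_that("PCA orientation puts the beta-sheet loading positive on PC1", {
  cfg <- defaultPipelineConfig()
  d <- smallDesign(seed = 12L)
  ss <- synthDataset(d)
  prep <- preprocessChain(subsetBySplit(ss, "pca_cal"))
  mod <- pcaFit(prep$set, nComponents = 5L)
  wn <- wavenumbers(mod)
  expect_gt(mod@loadings[1, which.min(abs(wn - 1621))], 0)
  expect_lt(mod@loadings[1, which.min(abs(wn - 1650))], 0)
  # complete sign separation of the two classes along PC1
  lab <- classLabels(subsetBySplit(ss, "pca_cal"))
  s1 <- mod@scores[, 1]
  expect_true(all(s1[lab == "electrical_mark"] *
                  s1[lab == "normal_epidermis"][1] < 0))
  expect_true(all(sign(s1[lab == "electrical_mark"]) ==
                  sign(s1[lab == "electrical_mark"][1])))
  expect_true(all(sign(s1[lab == "normal_epidermis"]) ==
                  sign(s1[lab == "normal_epidermis"][1])))
})

test_that("confidence ellipse has the closed-form size and equivariance", {
  pts <- matrix(c(1, 0, -1, 0, 0, 1, 0, -1), ncol = 2, byrow = TRUE)
  # sample covariance of these 4 points is (2/3) I; rescale to unit variance
  pts <- pts / sqrt(2 / 3)
  e <- confidenceEllipse(pts, level = 0.95)
  expect_equal(unname(e$semiAxes), rep(sqrt(qchisq(0.95, 2)), 2),
               tolerance = 1e-8)
  e2 <- confidenceEllipse(2 * pts, level = 0.95)
  expect_equal(e2$semiAxes, 2 * e$semiAxes, tolerance = 1e-8)
  expect_error(confidenceEllipse(pts[1:2, ]), "at least 3")
  expect_error(confidenceEllipse(cbind(1:5, 2 * (1:5))), "degenerate")
})

test_that("confidence ellipse covers ~95% of a large bivariate normal", {
  set.seed(31)
  n <- 5000
  A <- matrix(c(2, 0.8, 0.3, 1), 2)
  pts <- matrix(rnorm(2 * n), ncol = 2) %*% t(A)
  e <- confidenceEllipse(pts, level = 0.95)
  cover <- mean(insideEllipse(pts, e))
  expect_gt(cover, 0.93)
  expect_lt(cover, 0.97)
})

test_that("PLS1 is exact for a single informative channel", {
  grid <- 1000 + 4 * (1:6)
  set.seed(6)
  # in-sample uncorrelated channels: one latent factor then isolates the
  # informative channel exactly
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(60), nrow = 10))))[, 2:7]
  X <- t(Q)   # channels x spectra; columns centred and orthogonal
  y <- 2 + 3 * X[4, ]
  ss <- spectraSet(X, grid)
  mod <- pls1Fit(ss, y = y, nFactors = 1L)
  expect_equal(unname(predict(mod, ss)), y, tolerance = 1e-8)
  # training-mean identity
  xm <- matrix(rowMeans(X), nrow = 1)
  expect_equal(unname(predict(mod, xm)), mean(y), tolerance = 1e-10)
})

test_that("full-rank PLS1 equals the least-squares oracle", {
  set.seed(8)
  X <- matrix(rnorm(40), nrow = 8, ncol = 5)    # spectra x channels
  y <- rnorm(8)
  ss <- spectraSet(t(X), 1000 + 4 * (1:5))
  mod <- pls1Fit(ss, y = y, nFactors = 5L)
  Xc <- sweep(X, 2, colMeans(X))
  bOls <- qr.solve(Xc, y - mean(y))
  expect_equal(mod@coef, bOls, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("first PLS weight is proportional to X'y", {
  set.seed(13)
  X <- matrix(rnorm(60), nrow = 10)
  y <- rnorm(10)
  ss <- spectraSet(t(X), 1000 + 4 * (1:6))
  mod <- pls1Fit(ss, y = y, nFactors = 2L)
  Xc <- sweep(X, 2, colMeans(X)); yc <- y - mean(y)
  w <- drop(crossprod(Xc, yc)); w <- w / sqrt(sum(w^2))
  expect_equal(abs(mod@weights[, 1]), abs(w), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("LOOCV finds low-rank structure and is order-invariant", {
  # noiseless rank-2 class structure
  set.seed(17)
  n <- 18
  cls <- rep(1:3, each = 6)
  b1 <- rnorm(12); b2 <- rnorm(12)
  X <- outer(cls == 2, b1) * 1 + outer(cls == 3, b2) * 1
  y <- as.numeric(cls)
  ss <- spectraSet(t(X), 1000 + 4 * (1:12))
  cv <- plsLoocv(ss, y = y, maxFactors = 6L)
  expect_lte(cv@chosenFactors, 2L)
  expect_lt(cv@rmsecv[2], 1e-6)
  # permutation invariance
  perm <- sample(n)
  cvP <- plsLoocv(ss[, perm], y = y[perm], maxFactors = 6L)
  expect_equal(cvP@predictions[order(perm), ], cv@predictions,
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(cvP@rmsecv, cv@rmsecv, tolerance = 1e-9)
  expect_error(plsLoocv(ss, y = rep(1, n)), "zero-variance")
})

test_that("Y thresholds classify with a closed electrical interval", {
  expect_equal(classifyY(1.0), "normal_epidermis")
  expect_equal(classifyY(2.0), "electrical_mark")
  expect_equal(classifyY(c(1.5, 2.5)), rep("electrical_mark", 2))
  expect_equal(classifyY(2.5000001), "normal_dermis")
  expect_equal(classifyY(1.4999999), "normal_epidermis")
  expect_equal(classifyY(c(0.2, 3.8)),
               c("normal_epidermis", "normal_dermis"))
})

test_that("accuracy tables report per-class counts to 0.1%", {
  truth <- c(rep("normal_epidermis", 20), rep("normal_dermis", 14))
  pred <- truth
  pred[c(1, 2, 3)] <- "electrical_mark"   # 17/20 epidermis correct
  pred[c(21, 22, 23)] <- "electrical_mark"  # 11/14 dermis correct
  tab <- accuracyTable(pred, truth)
  expect_equal(tab$accuracyPct[tab$class == "normal_epidermis"], 85.0)
  expect_equal(tab$accuracyPct[tab$class == "normal_dermis"], 78.6)
  expect_equal(tab$correct[tab$class == "normal_epidermis"], 17)
  allOk <- accuracyTable(truth, truth)
  expect_true(all(allOk$accuracyPct == 100))
  expect_error(accuracyTable(c("a", "b"), c("x", "y")), "disjoint")
  expect_error(accuracyTable("a", c("a", "a")), "equal length")
})
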