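test_that("EMSC recovers affine and polynomial distortions exactly", {
  grid <- tinyGrid()
  ref <- bandSum(pureProfile(), grid)
  ns <- 2 * (grid - min(grid)) / diff(range(grid)) - 1
  z1 <- ref                                # identity
  z2 <- 0.2 + 1.5 * ref                    # affine
  z3 <- ref + 0.001 * ns + 0.0005 * ns^2   # polynomial baseline
  ss <- spectraSet(cbind(z1, z2, z3), grid)
  res <- emscCorrect(ss, reference = ref)
  cf <- res@coefficients
  expect_equal(unname(cf["z1", ]), c(0, 1, 0, 0), tolerance = 1e-10)
  expect_equal(unname(cf["z2", c("a", "b")]), c(0.2, 1.5), tolerance = 1e-10)
  for (j in 1:3)
    expect_equal(spectraMatrix(res@corrected)[, j], ref, tolerance = 1e-10,
                 ignore_attr = TRUE)
  # coefficients agree with the brute-force normal-equations oracle
  expect_equal(unname(cf["z3", ]), emscOracle(z3, ref, ns),
               tolerance = 1e-9)
})

test_that("EMSC is idempotent and flags non-positive scales", {
  grid <- tinyGrid()
  ref <- bandSum(pureProfile(), grid)
  set.seed(5)
  X <- sapply(1:6, function(i)
    exp(rnorm(1, sd = 0.2)) * ref + rnorm(1, sd = 0.05))
  first <- emscCorrect(spectraSet(X, grid), reference = ref)
  second <- emscCorrect(first@corrected, reference = ref)
  expect_equal(spectraMatrix(second@corrected),
               spectraMatrix(first@corrected), tolerance = 1e-9)
  expect_equal(unname(second@coefficients[, "b"]), rep(1, 6),
               tolerance = 1e-9)
  expect_equal(max(abs(second@coefficients[, c("a", "d1", "d2")])), 0,
               tolerance = 1e-9)
  # a spectrum anti-correlated with the reference gets flagged, not divided
  bad <- cbind(ref, -ref)
  resBad <- emscCorrect(spectraSet(bad, grid), reference = ref)
  expect_equal(resBad@flagged, c(FALSE, TRUE))
  expect_equal(spectraMatrix(resBad@corrected)[, 2], -ref,
               ignore_attr = TRUE)
  # constant reference is a singular design
  expect_error(emscCorrect(spectraSet(X, grid), reference = rep(1, length(grid))),
               "singular|constant")
})

test_that("EMSC removes the generator's scatter distortions", {
  grid <- defaultGrid()
  prof <- classProfile("normal_epidermis",
                       defaultBandLibrary()$normal_epidermis@bands,
                       amplitudeCv = 0, noiseSd = 0.005)
  set.seed(21)
  X <- replicate(60, synthSpectrum(prof, grid, scatterModel()))
  res <- emscCorrect(spectraSet(X, grid), reference = bandSum(prof, grid))
  corrected <- spectraMatrix(res@corrected)
  expect_lt(max(abs(rowMeans(corrected) - bandSum(prof, grid))),
            3 * 0.005)
})

test_that("SG second derivative is exact on low-order polynomials", {
  grid <- 1500 + 4 * (0:50)
  idx <- 0:50
  quad <- spectraSet(cbind(idx^2, idx^3, rep(2, 51)), grid)
  d <- savgolSecondDerivative(quad, 9L, 3L)
  h2 <- 16  # (4 cm^-1)^2
  expect_equal(spectraMatrix(d)[, 1], rep(2 / h2, 51), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(spectraMatrix(d)[, 2], 6 * idx / h2, tolerance = 1e-7,
               ignore_attr = TRUE)
  expect_equal(spectraMatrix(d)[, 3], rep(0, 51), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("SG second derivative matches the per-window polyfit oracle", {
  grid <- 1500 + 4 * (0:40)
  set.seed(9)
  v <- rnorm(41)
  d <- savgolSecondDerivative(spectraSet(matrix(v), grid), 9L, 3L)
  for (i in c(5L, 13L, 27L, 37L))
    expect_equal(unname(spectraMatrix(d)[i, 1]), sgOracle(v, i, 9L, 3L, h = 4),
                 tolerance = 1e-8)
})

test_that("SG second derivative is linear and rejects bad inputs", {
  grid <- 1500 + 4 * (0:30)
  set.seed(2)
  x <- rnorm(31); y <- rnorm(31)
  D2 <- function(v) spectraMatrix(
    savgolSecondDerivative(spectraSet(matrix(v), grid)))[, 1]
  expect_equal(D2(2 * x + 3 * y), 2 * D2(x) + 3 * D2(y), tolerance = 1e-12)
  expect_error(savgolSecondDerivative(spectraSet(matrix(x), grid), 8L),
               "odd")
  expect_error(
    savgolSecondDerivative(spectraSet(matrix(rnorm(3)), c(1, 2, 4.5)), 3L, 2L),
    "uniform")
})

test_that("a Gaussian band's second derivative is deepest at its centre", {
  grid <- seq(1500, 1800, by = 4)
  v <- bandSum(pureProfile(1648, 30, 1), grid)  # on-grid centre
  d <- spectraMatrix(savgolSecondDerivative(spectraSet(matrix(v), grid)))[, 1]
  expect_equal(grid[which.min(d)], 1648)
})

test_that("window extraction keeps the closed interval, in order", {
  ss <- synthDataset(smallDesign())
  win <- extractWindow(ss, 1710, 1585)
  wn <- wavenumbers(win)
  # direct count of default-grid points in [1585, 1710]
  expect_equal(length(wn), sum(defaultGrid() >= 1585 & defaultGrid() <= 1710))
  expect_equal(range(wn), c(1588, 1708))
  expect_false(is.unsorted(wn, strictly = TRUE))
  # identity when the window covers the grid
  full <- extractWindow(ss, 4000, 900)
  expect_equal(spectraMatrix(full), spectraMatrix(ss))
  expect_error(extractWindow(ss, 1900, 2000), "high > low")
  expect_error(extractWindow(ss, 4200, 4100), "intersect")
})
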