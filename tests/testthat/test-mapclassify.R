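# Train a small PLS model once for the map tests
trainSmallModel <- function(seed = 19L) {
  ss <- synthDataset(smallDesign(seed))
  cal <- subsetBySplit(ss, "pls_cal")
  prep <- preprocessChain(cal)
  cv <- plsLoocv(prep$set, maxFactors = 5L)
  list(pls = pls1Fit(prep$set, nFactors = cv@chosenFactors),
       reference = prep$reference)
}

test_that("an all-background map classifies entirely as background", {
  mdl <- trainSmallModel()
  g <- scanGeometry(40, 50, 10)
  hm <- synthMap(matrix("background", 4, 5), g, seed = 2L)
  cm <- classifyHyperMap(hm, mdl$reference, mdl$pls,
                         backgroundThreshold = 0.05)
  expect_true(all(classLabels(cm) == "background"))
})

test_that("lesion maps are recovered with high per-pixel agreement", {
  mdl <- trainSmallModel()
  hm <- synthMap("electrical_lesion", scanGeometry(), seed = 5L)
  cm <- classifyHyperMap(hm, mdl$reference, mdl$pls)
  expect_gte(mapAgreement(cm, hm@truth), 0.85)
  # normal-skin maps must contain no electrical pixels on true epidermis
  hm2 <- synthMap("normal_skin", scanGeometry(), seed = 6L)
  cm2 <- classifyHyperMap(hm2, mdl$reference, mdl$pls)
  expect_equal(sum(classLabels(cm2)[hm2@truth == "normal_epidermis"] ==
                   "electrical_mark"), 0L)
})

test_that("classification is per-pixel independent", {
  mdl <- trainSmallModel()
  g <- scanGeometry(60, 60, 10)
  hm <- synthMap(mapLayout("electrical_lesion", g), g, seed = 7L)
  cm <- classifyHyperMap(hm, mdl$reference, mdl$pls,
                         backgroundThreshold = 0.05)
  # permute pixels, classify, un-permute: identical labels
  set.seed(8)
  perm <- sample(36)
  cube <- hm@cube
  dim(cube) <- c(36, dim(hm@cube)[3])
  cubeP <- array(cube[perm, ], dim = c(6, 6, dim(hm@cube)[3]))
  hmP <- hyperMap(cubeP, wavenumbers(hm), g)
  cmP <- classifyHyperMap(hmP, mdl$reference, mdl$pls,
                          backgroundThreshold = 0.05)
  labP <- classLabels(cmP)
  dim(labP) <- NULL
  unperm <- character(36)
  unperm[perm] <- labP
  expect_equal(unperm, as.character(classLabels(cm)))
})

test_that("raising the background threshold only grows the background", {
  mdl <- trainSmallModel()
  hm <- synthMap("electrical_lesion", scanGeometry(60, 80, 10), seed = 9L)
  thresholds <- c(0.01, 0.05, 0.2, 0.5)
  prev <- NULL
  for (bt in thresholds) {
    cm <- classifyHyperMap(hm, mdl$reference, mdl$pls,
                           backgroundThreshold = bt)
    bg <- classLabels(cm) == "background"
    if (!is.null(prev)) {
      expect_true(all(bg[prev]))  # background region is monotone
      # tissue pixels never switch tissue class as the threshold rises
      keep <- !bg & !prev
      expect_equal(classLabels(cm)[keep], prevLabels[keep])
    }
    prev <- bg
    prevLabels <- classLabels(cm)
  }
})

test_that("class-map rendering uses the exact legend and round-trips", {
  leg <- classMapLegend()
  expect_equal(unname(grDevices::col2rgb(leg[["electrical_mark"]])[, 1]),
               c(255, 255, 0))
  expect_equal(unname(grDevices::col2rgb(leg[["normal_epidermis"]])[, 1]),
               c(173, 216, 230))
  expect_equal(unname(grDevices::col2rgb(leg[["normal_dermis"]])[, 1]),
               c(139, 69, 19))
  expect_equal(unname(grDevices::col2rgb(leg[["background"]])[, 1]),
               c(0, 0, 139))
  # 1x1 electrical map renders a single yellow pixel
  f <- tempfile(fileext = ".png")
  renderClassMap(classMap(matrix("electrical_mark", 1, 1)), f)
  px <- png::readPNG(f)
  expect_equal(dim(px)[1:2], c(1L, 1L))
  expect_equal(as.numeric(px[1, 1, 1:3]), c(1, 1, 0))
  # full legend round trip on a random map, with upscaling
  set.seed(10)
  lab <- matrix(sample(names(leg), 14 * 20, replace = TRUE), 14, 20)
  f2 <- tempfile(fileext = ".png")
  renderClassMap(classMap(lab), f2, upscale = 3L)
  px2 <- png::readPNG(f2)
  expect_equal(dim(px2)[1:2], c(42L, 60L))
  expect_equal(decodeClassMap(f2, upscale = 3L), lab)
  unlink(c(f, f2))
})

test_that("confusion matrices tally every pixel", {
  lab <- matrix(c("normal_epidermis", "normal_epidermis",
                  "electrical_mark", "normal_dermis"), 2, 2)
  cm <- classMap(lab)
  conf <- confusionOnTruth(cm, lab)
  expect_true(all(conf[row(conf) != col(conf)] == 0))
  expect_equal(sum(conf), 4)
  # one mislabelled pixel appears off-diagonal
  truth <- lab; truth[1, 1] <- "electrical_mark"
  conf2 <- confusionOnTruth(cm, truth)
  expect_equal(conf2["electrical_mark", "normal_epidermis"], 1,
               ignore_attr = TRUE)
  expect_equal(sum(conf2), 4)
  # random maps: totals equal the pixel count (brute-force tally)
  set.seed(11)
  cls <- c("normal_epidermis", "electrical_mark", "normal_dermis")
  a <- matrix(sample(cls, 30, TRUE), 5, 6)
  b <- matrix(sample(cls, 30, TRUE), 5, 6)
  expect_equal(sum(confusionOnTruth(classMap(a), b)), 30)
  expect_error(confusionOnTruth(classMap(a), b[1:4, ]), "dims")
})
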