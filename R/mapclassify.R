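#' Classify a hyperspectral map pixel by pixel
#'
#' Applies the trained pipeline to every pixel of an absorbance-mode
#' [HyperMap]. Pixels whose mean raw absorbance over the Amide I window
#' falls below \code{backgroundThreshold} are labelled background before
#' any correction (EMSC of a near-zero spectrum is ill-posed). All other
#' pixels are EMSC-corrected against the stored calibration reference,
#' second-derivative transformed, windowed to the model's channels, and
#' classified by thresholding the PLS prediction.
#'
#' @param map an absorbance-mode [HyperMap] on the calibration grid
#' @param emscReference numeric calibration reference spectrum (full grid)
#' @param pls a fitted [PLSModel] (trained on windowed second-derivative
#'   spectra)
#' @param backgroundThreshold absolute absorbance threshold, or NULL
#'   (default) to use 10\% of the map's median Amide I mean absorbance — a
#'   heuristic: the original figure's background rule is not documented
#' @param windowHigh,windowLow Amide I window edges (cm^-1)
#' @param sgWindow,sgOrder Savitzky-Golay settings (must match training)
#' @param emscDegree EMSC baseline degree (must match training)
#' @return a [ClassMap] with the fixed legend
#' @export
classifyHyperMap <- function(map, emscReference, pls,
                             backgroundThreshold = NULL,
                             windowHigh = 1710, windowLow = 1585,
                             sgWindow = 9L, sgOrder = 3L,
                             emscDegree = 2L) {
  stopifnot(is(map, "HyperMap"), is(pls, "PLSModel"))
  if (!identical(spectraMode(map), "absorbance"))
    stop("classifyHyperMap expects a raw absorbance map")
  flat <- flattenMap(map)
  wn <- wavenumbers(flat)
  inWin <- wn >= windowLow & wn <= windowHigh
  pixelMean <- colMeans(spectraMatrix(flat)[inWin, , drop = FALSE])
  if (is.null(backgroundThreshold))
    backgroundThreshold <- 0.1 * median(pixelMean)
  bg <- pixelMean < backgroundThreshold
  d <- gridDims(map)
  labels <- matrix("background", d[[1L]], d[[2L]])
  if (any(!bg)) {
    tissue <- flat[, !bg]
    corrected <- emscCorrect(tissue, reference = emscReference,
                             polyDegree = emscDegree)@corrected
    deriv <- savgolSecondDerivative(corrected, sgWindow, sgOrder)
    win <- extractWindow(deriv, windowHigh, windowLow)
    if (length(wavenumbers(win)) != length(wavenumbers(pls)) ||
        max(abs(wavenumbers(win) - wavenumbers(pls))) > 1e-8)
      stop("map grid does not match the PLS model grid after windowing")
    yPred <- predict(pls, win)
    cls <- classifyY(yPred, pls@thresholds)
    pr <- colData(tissue)$pixelRow
    pc <- colData(tissue)$pixelCol
    labels[cbind(pr, pc)] <- cls
  }
  classMap(labels)
}

#' Render a class map as a pseudo-colored PNG
#'
#' One image pixel per spectrum (optionally replicated by an integer
#' upscale factor) with the exact legend colors: yellow electrical mark,
#' light blue normal epidermis, brown normal dermis, dark blue background.
#' The colors are bijective, so a rendered map decodes back to its labels.
#'
#' @param cm a [ClassMap]
#' @param path output PNG path
#' @param upscale integer pixel replication factor (default 1)
#' @return invisibly, the path
#' @export
renderClassMap <- function(cm, path, upscale = 1L) {
  stopifnot(is(cm, "ClassMap"))
  rgb <- grDevices::col2rgb(cm@legend[cm@labels]) / 255
  nr <- nrow(cm@labels); nc <- ncol(cm@labels)
  arr <- array(0, dim = c(nr, nc, 3L))
  for (k in 1:3) arr[, , k] <- matrix(rgb[k, ], nr, nc)
  if (upscale > 1L)
    arr <- arr[rep(seq_len(nr), each = upscale),
               rep(seq_len(nc), each = upscale), , drop = FALSE]
  png::writePNG(arr, path)
  invisible(path)
}

#' Decode a rendered class-map PNG back to labels
#'
#' @param path PNG written by [renderClassMap()]
#' @param legend the legend used for rendering
#' @param upscale the upscale factor used for rendering
#' @return character matrix of labels
#' @export
decodeClassMap <- function(path, legend = classMapLegend(), upscale = 1L) {
  arr <- png::readPNG(path)
  if (upscale > 1L) {
    ri <- seq(1L, dim(arr)[1L], by = upscale)
    ci <- seq(1L, dim(arr)[2L], by = upscale)
    arr <- arr[ri, ci, , drop = FALSE]
  }
  key <- grDevices::col2rgb(legend) / 255
  nr <- dim(arr)[1L]; nc <- dim(arr)[2L]
  out <- matrix(NA_character_, nr, nc)
  for (j in seq_len(nc))
    for (i in seq_len(nr)) {
      d <- colSums((key - arr[i, j, 1:3])^2)
      out[i, j] <- names(legend)[which.min(d)]
    }
  out
}

#' Pixel confusion matrix against ground truth
#'
#' Counts of (true class, predicted class) pixel pairs. Background pixels
#' (in either map) can be excluded, which is the relevant comparison for
#' tissue classification accuracy.
#'
#' @param cm a [ClassMap]
#' @param truth character matrix of true classes, same dims
#' @param excludeBackground drop pixels that are background in truth or
#'   prediction (default TRUE)
#' @return a table of counts, true classes x predicted classes
#' @export
confusionOnTruth <- function(cm, truth, excludeBackground = TRUE) {
  stopifnot(is(cm, "ClassMap"))
  truth <- as.matrix(truth)
  if (!identical(dim(truth), dim(cm@labels)))
    stop("truth dims must match the class map")
  tv <- as.character(truth); pv <- as.character(cm@labels)
  if (excludeBackground) {
    keep <- tv != "background" & pv != "background"
    tv <- tv[keep]; pv <- pv[keep]
  }
  table(true = tv, predicted = pv)
}

#' Per-pixel agreement with ground truth
#'
#' @inheritParams confusionOnTruth
#' @return fraction of (non-background) pixels whose predicted class
#'   equals the true class
#' @export
mapAgreement <- function(cm, truth, excludeBackground = TRUE) {
  truth <- as.matrix(truth)
  tv <- as.character(truth); pv <- as.character(cm@labels)
  if (excludeBackground) {
    keep <- tv != "background"
    tv <- tv[keep]; pv <- pv[keep]
  }
  mean(pv == tv)
}
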