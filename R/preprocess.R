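#' EMSC correction result
#'
#' Output of [emscCorrect()]: the corrected spectra, the per-spectrum fit
#' coefficients (offset a, multiplicative scale b, and polynomial baseline
#' coefficients d1, d2 on the rescaled wavenumber), the reference spectrum
#' used, and a flag for spectra whose fitted scale was not positive (these
#' are left uncorrected rather than silently divided by a non-positive b).
#'
#' @slot corrected a [SpectraSet] of corrected spectra
#' @slot coefficients matrix, one row per spectrum: a, b, d1..dk
#' @slot reference numeric reference spectrum
#' @slot flagged logical vector, TRUE where b <= 0
#' @slot polyDegree baseline polynomial degree used (0, 1 or 2)
#' @export
setClass("EMSCResult",
  representation(corrected = "SpectraSet", coefficients = "matrix",
                 reference = "numeric", flagged = "logical",
                 polyDegree = "integer"))

setMethod("show", "EMSCResult", function(object) {
  cat(sprintf("EMSCResult: %d spectra, baseline degree %d, %d flagged (b <= 0)\n",
              ncol(object@corrected), object@polyDegree,
              sum(object@flagged)))
})

#' Extended multiplicative signal correction
#'
#' Fits each spectrum z by least squares to
#' \deqn{z \approx a + b\, m(\nu) + \sum_k d_k \nu_*^k}
#' where m is a reference spectrum and \eqn{\nu_*} is the wavenumber
#' rescaled to [-1, 1], then returns the corrected spectrum
#' \eqn{(z - a - \sum_k d_k \nu_*^k)/b}. This removes additive offset,
#' polynomial baseline drift and multiplicative path-length (section
#' thickness) differences in one step. The reference defaults to the mean
#' spectrum of the set; for prediction data pass the stored calibration
#' reference so no information leaks from validation spectra into the
#' correction.
#'
#' @param set a [SpectraSet] in absorbance mode
#' @param reference \code{"mean"} (default) or a numeric spectrum on the
#'   same grid
#' @param polyDegree baseline polynomial degree: 0, 1 or 2 (default 2)
#' @return an [EMSCResult]
#' @examples
#' ss <- synthDataset(studyDesign(pcaCal = c(electrical_mark = 5,
#'   normal_epidermis = 5), plsCal = c(electrical_mark = 0),
#'   internalPred = c(electrical_mark = 0),
#'   externalVal = c(electrical_mark = 0)))
#' res <- emscCorrect(ss)
#' head(res@coefficients)
#' @export
emscCorrect <- function(set, reference = "mean", polyDegree = 2L) {
  stopifnot(is(set, "SpectraSet"))
  if (ncol(set) == 0L) stop("cannot EMSC-correct an empty SpectraSet")
  if (!polyDegree %in% 0:2) stop("polyDegree must be 0, 1 or 2")
  X <- spectraMatrix(set)
  m <- if (identical(reference, "mean")) rowMeans(X) else as.numeric(reference)
  if (length(m) != nrow(X))
    stop("reference must be on the same wavenumber grid as the set")
  if (sd(m) < .Machine$double.eps^0.5)
    stop("singular EMSC design: reference spectrum is constant")
  ns <- .nuStar(wavenumbers(set))
  D <- cbind(intercept = 1, ref = m)
  if (polyDegree >= 1L) D <- cbind(D, d1 = ns)
  if (polyDegree >= 2L) D <- cbind(D, d2 = ns^2)
  fit <- lm.fit(D, X)
  cf <- t(as.matrix(fit$coefficients))
  colnames(cf) <- c("a", "b", if (polyDegree >= 1L) "d1",
                    if (polyDegree >= 2L) "d2")
  flagged <- cf[, "b"] <= 0
  baseline <- D[, -2L, drop = FALSE] %*% t(cf[, -2L, drop = FALSE])
  corrected <- sweep(X - baseline, 2L, cf[, "b"], "/")
  corrected[, flagged] <- X[, flagged]  # left untouched, flagged for the caller
  out <- set
  SummarizedExperiment::assay(out, "spectra") <- corrected
  new("EMSCResult", corrected = out, coefficients = cf, reference = m,
      flagged = unname(flagged), polyDegree = as.integer(polyDegree))
}

#' Savitzky-Golay second derivative
#'
#' Smoothed second derivative of each spectrum: in every window of
#' \code{windowPoints} channels a polynomial of degree \code{polyOrder} is
#' fitted and its second derivative at the window centre taken. Edge
#' channels use the polynomial fitted on the one-sided window (no
#' wraparound). The derivative is computed per channel index and scaled by
#' the squared channel spacing, so values are per cm^-2; this is exact for
#' the uniform grids required here.
#'
#' @param set a [SpectraSet] on a uniformly spaced grid
#' @param windowPoints odd window length (default 9)
#' @param polyOrder polynomial degree, >= 2 (default 3; degree 2 gives
#'   identical second-derivative coefficients)
#' @return a [SpectraSet] with \code{mode = "second_derivative"}
#' @export
savgolSecondDerivative <- function(set, windowPoints = 9L, polyOrder = 3L) {
  stopifnot(is(set, "SpectraSet"))
  if (windowPoints %% 2L != 1L) stop("windowPoints must be odd")
  if (polyOrder < 2L) stop("polyOrder must be >= 2 for a second derivative")
  if (windowPoints < polyOrder + 1L)
    stop("windowPoints must be >= polyOrder + 1")
  wn <- wavenumbers(set)
  if (length(wn) < windowPoints)
    stop("spectrum shorter than the filter window")
  dv <- diff(wn)
  if (max(abs(dv - dv[1L])) > 1e-8 * abs(dv[1L]))
    stop("Savitzky-Golay derivative requires a uniformly spaced grid")
  X <- spectraMatrix(set)
  out <- apply(X, 2L, signal::sgolayfilt, p = polyOrder, n = windowPoints,
               m = 2L, ts = dv[1L])
  out <- matrix(out, nrow = nrow(X), dimnames = dimnames(X))
  res <- set
  SummarizedExperiment::assay(res, "spectra") <- out
  metadata(res)$mode <- "second_derivative"
  res
}

#' Extract a wavenumber window
#'
#' Keeps the channels with \code{low <= wavenumber <= high} (closed
#' interval, order preserved). Spectroscopy convention quotes windows as
#' high-low (e.g. the Amide I band, 1710-1585 cm^-1).
#'
#' @param set a [SpectraSet]
#' @param high upper window edge (cm^-1)
#' @param low lower window edge (cm^-1)
#' @return the windowed [SpectraSet]
#' @export
extractWindow <- function(set, high = 1710, low = 1585) {
  stopifnot(is(set, "SpectraSet"))
  if (high <= low) stop("window must be given as (high, low) with high > low")
  keep <- wavenumbers(set) >= low & wavenumbers(set) <= high
  if (!any(keep)) stop("window does not intersect the wavenumber grid")
  set[keep, ]
}
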