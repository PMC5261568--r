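#' @import methods
#' @importFrom stats coef cov lm.fit median predict qchisq rnorm sd setNames
#' @importFrom utils read.csv write.csv head tail
NULL

#' Wavenumber grid of an object
#'
#' Returns the shared wavenumber axis (cm^-1, ascending) of a spectral
#' container.
#'
#' @param x a [SpectraSet], [HyperMap], [PCAModel] or [PLSModel]
#' @return numeric vector of wavenumbers in cm^-1
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' Spectral data matrix
#'
#' @param x a [SpectraSet]
#' @return numeric matrix, channels x spectra
#' @export
setGeneric("spectraMatrix", function(x) standardGeneric("spectraMatrix"))

#' Class labels of spectra
#'
#' @param x a [SpectraSet] or [ClassMap]
#' @return character vector (or matrix for maps) of tissue-class labels
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' Split tags of spectra
#'
#' Which study split (\code{pca_cal}, \code{pls_cal}, \code{internal_pred},
#' \code{external_val}) each spectrum belongs to.
#'
#' @param x a [SpectraSet]
#' @return character vector
#' @export
setGeneric("splitTags", function(x) standardGeneric("splitTags"))

#' Spectral mode
#'
#' Whether values are raw absorbance or second-derivative absorbance.
#'
#' @param x a [SpectraSet] or [HyperMap]
#' @return \code{"absorbance"} or \code{"second_derivative"}
#' @export
setGeneric("spectraMode", function(x) standardGeneric("spectraMode"))

#' Grid dimensions of a raster scan
#'
#' @param x a [ScanGeometry] or [HyperMap]
#' @return integer vector \code{c(rows, cols)}
#' @export
setGeneric("gridDims", function(x) standardGeneric("gridDims"))
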