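#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors metadata "metadata<-" DataFrame SimpleList
NULL

.TISSUE_CLASSES <- c("normal_epidermis", "electrical_mark", "normal_dermis",
                     "background")

#' Raster scan geometry
#'
#' Physical geometry of a microscope raster scan: the scanned area, the
#' stage step between pixels, and the microscope aperture. The pixel grid
#' has \code{floor(area/step)} pixels along each axis.
#'
#' @slot areaX,areaY scanned area extent in micrometres
#' @slot step stage step in micrometres (> 0)
#' @slot aperture aperture edge length in micrometres (metadata only)
#' @export
setClass("ScanGeometry",
  representation(areaX = "numeric", areaY = "numeric",
                 step = "numeric", aperture = "numeric"),
  prototype(areaX = 140, areaY = 200, step = 10, aperture = 40),
  validity = function(object) {
    if (length(object@step) != 1L || object@step <= 0)
      return("step must be a single value > 0")
    if (object@areaX <= 0 || object@areaY <= 0)
      return("scan area must be positive")
    TRUE
  })

#' @param areaX,areaY scanned area in micrometres
#' @param step stage step in micrometres
#' @param aperture aperture size in micrometres
#' @return a \code{ScanGeometry} object
#' @rdname ScanGeometry-class
#' @examples
#' gridDims(scanGeometry())  # 14 x 20 pixels
#' @export
scanGeometry <- function(areaX = 140, areaY = 200, step = 10, aperture = 40) {
  new("ScanGeometry", areaX = areaX, areaY = areaY, step = step,
      aperture = aperture)
}

#' @rdname gridDims
#' @export
setMethod("gridDims", "ScanGeometry", function(x) {
  c(rows = as.integer(floor(x@areaX / x@step)),
    cols = as.integer(floor(x@areaY / x@step)))
})

setMethod("show", "ScanGeometry", function(object) {
  d <- gridDims(object)
  cat(sprintf("ScanGeometry: %g x %g um, step %g um, aperture %g um (%d x %d px)\n",
              object@areaX, object@areaY, object@step, object@aperture,
              d[1L], d[2L]))
})

#' Collection of spectra on a shared wavenumber grid
#'
#' A \code{SpectraSet} is a \linkS4class{SummarizedExperiment} whose rows are
#' wavenumber channels and whose columns are individual spectra. The
#' wavenumber axis lives in \code{rowData(x)$wavenumber} (strictly
#' ascending); per-spectrum class labels, study-split tags and optional
#' pixel coordinates live in \code{colData}. The spectral mode (raw
#' absorbance vs second derivative) is kept in \code{metadata(x)$mode}.
#'
#' @export
setClass("SpectraSet", contains = "SummarizedExperiment",
  validity = function(object) {
    wn <- rowData(object)$wavenumber
    if (is.null(wn))
      return("rowData must contain a 'wavenumber' column")
    if (nrow(object) > 1L && any(diff(wn) <= 0))
      return("wavenumbers must be strictly increasing")
    md <- metadata(object)$mode
    if (!is.null(md) && !md %in% c("absorbance", "second_derivative"))
      return("mode must be 'absorbance' or 'second_derivative'")
    TRUE
  })

#' Construct a SpectraSet
#'
#' @param spectra numeric matrix, channels x spectra
#' @param wavenumbers ascending numeric vector, one per channel (cm^-1)
#' @param labels optional character vector of class labels per spectrum
#' @param splits optional character vector of study-split tags per spectrum
#' @param mode \code{"absorbance"} (default) or \code{"second_derivative"}
#' @param pixels optional two-column matrix/data.frame of (row, col) pixel
#'   coordinates per spectrum
#' @return a [SpectraSet]
#' @examples
#' wn <- seq(900, 4000, by = 4)
#' m <- matrix(rnorm(length(wn) * 3, sd = 0.01), ncol = 3)
#' ss <- spectraSet(m, wn, labels = rep("normal_epidermis", 3))
#' dim(ss)
#' @export
spectraSet <- function(spectra, wavenumbers, labels = NULL, splits = NULL,
                       mode = "absorbance", pixels = NULL) {
  spectra <- as.matrix(spectra)
  if (nrow(spectra) != length(wavenumbers))
    stop("nrow(spectra) must equal length(wavenumbers)")
  n <- ncol(spectra)
  if (is.null(colnames(spectra)))
    colnames(spectra) <- sprintf("s%04d", seq_len(max(n, 1L))[seq_len(n)])
  cd <- DataFrame(row.names = colnames(spectra))
  cd$label <- if (is.null(labels)) rep(NA_character_, n) else as.character(labels)
  cd$split <- if (is.null(splits)) rep(NA_character_, n) else as.character(splits)
  if (!is.null(pixels)) {
    pixels <- as.matrix(pixels)
    cd$pixelRow <- as.integer(pixels[, 1L])
    cd$pixelCol <- as.integer(pixels[, 2L])
  }
  se <- SummarizedExperiment(
    assays = SimpleList(spectra = spectra),
    rowData = DataFrame(wavenumber = as.numeric(wavenumbers)),
    colData = cd,
    metadata = list(mode = mode))
  new("SpectraSet", se)
}

#' @rdname wavenumbers
#' @export
setMethod("wavenumbers", "SpectraSet",
          function(x) rowData(x)$wavenumber)

#' @rdname spectraMatrix
#' @export
setMethod("spectraMatrix", "SpectraSet",
          function(x) assay(x, "spectra"))

#' @rdname classLabels
#' @export
setMethod("classLabels", "SpectraSet",
          function(x) colData(x)$label)

#' @rdname splitTags
#' @export
setMethod("splitTags", "SpectraSet",
          function(x) colData(x)$split)

#' @rdname spectraMode
#' @export
setMethod("spectraMode", "SpectraSet",
          function(x) metadata(x)$mode)

setMethod("show", "SpectraSet", function(object) {
  wn <- wavenumbers(object)
  cat(sprintf("SpectraSet: %d spectra x %d channels (%g-%g cm^-1), mode=%s\n",
              ncol(object), nrow(object),
              if (length(wn)) min(wn) else NA, if (length(wn)) max(wn) else NA,
              spectraMode(object)))
  lb <- classLabels(object)
  if (!all(is.na(lb))) {
    tb <- table(lb, useNA = "no")
    cat("  classes:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "),
        "\n")
  }
})

#' Take a subset of spectra by study split
#'
#' @param x a [SpectraSet]
#' @param split one or more split tags to keep
#' @return a [SpectraSet] containing only the matching columns
#' @export
subsetBySplit <- function(x, split) {
  stopifnot(is(x, "SpectraSet"))
  x[, splitTags(x) %in% split]
}

#' Hyperspectral map
#'
#' A spatial grid of spectra from a raster scan: a \code{rows x cols x
#' channels} absorbance cube plus the scan geometry, and (for synthetic
#' maps) the ground-truth class of every pixel.
#'
#' @slot cube numeric array rows x cols x channels
#' @slot wavenumbers ascending numeric vector of channel wavenumbers
#' @slot geometry a [ScanGeometry]
#' @slot truth character matrix of true pixel classes, or NULL
#' @slot mode "absorbance" or "second_derivative"
#' @export
setClass("HyperMap",
  representation(cube = "array", wavenumbers = "numeric",
                 geometry = "ScanGeometry", truth = "ANY",
                 mode = "character"),
  prototype(mode = "absorbance", truth = NULL),
  validity = function(object) {
    d <- dim(object@cube)
    if (length(d) != 3L)
      return("cube must be a 3-d array (rows x cols x channels)")
    g <- gridDims(object@geometry)
    if (d[1L] != g[1L] || d[2L] != g[2L])
      return(sprintf("cube is %d x %d pixels but geometry implies %d x %d",
                     d[1L], d[2L], g[1L], g[2L]))
    if (d[3L] != length(object@wavenumbers))
      return("third cube dimension must match length(wavenumbers)")
    if (any(diff(object@wavenumbers) <= 0))
      return("wavenumbers must be strictly increasing")
    if (!is.null(object@truth) &&
        !identical(dim(as.matrix(object@truth)), d[1:2]))
      return("truth dims must match cube pixel grid")
    TRUE
  })

#' @param cube numeric array rows x cols x channels
#' @param wavenumbers channel wavenumbers (cm^-1, ascending)
#' @param geometry a [ScanGeometry]
#' @param truth optional character matrix of true pixel classes
#' @param mode spectral mode of the cube values
#' @return a \code{HyperMap}
#' @rdname HyperMap-class
#' @export
hyperMap <- function(cube, wavenumbers, geometry, truth = NULL,
                     mode = "absorbance") {
  new("HyperMap", cube = cube, wavenumbers = as.numeric(wavenumbers),
      geometry = geometry, truth = truth, mode = mode)
}

#' @rdname wavenumbers
#' @export
setMethod("wavenumbers", "HyperMap", function(x) x@wavenumbers)

#' @rdname gridDims
#' @export
setMethod("gridDims", "HyperMap", function(x) gridDims(x@geometry))

#' @rdname spectraMode
#' @export
setMethod("spectraMode", "HyperMap", function(x) x@mode)

setMethod("show", "HyperMap", function(object) {
  d <- dim(object@cube)
  cat(sprintf("HyperMap: %d x %d pixels, %d channels, mode=%s%s\n",
              d[1L], d[2L], d[3L], object@mode,
              if (is.null(object@truth)) "" else ", with truth labels"))
})

#' Flatten a HyperMap into a SpectraSet
#'
#' Pixels are unrolled column-major (all rows of column 1, then column 2,
#' ...); pixel coordinates are preserved in \code{colData} so the map can be
#' reassembled.
#'
#' @param x a [HyperMap]
#' @return a [SpectraSet] with one column per pixel
#' @export
flattenMap <- function(x) {
  stopifnot(is(x, "HyperMap"))
  d <- dim(x@cube)
  m <- matrix(aperm(x@cube, c(3L, 1L, 2L)), nrow = d[3L])
  px <- cbind(rep(seq_len(d[1L]), times = d[2L]),
              rep(seq_len(d[2L]), each = d[1L]))
  labels <- if (is.null(x@truth)) NULL else as.character(x@truth)[
    px[, 1L] + (px[, 2L] - 1L) * d[1L]]
  spectraSet(m, x@wavenumbers, labels = labels, mode = x@mode, pixels = px)
}

#' Per-pixel categorical class map
#'
#' The result of classifying a [HyperMap]: a matrix of tissue-class labels
#' plus the fixed pseudo-color legend used for rendering (yellow =
#' electrical mark, light blue = normal epidermis, brown = normal dermis,
#' dark blue = background).
#'
#' @slot labels character matrix of class labels, rows x cols
#' @slot legend named character vector of hex colors, one per class
#' @export
setClass("ClassMap",
  representation(labels = "matrix", legend = "character"),
  validity = function(object) {
    if (!all(object@labels %in% names(object@legend)))
      return("all labels must have a legend color")
    TRUE
  })

#' Fixed class-map legend
#'
#' @return named vector of hex colors for the four map classes
#' @export
classMapLegend <- function() {
  c(electrical_mark  = "#FFFF00",  # yellow
    normal_epidermis = "#ADD8E6",  # light blue
    normal_dermis    = "#8B4513",  # brown
    background       = "#00008B")  # dark blue
}

#' @param labels character matrix of per-pixel class labels
#' @param legend named character vector of hex colors
#' @return a \code{ClassMap}
#' @rdname ClassMap-class
#' @export
classMap <- function(labels, legend = classMapLegend()) {
  new("ClassMap", labels = labels, legend = legend)
}

#' @rdname classLabels
#' @export
setMethod("classLabels", "ClassMap", function(x) x@labels)

setMethod("show", "ClassMap", function(object) {
  cat(sprintf("ClassMap: %d x %d pixels\n", nrow(object@labels),
              ncol(object@labels)))
  tb <- table(object@labels)
  cat(" ", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
})
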