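#' Default wavenumber grid
#'
#' Mid-IR absorbance grid, 900-4000 cm^-1 ascending at 4 cm^-1 spacing.
#' This is finer than a 16 cm^-1 instrument resolution, emulating the
#' standard zero-filled interpolation of FT instruments, and gives enough
#' points in the Amide I window (1710-1585 cm^-1) for a 9-point derivative
#' filter to be meaningful.
#'
#' @return ascending numeric vector of wavenumbers (cm^-1)
#' @export
defaultGrid <- function() seq(900, 4000, by = 4)

#' Spectral class profile
#'
#' Mean band composition of one tissue class plus its within-class
#' variability: each band is a Gaussian or Lorentzian component with a
#' center (cm^-1), full width at half maximum (cm^-1) and mean amplitude
#' (absorbance). Per-spectrum amplitudes are jittered multiplicatively
#' with relative SD \code{amplitudeCv}; additive detector noise has SD
#' \code{noiseSd} (absorbance units).
#'
#' @slot name class name
#' @slot bands data.frame with columns center, fwhm, amplitude, shape
#' @slot amplitudeCv relative SD of per-spectrum amplitude jitter (>= 0)
#' @slot noiseSd additive noise SD in absorbance units (>= 0)
#' @export
setClass("ClassProfile",
  representation(name = "character", bands = "data.frame",
                 amplitudeCv = "numeric", noiseSd = "numeric"),
  validity = function(object) {
    b <- object@bands
    need <- c("center", "fwhm", "amplitude", "shape")
    if (!all(need %in% names(b)))
      return("bands must have columns center, fwhm, amplitude, shape")
    if (nrow(b)) {
      if (any(b$fwhm <= 0)) return("band fwhm must be > 0")
      if (any(b$amplitude < 0)) return("band amplitudes must be >= 0")
      if (any(b$center < 900 | b$center > 4000))
        return("band centers must lie within 900-4000 cm^-1")
      if (!all(b$shape %in% c("gaussian", "lorentzian")))
        return("band shape must be 'gaussian' or 'lorentzian'")
    }
    if (object@amplitudeCv < 0 || object@noiseSd < 0)
      return("amplitudeCv and noiseSd must be >= 0")
    TRUE
  })

#' @param name class name
#' @param bands band table (see [bandComponents()])
#' @param amplitudeCv relative SD of amplitude jitter
#' @param noiseSd additive noise SD (absorbance)
#' @return a \code{ClassProfile}
#' @rdname ClassProfile-class
#' @export
classProfile <- function(name, bands, amplitudeCv = 0.10, noiseSd = 0.005) {
  new("ClassProfile", name = name, bands = bands,
      amplitudeCv = amplitudeCv, noiseSd = noiseSd)
}

#' Build a band table
#'
#' @param center band centers (cm^-1)
#' @param fwhm full widths at half maximum (cm^-1)
#' @param amplitude mean peak amplitudes (absorbance)
#' @param shape "gaussian" (default) or "lorentzian", recycled
#' @return data.frame usable as the \code{bands} slot of a [ClassProfile]
#' @export
bandComponents <- function(center, fwhm, amplitude, shape = "gaussian") {
  data.frame(center = center, fwhm = fwhm, amplitude = amplitude,
             shape = rep_len(shape, length(center)))
}

#' Scatter/baseline distortion model
#'
#' Random per-spectrum distortions applied on top of the pure band sum:
#' an additive offset, a multiplicative (log-normal) path-length scale and
#' a linear + quadratic baseline in the rescaled wavenumber coordinate
#' nu* in [-1, 1] (the same basis EMSC fits). All spreads are standard
#' deviations; zero everywhere gives the identity distortion.
#'
#' @slot offsetSd SD of the additive offset (absorbance)
#' @slot scaleLogSd SD of log(multiplicative scale); realized scale is
#'   always > 0
#' @slot slopeSd SD of the linear baseline coefficient (per unit nu*)
#' @slot curvatureSd SD of the quadratic baseline coefficient
#' @export
setClass("ScatterModel",
  representation(offsetSd = "numeric", scaleLogSd = "numeric",
                 slopeSd = "numeric", curvatureSd = "numeric"),
  validity = function(object) {
    if (any(c(object@offsetSd, object@scaleLogSd, object@slopeSd,
              object@curvatureSd) < 0))
      return("all scatter spreads must be >= 0")
    TRUE
  })

#' @param offsetSd,scaleLogSd,slopeSd,curvatureSd spreads (see slots)
#' @return a \code{ScatterModel}
#' @rdname ScatterModel-class
#' @export
scatterModel <- function(offsetSd = 0.02, scaleLogSd = 0.15,
                         slopeSd = 0.01, curvatureSd = 0.005) {
  new("ScatterModel", offsetSd = offsetSd, scaleLogSd = scaleLogSd,
      slopeSd = slopeSd, curvatureSd = curvatureSd)
}

#' Zero scatter model (identity distortion)
#' @return a [ScatterModel] with all spreads 0
#' @export
noScatter <- function() scatterModel(0, 0, 0, 0)

#' Study design: how many spectra go into each split
#'
#' Per-class spectrum counts for the four stages of the study: PCA
#' calibration (electrical mark vs normal epidermis), PLS calibration
#' (three tissue classes), an internal prediction set drawn from the
#' calibration material but excluded from model fitting, and an external
#' validation set. The defaults reproduce the published design: 35/46
#' PCA spectra, 35/34/27 PLS calibration spectra, 48 internal-prediction
#' spectra and 17/20/14 external-validation spectra.
#'
#' @slot pcaCal named counts for classes electrical_mark, normal_epidermis
#' @slot plsCal named counts for electrical_mark, normal_epidermis,
#'   normal_dermis
#' @slot internalPred named counts for the three classes (total 48 by
#'   default, split 16/16/16)
#' @slot externalVal named counts for the three classes
#' @slot seed integer seed driving every stochastic draw of the study
#' @export
setClass("StudyDesign",
  representation(pcaCal = "numeric", plsCal = "numeric",
                 internalPred = "numeric", externalVal = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (any(c(object@pcaCal, object@plsCal, object@internalPred,
              object@externalVal) < 0))
      return("all design counts must be >= 0")
    TRUE
  })

#' @param pcaCal,plsCal,internalPred,externalVal named per-class counts
#' @param seed integer seed
#' @return a \code{StudyDesign}
#' @rdname StudyDesign-class
#' @examples
#' d <- studyDesign()
#' sum(d@internalPred)  # 48
#' @export
studyDesign <- function(
    pcaCal = c(electrical_mark = 35, normal_epidermis = 46),
    plsCal = c(electrical_mark = 35, normal_epidermis = 34,
               normal_dermis = 27),
    internalPred = c(electrical_mark = 16, normal_epidermis = 16,
                     normal_dermis = 16),
    externalVal = c(electrical_mark = 17, normal_epidermis = 20,
                    normal_dermis = 14),
    seed = 20170124L) {
  new("StudyDesign", pcaCal = pcaCal, plsCal = plsCal,
      internalPred = internalPred, externalVal = externalVal,
      seed = as.integer(seed))
}

#' Default band library for the four map classes
#'
#' Encodes the qualitative Amide I contrasts between tissue classes as
#' generator parameters. Normal epidermis is dominated by the alpha-helix
#' band at 1650 cm^-1 with a clear antiparallel beta-sheet component at
#' 1695 cm^-1; the electrical mark shows elevated beta-sheet (1619 cm^-1)
#' and beta-turn (1681 cm^-1) with reduced 1650/1695 intensity; normal
#' dermis is collagen-like, with a strong 1660 cm^-1 band and prominent
#' amide II / amide III bands. All tissue profiles carry additional bands
#' outside the Amide I window (amide II ~1550, CH bending ~1455, amide
#' III ~1240, CH stretch ~2925, amide A ~3290 cm^-1) so that windowing to
#' 1710-1585 cm^-1 discards real signal. The background profile has no
#' bands: its pure spectrum is identically zero.
#'
#' @param amplitudeCv relative SD of per-spectrum amplitude jitter
#' @param noiseSd additive noise SD in absorbance units
#' @return named list of [ClassProfile] objects
#' @export
defaultBandLibrary <- function(amplitudeCv = 0.10, noiseSd = 0.005) {
  common <- function(amide2, ch, amide3) {
    bandComponents(center    = c(amide2[1], 1455, 1240, 2925, 3290),
                   fwhm      = c(amide2[2],   30,   40,   60,  150),
                   amplitude = c(amide2[3],  ch, amide3, 0.30, 0.55))
  }
  epi <- rbind(
    bandComponents(c(1650, 1695, 1619, 1681),
                   c(28, 20, 20, 20),
                   c(1.00, 0.40, 0.10, 0.10)),
    common(c(1548, 40, 0.55), 0.25, 0.18))
  ele <- rbind(
    bandComponents(c(1650, 1695, 1619, 1681),
                   c(28, 20, 20, 20),
                   c(0.55, 0.12, 0.75, 0.50)),
    common(c(1548, 40, 0.50), 0.25, 0.18))
  der <- rbind(
    bandComponents(c(1660, 1633),
                   c(30, 24),
                   c(0.95, 0.35)),
    common(c(1550, 40, 0.70), 0.30, 0.45))
  bg <- bandComponents(numeric(0), numeric(0), numeric(0), character(0))
  list(
    normal_epidermis = classProfile("normal_epidermis", epi,
                                    amplitudeCv, noiseSd),
    electrical_mark  = classProfile("electrical_mark", ele,
                                    amplitudeCv, noiseSd),
    normal_dermis    = classProfile("normal_dermis", der,
                                    amplitudeCv, noiseSd),
    background       = classProfile("background", bg, 0, noiseSd))
}

## Evaluate one band component on the grid.
.bandValues <- function(center, fwhm, amplitude, shape, grid) {
  if (shape == "gaussian") {
    sigma <- fwhm / (2 * sqrt(2 * log(2)))
    amplitude * exp(-0.5 * ((grid - center) / sigma)^2)
  } else {
    hw <- fwhm / 2
    amplitude * hw^2 / ((grid - center)^2 + hw^2)
  }
}

#' Pure (noise-free, scatter-free) class spectrum
#'
#' The deterministic sum of a profile's band components on a grid; the
#' expected value of [synthSpectrum()] with zero scatter and noise and no
#' amplitude jitter.
#'
#' @param profile a [ClassProfile]
#' @param grid ascending wavenumber vector (cm^-1)
#' @return numeric absorbance vector, one value per grid point
#' @export
bandSum <- function(profile, grid) {
  stopifnot(is(profile, "ClassProfile"))
  if (length(grid) == 0L) stop("empty wavenumber grid")
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  v <- numeric(length(grid))
  b <- profile@bands
  for (i in seq_len(nrow(b)))
    v <- v + .bandValues(b$center[i], b$fwhm[i], b$amplitude[i],
                         b$shape[i], grid)
  v
}

## nu rescaled to [-1, 1] over the grid span: the baseline basis shared by
## the generator and the EMSC fit.
.nuStar <- function(grid) {
  if (length(grid) == 1L) return(0)
  2 * (grid - min(grid)) / (max(grid) - min(grid)) - 1
}

#' Draw one synthetic spectrum
#'
#' One realization of \code{scale * sum(bands) + offset + slope*nu* +
#' curvature*nu*^2 + noise}, where band amplitudes are jittered with
#' relative SD \code{amplitudeCv}, the multiplicative scale is log-normal,
#' and nu* is the wavenumber rescaled to [-1, 1]. Uses the current RNG
#' state; with [noScatter()] and \code{noiseSd = 0} and
#' \code{amplitudeCv = 0} the result is the deterministic [bandSum()].
#'
#' @param profile a [ClassProfile]
#' @param grid ascending wavenumber vector (cm^-1)
#' @param scatter a [ScatterModel]
#' @return numeric absorbance vector
#' @export
synthSpectrum <- function(profile, grid, scatter = scatterModel()) {
  stopifnot(is(profile, "ClassProfile"), is(scatter, "ScatterModel"))
  if (length(grid) == 0L) stop("empty wavenumber grid")
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  b <- profile@bands
  v <- numeric(length(grid))
  for (i in seq_len(nrow(b))) {
    amp <- b$amplitude[i]
    if (profile@amplitudeCv > 0 && amp > 0)
      amp <- amp * max(0, 1 + rnorm(1, sd = profile@amplitudeCv))
    v <- v + .bandValues(b$center[i], b$fwhm[i], amp, b$shape[i], grid)
  }
  scale <- exp(rnorm(1, sd = scatter@scaleLogSd))
  offset <- rnorm(1, sd = scatter@offsetSd)
  slope <- rnorm(1, sd = scatter@slopeSd)
  curv <- rnorm(1, sd = scatter@curvatureSd)
  ns <- .nuStar(grid)
  out <- scale * v + offset + slope * ns + curv * ns^2
  if (profile@noiseSd > 0)
    out <- out + rnorm(length(grid), sd = profile@noiseSd)
  out
}

#' Simulate a complete study dataset
#'
#' Draws every spectrum of the study design with its class profile and
#' tags it with its split (\code{pca_cal}, \code{pls_cal},
#' \code{internal_pred}, \code{external_val}). All randomness flows from
#' \code{design@seed}; identical designs give bit-identical datasets.
#'
#' @param design a [StudyDesign]
#' @param library named list of [ClassProfile] (default
#'   [defaultBandLibrary()])
#' @param grid wavenumber grid (default [defaultGrid()])
#' @param scatter a [ScatterModel]
#' @return a [SpectraSet] with labels and split tags
#' @examples
#' ss <- synthDataset(studyDesign())
#' table(splitTags(ss), classLabels(ss))
#' @export
synthDataset <- function(design = studyDesign(),
                         library = defaultBandLibrary(),
                         grid = defaultGrid(),
                         scatter = scatterModel()) {
  stopifnot(is(design, "StudyDesign"))
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(design@seed)
  splits <- list(pca_cal = design@pcaCal, pls_cal = design@plsCal,
                 internal_pred = design@internalPred,
                 external_val = design@externalVal)
  cols <- list(); labs <- character(0); tags <- character(0)
  for (sp in names(splits)) {
    counts <- splits[[sp]]
    for (cl in names(counts)) {
      n <- counts[[cl]]
      if (n == 0) next
      prof <- library[[cl]]
      if (is.null(prof)) stop("no profile in library for class ", cl)
      for (k in seq_len(n))
        cols[[length(cols) + 1L]] <- synthSpectrum(prof, grid, scatter)
      labs <- c(labs, rep(cl, n))
      tags <- c(tags, rep(sp, n))
    }
  }
  m <- if (length(cols)) do.call(cbind, cols) else
    matrix(numeric(0), nrow = length(grid), ncol = 0)
  spectraSet(m, grid, labels = labs, splits = tags)
}

#' Built-in map layouts
#'
#' Ground-truth pixel layouts for synthetic hyperspectral maps.
#' \code{"electrical_lesion"}: background above, an epidermal band with a
#' central electrical-mark region, dermis below. \code{"normal_skin"}: the
#' same skin architecture without any lesion.
#'
#' @param name \code{"electrical_lesion"} or \code{"normal_skin"}
#' @param geometry a [ScanGeometry]
#' @return character matrix of class names, rows x cols
#' @export
mapLayout <- function(name = c("electrical_lesion", "normal_skin"),
                      geometry = scanGeometry()) {
  name <- match.arg(name)
  d <- gridDims(geometry)
  nr <- d[[1L]]; nc <- d[[2L]]
  lay <- matrix("normal_dermis", nr, nc)
  bgRows <- seq_len(max(1L, round(nr * 0.2)))
  epiRows <- seq(max(bgRows) + 1L, min(nr, max(bgRows) + max(1L, round(nr * 0.3))))
  lay[bgRows, ] <- "background"
  lay[epiRows, ] <- "normal_epidermis"
  if (name == "electrical_lesion") {
    lesionCols <- seq(max(1L, floor(nc * 0.3)), min(nc, ceiling(nc * 0.7)))
    lay[epiRows, lesionCols] <- "electrical_mark"
  }
  lay
}

#' Simulate a hyperspectral map
#'
#' Draws one spectrum per pixel from the pixel's class profile. Pixels are
#' simulated independently (the instrumental aperture overlap between
#' neighbouring pixels is not emulated).
#'
#' @param layout a character matrix of class names, or a layout name
#'   accepted by [mapLayout()]
#' @param geometry a [ScanGeometry]; its grid must match \code{layout}
#' @param library named list of [ClassProfile]
#' @param grid wavenumber vector
#' @param scatter a [ScatterModel]
#' @param seed integer seed for the map draw
#' @return a [HyperMap] with truth labels
#' @export
synthMap <- function(layout = "electrical_lesion",
                     geometry = scanGeometry(),
                     library = defaultBandLibrary(),
                     grid = defaultGrid(),
                     scatter = scatterModel(),
                     seed = 20170124L) {
  if (is.character(layout) && length(layout) == 1L)
    layout <- mapLayout(layout, geometry)
  layout <- as.matrix(layout)
  d <- gridDims(geometry)
  if (nrow(layout) != d[[1L]] || ncol(layout) != d[[2L]])
    stop(sprintf("layout is %d x %d but geometry implies %d x %d",
                 nrow(layout), ncol(layout), d[[1L]], d[[2L]]))
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  cube <- array(0, dim = c(nrow(layout), ncol(layout), length(grid)))
  for (j in seq_len(ncol(layout)))
    for (i in seq_len(nrow(layout))) {
      prof <- library[[layout[i, j]]]
      if (is.null(prof)) stop("no profile in library for class ", layout[i, j])
      cube[i, j, ] <- synthSpectrum(prof, grid, scatter)
    }
  hyperMap(cube, grid, geometry, truth = layout)
}
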