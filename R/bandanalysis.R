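#' Default Amide I secondary-structure band assignments
#'
#' The four protein secondary-structure components resolved in the Amide I
#' region of second-derivative skin spectra: alpha-helix (1650 cm^-1),
#' antiparallel beta-sheet (1695 cm^-1), beta-sheet (1619 cm^-1) and
#' beta-turn (1681 cm^-1). The matching tolerance defaults to +/- 8 cm^-1
#' (two grid steps on the default grid): observed loading and band minima
#' drift a few cm^-1 from the nominal centres, so exact matching would be
#' wrong.
#'
#' @param tolerance matching tolerance in cm^-1 (> 0)
#' @return data.frame with columns structure, center, tolerance
#' @export
defaultBandAssignments <- function(tolerance = 8) {
  stopifnot(tolerance > 0)
  data.frame(
    structure = c("alpha_helix", "antiparallel_beta_sheet", "beta_sheet",
                  "beta_turn"),
    center = c(1650, 1695, 1619, 1681),
    tolerance = tolerance)
}

#' Find negative peaks in a second-derivative spectrum
#'
#' Band centres appear as negative minima in a second-derivative spectrum.
#' Every interior channel that is a strict local minimum with a negative
#' value is reported; its position is refined by fitting a parabola
#' through the three surrounding points (sub-grid resolution matters
#' because the 4 cm^-1 grid is coarse relative to the 2-3 cm^-1 band
#' distinctions of interest). Depth is the magnitude of the interpolated
#' minimum. Peaks are returned sorted by depth, deepest first.
#'
#' @param values numeric second-derivative trace
#' @param wavenumbers matching wavenumber vector (ascending)
#' @return data.frame with columns wavenumber, depth (possibly 0 rows)
#' @export
findNegativePeaks <- function(values, wavenumbers) {
  stopifnot(length(values) == length(wavenumbers))
  n <- length(values)
  out <- data.frame(wavenumber = numeric(0), depth = numeric(0))
  if (n < 3L) return(out)
  for (i in 2:(n - 1L)) {
    if (values[i] < 0 && values[i] < values[i - 1L] &&
        values[i] < values[i + 1L]) {
      y0 <- values[i - 1L]; y1 <- values[i]; y2 <- values[i + 1L]
      denom <- y0 - 2 * y1 + y2
      delta <- if (denom > 0) 0.5 * (y0 - y2) / denom else 0
      delta <- max(-0.5, min(0.5, delta))
      step <- wavenumbers[i + 1L] - wavenumbers[i]
      pos <- wavenumbers[i] + delta * step
      depth <- abs(y1 - 0.25 * (y0 - y2) * delta)
      out <- rbind(out, data.frame(wavenumber = pos, depth = depth))
    }
  }
  out[order(-out$depth), , drop = FALSE]
}

#' Peaks of every spectrum in a set
#'
#' @param set a [SpectraSet] in second-derivative mode
#' @return data.frame with columns spectrum, wavenumber, depth
#' @export
findNegativePeaksSet <- function(set) {
  stopifnot(is(set, "SpectraSet"))
  if (!identical(spectraMode(set), "second_derivative"))
    stop("peak finding requires a second-derivative SpectraSet")
  X <- spectraMatrix(set)
  wn <- wavenumbers(set)
  res <- lapply(seq_len(ncol(X)), function(j) {
    p <- findNegativePeaks(X[, j], wn)
    if (nrow(p)) cbind(spectrum = colnames(X)[j], p) else NULL
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(spectrum = character(0), wavenumber = numeric(0),
                      depth = numeric(0))
  out
}

#' Assign detected peaks to secondary-structure bands
#'
#' Greedy deepest-first matching: walking the peak list from the deepest
#' peak down, each peak is given to the nearest still-unassigned structure
#' whose nominal centre lies within its tolerance. Each structure receives
#' at most one peak and each peak is assigned at most once; structures
#' with no peak in range are absent from the result.
#'
#' @param peaks data.frame from [findNegativePeaks()]
#' @param assignments data.frame from [defaultBandAssignments()]
#' @return data.frame with columns structure, wavenumber, depth (one row
#'   per assigned structure)
#' @export
assignBands <- function(peaks, assignments = defaultBandAssignments()) {
  peaks <- peaks[order(-peaks$depth), , drop = FALSE]
  taken <- rep(FALSE, nrow(assignments))
  rows <- list()
  for (i in seq_len(nrow(peaks))) {
    d <- abs(assignments$center - peaks$wavenumber[i])
    ok <- which(!taken & d <= assignments$tolerance)
    if (!length(ok)) next
    j <- ok[which.min(d[ok])]
    taken[j] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      structure = assignments$structure[j],
      wavenumber = peaks$wavenumber[i],
      depth = peaks$depth[i])
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(structure = character(0), wavenumber = numeric(0),
                      depth = numeric(0))
  out
}

#' Per-structure intensity image of a hyperspectral map
#'
#' For each pixel, a scalar measuring the contribution of one
#' secondary-structure band: either the raw absorbance at the channel
#' nearest the nominal band centre (\code{"absorbance_peak"}; use on an
#' absorbance-mode map) or the depth of the second-derivative peak
#' assigned to that structure, 0 when no peak is assigned
#' (\code{"second_derivative_depth"}; use on a second-derivative map).
#' The map must already be preprocessed consistently with the chosen mode.
#'
#' @param map a [HyperMap]
#' @param structure one of the structures in \code{assignments}
#' @param mode intensity definition (see above)
#' @param assignments band table from [defaultBandAssignments()]
#' @return numeric matrix, rows x cols
#' @export
structureIntensityMap <- function(map, structure,
    mode = c("second_derivative_depth", "absorbance_peak"),
    assignments = defaultBandAssignments()) {
  stopifnot(is(map, "HyperMap"))
  mode <- match.arg(mode)
  row <- assignments[assignments$structure == structure, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown structure: ", structure)
  wn <- wavenumbers(map)
  if (row$center < min(wn) || row$center > max(wn))
    stop("band centre lies outside the wavenumber grid")
  d <- dim(map@cube)
  img <- matrix(0, d[1L], d[2L])
  if (mode == "absorbance_peak") {
    ch <- which.min(abs(wn - row$center))
    img[] <- map@cube[, , ch]
  } else {
    for (j in seq_len(d[2L]))
      for (i in seq_len(d[1L])) {
        pk <- findNegativePeaks(map@cube[i, j, ], wn)
        asg <- assignBands(pk, row)
        img[i, j] <- if (nrow(asg)) asg$depth[1L] else 0
      }
  }
  img
}

#' Jet color ramp
#'
#' Blue-to-red rainbow used for intensity rendering: blue marks the lowest
#' relative concentration and red the highest.
#'
#' @param n number of colors
#' @return character vector of hex colors
#' @export
jetColors <- function(n = 256L) {
  grDevices::colorRampPalette(
    c("#00007F", "blue", "#007FFF", "cyan", "#7FFF7F", "yellow",
      "#FF7F00", "red", "#7F0000"))(n)
}

#' Render an intensity image as a PNG
#'
#' Scales the image min-to-max onto the jet ramp (a constant image renders
#' in the lowest color) and writes one image pixel per map pixel, upscaled
#' by an integer factor.
#'
#' @param img numeric matrix from [structureIntensityMap()]
#' @param path output PNG path
#' @param upscale integer pixel replication factor
#' @return invisibly, the path
#' @export
renderIntensityMap <- function(img, path, upscale = 10L) {
  pal <- jetColors()
  rng <- range(img)
  idx <- if (rng[2] > rng[1]) {
    1L + as.integer(round((img - rng[1]) / (rng[2] - rng[1]) * 255))
  } else matrix(1L, nrow(img), ncol(img))
  rgb <- grDevices::col2rgb(pal[idx]) / 255
  arr <- array(0, dim = c(nrow(img), ncol(img), 3L))
  for (k in 1:3) arr[, , k] <- matrix(rgb[k, ], nrow(img), ncol(img))
  up <- function(a) a[rep(seq_len(nrow(a)), each = upscale),
                      rep(seq_len(ncol(a)), each = upscale), , drop = FALSE]
  png::writePNG(up(arr), path)
  invisible(path)
}
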