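#' Write a SpectraSet as CSV
#'
#' Column 1 is the wavenumber, remaining columns are spectra (header row =
#' spectrum IDs); values are written with 12 significant digits so a
#' write/read round trip is lossless at that precision. A sidecar
#' \code{<path>.labels.csv} with columns id, label, split is written when
#' any label or split is present.
#'
#' @param set a [SpectraSet]
#' @param path output CSV path
#' @return invisibly, the path
#' @export
writeSpectraCsv <- function(set, path) {
  stopifnot(is(set, "SpectraSet"))
  m <- spectraMatrix(set)
  df <- data.frame(wavenumber = format(wavenumbers(set), digits = 12,
                                       trim = TRUE, scientific = FALSE))
  for (j in seq_len(ncol(m)))
    df[[colnames(m)[j]]] <- format(m[, j], digits = 12, trim = TRUE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  lb <- classLabels(set); sp <- splitTags(set)
  if (!all(is.na(lb)) || !all(is.na(sp))) {
    side <- data.frame(id = colnames(m), label = lb, split = sp)
    write.csv(side, paste0(path, ".labels.csv"), row.names = FALSE,
              quote = FALSE)
  }
  invisible(path)
}

#' Read a SpectraSet from CSV
#'
#' Expects the layout of [writeSpectraCsv()]. A descending wavenumber grid
#' is reversed (with a warning) so the returned set is always ascending;
#' duplicate wavenumbers and non-numeric cells are errors.
#'
#' @param path CSV path
#' @param mode spectral mode to stamp on the result
#' @return a [SpectraSet]
#' @export
readSpectraCsv <- function(path, mode = "absorbance") {
  df <- read.csv(path, check.names = FALSE)
  if (names(df)[1L] != "wavenumber")
    stop("first column must be named 'wavenumber'")
  for (j in seq_along(df))
    if (!is.numeric(df[[j]]))
      stop("non-numeric cells in column '", names(df)[j], "'")
  wn <- df[[1L]]
  dup <- wn[duplicated(wn)]
  if (length(dup))
    stop("duplicate wavenumber value(s): ",
         paste(unique(dup), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (length(wn) > 1L && all(diff(wn) < 0)) {
    warning("descending wavenumber grid: reversing on read")
    wn <- rev(wn); m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  }
  labels <- splits <- NULL
  side <- paste0(path, ".labels.csv")
  if (file.exists(side)) {
    sd <- read.csv(side)
    idx <- match(colnames(m), sd$id)
    labels <- sd$label[idx]; splits <- sd$split[idx]
  }
  spectraSet(m, wn, labels = labels, splits = splits, mode = mode)
}

#' Read a JCAMP-DX spectrum
#'
#' Minimal reader for single-spectrum JCAMP-DX files in AFFN (plain
#' decimal) form with either \code{##XYDATA=(X++(Y..Y))} or
#' \code{##XYPOINTS=(XY..XY)} blocks. \code{XFACTOR}/\code{YFACTOR} are
#' applied; \code{FIRSTX}/\code{LASTX}/\code{NPOINTS} are honoured and
#' checked. Compressed dialects (SQZ/DIF/DUP) are rejected with an
#' explicit error.
#'
#' @param path JCAMP-DX file path
#' @return list with \code{wavenumbers}, \code{values}, \code{title}
#' @export
readJcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  getLdr <- function(key) {
    hit <- grep(paste0("^##", key, "="), lines, ignore.case = TRUE,
                value = TRUE)
    if (!length(hit)) return(NULL)
    sub(paste0("^##", key, "="), "", hit[1L], ignore.case = TRUE)
  }
  num <- function(key, default = NA_real_) {
    v <- getLdr(key)
    if (is.null(v)) default else as.numeric(v)
  }
  xf <- num("XFACTOR", 1); yf <- num("YFACTOR", 1)
  npt <- num("NPOINTS"); firstx <- num("FIRSTX"); lastx <- num("LASTX")
  xyStart <- grep("^##(XYDATA|XYPOINTS)=", lines, ignore.case = TRUE)
  if (!length(xyStart)) stop("no XYDATA or XYPOINTS block found")
  header <- lines[xyStart[1L]]
  isPoints <- grepl("^##XYPOINTS", header, ignore.case = TRUE)
  body <- lines[(xyStart[1L] + 1L):length(lines)]
  endIdx <- grep("^##", body)
  if (length(endIdx)) body <- body[seq_len(endIdx[1L] - 1L)]
  if (any(grepl("[A-DF-Zj-s%@]", gsub("[eE][+-]?[0-9]+", "", body))))
    stop("unsupported JCAMP-DX dialect: SQZ/DIF compressed data ",
         "(only AFFN is supported)")
  if (isPoints) {
    toks <- as.numeric(unlist(strsplit(trimws(body), "[,;[:space:]]+")))
    if (anyNA(toks) || length(toks) %% 2L != 0L)
      stop("malformed XYPOINTS data")
    x <- toks[seq(1L, length(toks), 2L)] * xf
    y <- toks[seq(2L, length(toks), 2L)] * yf
  } else {
    x <- numeric(0); y <- numeric(0)
    for (ln in body) {
      toks <- as.numeric(unlist(strsplit(trimws(ln), "[,;[:space:]]+")))
      if (!length(toks)) next
      if (anyNA(toks)) stop("malformed XYDATA line: ", ln)
      ny <- length(toks) - 1L
      if (ny < 1L) stop("XYDATA line with no Y values: ", ln)
      x0 <- toks[1L] * xf
      dx <- if (!is.na(npt) && npt > 1L && !is.na(firstx) && !is.na(lastx))
        (lastx - firstx) * xf / (npt - 1L) else NA_real_
      if (is.na(dx)) stop("XYDATA requires FIRSTX, LASTX and NPOINTS")
      x <- c(x, x0 + dx * (seq_len(ny) - 1L))
      y <- c(y, toks[-1L] * yf)
    }
  }
  if (!is.na(npt) && length(y) != npt)
    stop(sprintf("NPOINTS=%d but %d data points found", npt, length(y)))
  ord <- order(x)
  list(wavenumbers = x[ord], values = y[ord],
       title = getLdr("TITLE") %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a HyperMap container
#'
#' Serializes the map as a named list of arrays \code{cube},
#' \code{wavenumbers}, \code{truth_labels} and \code{geometry} in a single
#' RDS file.
#'
#' @param map a [HyperMap]
#' @param path output path
#' @return invisibly, the path
#' @export
writeHyperMap <- function(map, path) {
  stopifnot(is(map, "HyperMap"))
  saveRDS(list(cube = map@cube, wavenumbers = map@wavenumbers,
               truth_labels = map@truth,
               geometry = c(areaX = map@geometry@areaX,
                            areaY = map@geometry@areaY,
                            step = map@geometry@step,
                            aperture = map@geometry@aperture),
               mode = map@mode),
          path)
  invisible(path)
}

#' Read a HyperMap container
#'
#' @param path path written by [writeHyperMap()]
#' @return a [HyperMap]
#' @export
readHyperMap <- function(path) {
  x <- readRDS(path)
  g <- x$geometry
  hyperMap(x$cube, x$wavenumbers,
           scanGeometry(g[["areaX"]], g[["areaY"]], g[["step"]],
                        g[["aperture"]]),
           truth = x$truth_labels, mode = x$mode %||% "absorbance")
}
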