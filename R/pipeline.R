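#' Default pipeline configuration
#'
#' Nested list mirroring the stages: generator (study design and scatter
#' model), preprocessing (EMSC degree 2, 9-point order-3 Savitzky-Golay,
#' Amide I window 1710-1585 cm^-1), model (factor cap 10, Y thresholds
#' 1.5/2.5), and map (scan geometry and background rule). The instrument
#' resolution (16 cm^-1, 8 scans) is recorded as metadata only; the grid
#' itself is the finer zero-filled 4 cm^-1 axis.
#'
#' @param seed integer seed driving every stochastic stage
#' @return nested configuration list
#' @export
defaultPipelineConfig <- function(seed = 20170124L) {
  list(
    seed = as.integer(seed),
    generator = list(
      design = list(
        pca_cal = c(electrical_mark = 35, normal_epidermis = 46),
        pls_cal = c(electrical_mark = 35, normal_epidermis = 34,
                    normal_dermis = 27),
        internal_pred = c(electrical_mark = 16, normal_epidermis = 16,
                          normal_dermis = 16),
        external_val = c(electrical_mark = 17, normal_epidermis = 20,
                         normal_dermis = 14)),
      scatter = list(offsetSd = 0.02, scaleLogSd = 0.15, slopeSd = 0.01,
                     curvatureSd = 0.005),
      amplitudeCv = 0.10, noiseSd = 0.005),
    preprocess = list(emscDegree = 2L, sgWindow = 9L, sgOrder = 3L,
                      windowHigh = 1710, windowLow = 1585),
    model = list(maxFactors = 10L, nPcaComponents = 8L,
                 thresholds = c(lower = 1.5, upper = 2.5)),
    map = list(geometry = c(areaX = 140, areaY = 200, step = 10,
                            aperture = 40),
               backgroundThreshold = NA,
               layouts = c("electrical_lesion", "normal_skin")),
    instrument = list(resolution_cm1 = 16, scans = 8))
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults; everything else
#' keeps its default.
#'
#' @param path YAML file path
#' @param seed optional seed overriding both default and file
#' @return nested configuration list
#' @export
readPipelineConfig <- function(path, seed = NULL) {
  cfg <- defaultPipelineConfig()
  usr <- yaml::read_yaml(path)
  merge <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        merge(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
  }
  cfg <- merge(cfg, usr)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg
}

.designFromConfig <- function(cfg) {
  g <- cfg$generator$design
  studyDesign(pcaCal = unlist(g$pca_cal), plsCal = unlist(g$pls_cal),
              internalPred = unlist(g$internal_pred),
              externalVal = unlist(g$external_val), seed = cfg$seed)
}

.scatterFromConfig <- function(cfg) {
  s <- cfg$generator$scatter
  scatterModel(s$offsetSd, s$scaleLogSd, s$slopeSd, s$curvatureSd)
}

#' Preprocess spectra with the standard chain
#'
#' EMSC correction (full grid) followed by the Savitzky-Golay second
#' derivative and extraction of the Amide I window. When
#' \code{reference = "mean"} the EMSC reference is the mean of this set
#' (use for calibration data) and is returned so that prediction data can
#' later be corrected against the same stored reference.
#'
#' @param set a raw-absorbance [SpectraSet]
#' @param reference \code{"mean"} or a stored calibration reference
#' @param emscDegree EMSC baseline polynomial degree
#' @param sgWindow,sgOrder Savitzky-Golay window and polynomial order
#' @param windowHigh,windowLow Amide I window edges (cm^-1)
#' @return list with \code{set} (windowed second-derivative
#'   [SpectraSet]), \code{reference} (EMSC reference on the full grid),
#'   \code{emsc} (the full [EMSCResult])
#' @export
preprocessChain <- function(set, reference = "mean", emscDegree = 2L,
                            sgWindow = 9L, sgOrder = 3L,
                            windowHigh = 1710, windowLow = 1585) {
  res <- emscCorrect(set, reference = reference, polyDegree = emscDegree)
  deriv <- savgolSecondDerivative(res@corrected, sgWindow, sgOrder)
  win <- extractWindow(deriv, windowHigh, windowLow)
  list(set = win, reference = res@reference, emsc = res)
}

#' Run the full modelling study on a simulated dataset
#'
#' Executes every statistical stage of the workflow on one simulated
#' study: PCA exploration on the PCA calibration split, PLS1 calibration
#' with LOOCV factor selection on the PLS calibration split, internal
#' prediction, external validation with per-class accuracies, and
#' optional classification of simulated hyperspectral maps.
#'
#' @param config configuration list from [defaultPipelineConfig()]
#' @param withMaps also simulate and classify the two built-in map
#'   layouts (default TRUE)
#' @return list with elements \code{dataset}, \code{pca}, \code{cv},
#'   \code{pls}, \code{emscReference}, \code{internal} and
#'   \code{external} (each a list with predictions, labels and an
#'   accuracy table), and \code{maps} (per layout: the [HyperMap], the
#'   [ClassMap] and the agreement with truth)
#' @examples
#' \donttest{
#' res <- runStudy(defaultPipelineConfig(seed = 1))
#' res$external$table
#' }
#' @export
runStudy <- function(config = defaultPipelineConfig(), withMaps = TRUE) {
  pp <- config$preprocess
  design <- .designFromConfig(config)
  scatter <- .scatterFromConfig(config)
  library <- defaultBandLibrary(amplitudeCv = config$generator$amplitudeCv,
                                noiseSd = config$generator$noiseSd)
  dataset <- synthDataset(design, library, scatter = scatter)
  rule <- thresholdRule(config$model$thresholds[["lower"]],
                        config$model$thresholds[["upper"]])

  chain <- function(s, ref) preprocessChain(s, ref, pp$emscDegree,
                                            pp$sgWindow, pp$sgOrder,
                                            pp$windowHigh, pp$windowLow)
  ## PCA exploration: electrical mark vs normal epidermis
  pcaRaw <- subsetBySplit(dataset, "pca_cal")
  pcaPrep <- chain(pcaRaw, "mean")
  pca <- pcaFit(pcaPrep$set, nComponents = min(config$model$nPcaComponents,
                                               ncol(pcaPrep$set) - 1L))
  ## PLS calibration on the three tissue classes
  calRaw <- subsetBySplit(dataset, "pls_cal")
  calPrep <- chain(calRaw, "mean")
  cv <- plsLoocv(calPrep$set, maxFactors = config$model$maxFactors,
                 rule = rule)
  pls <- pls1Fit(calPrep$set, nFactors = cv@chosenFactors, rule = rule)

  evaluate <- function(tag) {
    raw <- subsetBySplit(dataset, tag)
    prep <- chain(raw, calPrep$reference)
    y <- predict(pls, prep$set)
    lab <- classifyY(y, rule)
    list(yPred = y, predicted = lab, truth = classLabels(raw),
         table = accuracyTable(lab, classLabels(raw)))
  }
  internal <- evaluate("internal_pred")
  external <- evaluate("external_val")

  maps <- NULL
  if (withMaps) {
    g <- config$map$geometry
    geometry <- scanGeometry(g[["areaX"]], g[["areaY"]], g[["step"]],
                             g[["aperture"]])
    bt <- config$map$backgroundThreshold
    if (is.null(bt) || is.na(bt)) bt <- NULL
    maps <- lapply(seq_along(config$map$layouts), function(i) {
      nm <- config$map$layouts[[i]]
      hm <- synthMap(nm, geometry, library, scatter = scatter,
                     seed = config$seed + i)
      cm <- classifyHyperMap(hm, calPrep$reference, pls,
                             backgroundThreshold = bt,
                             windowHigh = pp$windowHigh,
                             windowLow = pp$windowLow,
                             sgWindow = pp$sgWindow, sgOrder = pp$sgOrder,
                             emscDegree = pp$emscDegree)
      list(layout = nm, map = hm, classMap = cm,
           agreement = mapAgreement(cm, hm@truth))
    })
    names(maps) <- config$map$layouts
  }
  list(dataset = dataset, pca = pca, cv = cv, pls = pls,
       emscReference = calPrep$reference, internal = internal,
       external = external, maps = maps)
}

#' Run the pipeline end to end and write all artifacts
#'
#' Simulates the study, fits and validates the models, classifies the two
#' built-in map layouts and writes every artifact (spectra CSV, scores
#' and loadings CSVs, prediction CSVs, the accuracy table, class-map
#' label CSVs and PNGs) under \code{outDir}. Returns a run manifest with
#' the configuration hash, seed, parameters used and the MD5 digest of
#' every written file; identical configuration and seed reproduce
#' identical digests.
#'
#' @param config configuration list (see [defaultPipelineConfig()])
#' @param outDir output directory (created if needed)
#' @return the run manifest, invisibly written to
#'   \code{outDir/manifest.yaml}
#' @export
runPipeline <- function(config = defaultPipelineConfig(), outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  res <- runStudy(config, withMaps = TRUE)
  pp <- config$preprocess
  paths <- character(0)
  out <- function(f) { p <- file.path(outDir, f); paths[[f]] <<- p; p }

  writeSpectraCsv(res$dataset, out("spectra.csv"))
  write.csv(data.frame(wavenumber = wavenumbers(res$pca),
                       t(res$pca@loadings)),
            out("pca_loadings.csv"), row.names = FALSE)
  write.csv(data.frame(id = rownames(res$pca@scores), res$pca@scores,
                       label = classLabels(subsetBySplit(res$dataset,
                                                         "pca_cal"))),
            out("pca_scores.csv"), row.names = FALSE)
  write.csv(data.frame(component = seq_along(res$pca@explainedVarPct),
                       explainedVarPct = res$pca@explainedVarPct),
            out("pca_variance.csv"), row.names = FALSE)
  write.csv(data.frame(factors = seq_along(res$cv@rmsecv),
                       rmsecv = res$cv@rmsecv),
            out("pls_rmsecv.csv"), row.names = FALSE)
  for (tag in c("internal", "external")) {
    ev <- res[[tag]]
    write.csv(data.frame(id = seq_along(ev$yPred), yPred = ev$yPred,
                         predicted = ev$predicted, truth = ev$truth),
              out(paste0(tag, "_predictions.csv")), row.names = FALSE)
  }
  tab <- res$external$table
  tab$yRange <- c(normal_epidermis = "0-1.5", electrical_mark = "1.5-2.5",
                  normal_dermis = ">2.5")[tab$class]
  write.csv(tab[, c("class", "yRange", "correct", "false", "accuracyPct")],
            out("validation_table.csv"), row.names = FALSE)
  for (nm in names(res$maps)) {
    m <- res$maps[[nm]]
    write.csv(m$classMap@labels, out(paste0("classmap_", nm, ".csv")),
              row.names = FALSE)
    renderClassMap(m$classMap, out(paste0("classmap_", nm, ".png")),
                   upscale = 10L)
  }
  cfgPath <- out("config.yaml")
  yaml::write_yaml(config, cfgPath)

  manifest <- list(
    configHash = unname(tools::md5sum(cfgPath)),
    seed = config$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    parameters = list(emscDegree = pp$emscDegree, sgWindow = pp$sgWindow,
                      sgOrder = pp$sgOrder, windowHigh = pp$windowHigh,
                      windowLow = pp$windowLow,
                      nFactors = res$cv@chosenFactors,
                      thresholds = as.list(config$model$thresholds)),
    externalAccuracyPct = setNames(as.list(tab$accuracyPct), tab$class),
    mapAgreement = lapply(res$maps, `[[`, "agreement"),
    files = as.list(tools::md5sum(unlist(paths))))
  names(manifest$files) <- basename(names(manifest$files))
  yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
  invisible(manifest)
}
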