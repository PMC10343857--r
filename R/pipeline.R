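#' Resolve a band argument
#'
#' Accepts a [Band], a preset name (`bandA`..`bandD`, `full`) or `"fused"`
#' (the four characteristic bands concatenated); returns the band object or
#' the string `"fused"`.
#' @keywords internal
.resolveBand <- function(band) {
  if (methods::is(band, "Band")) return(band)
  if (identical(band, "fused")) return("fused")
  bandPreset(band)
}

# images array (size, size, 3, N) from a list of CorrelationMaps
.renderToArray <- function(maps, mapType, cfg) {
  n <- length(maps)
  out <- array(0, dim = c(cfg@size, cfg@size, 3L, n))
  for (i in seq_len(n)) {
    m <- switch(mapType, sync = maps[[i]]@sync, async = maps[[i]]@async,
                integrative = maps[[i]]@integrative)
    # a map >= 8 orders of magnitude below its sibling maps is zero up to
    # roundoff; render it flat rather than amplifying numerical noise
    floor_i <- 1e-8 * max(abs(maps[[i]]@sync), abs(maps[[i]]@async))
    out[, , , i] <- renderMap(m, cfg, zeroFloor = floor_i)
  }
  dimnames(out) <- list(NULL, NULL, NULL, names(maps))
  out
}

#' Run the full identification pipeline
#'
#' Executes read -> normalize -> split -> band extraction -> 2D-COS ->
#' render -> train -> evaluate on one (band, map type) configuration and
#' writes a replayable run manifest.  Every random stage is governed by an
#' explicit seed, so a rerun with the same configuration reproduces the
#' split, the images and (on the same device) the training report.
#'
#' @param data a labeled [SpectraSet] or a path readable by [readSpectra()]
#' @param outDir output directory (manifest, train report, curves CSV and,
#'   when `writeImages = TRUE`, the PNG tree)
#' @param band a [Band], a preset name, or `"fused"`
#' @param mapType `"sync"`, `"async"` or `"integrative"`
#' @param params a [PerturbationParams]; note that with the default in-phase
#'   modulation (`phaseGradient = 0`) the asynchronous and integrative maps
#'   are identically zero -- set a nonzero `phaseGradient` to obtain
#'   informative maps of those types
#' @param renderCfg a [RenderConfig]
#' @param ratios train/test/external proportions
#' @param seed integer seed for the split
#' @param modelCfg a [ModelConfig]; `NULL` builds one matched to the data
#'   (classes from labels, input size from `renderCfg@size`)
#' @param normalization `"minmax"` or `"vector"`
#' @param writeImages also write the PNG tree under `outDir/images`
#' @param quiet suppress progress messages
#' @return list with elements `split`, `report` ([TrainReport]), `model`,
#'   and `manifest` (also written as JSON)
#' @export
runPipeline <- function(data, outDir = tempfile("ir2dcos_run"),
                        band = "bandC",
                        mapType = c("sync", "async", "integrative"),
                        params = perturbationParams(),
                        renderCfg = renderConfig(size = 32L),
                        ratios = c(0.7, 0.2, 0.1), seed = 1L,
                        modelCfg = NULL, normalization = "minmax",
                        writeImages = FALSE, quiet = FALSE) {
  mapType <- match.arg(mapType)
  stage <- function(name, expr) {
    if (!quiet) message("[", name, "] ...")
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  set <- stage("read", if (is.character(data)) readSpectra(data) else data)
  if (is.null(spectraLabels(set))) stop("a labeled spectrum set is required")
  set <- stage("normalize", normalizeSpectra(set, normalization))
  split <- stage("split", splitDataset(set, ratios = ratios, seed = seed))
  bandObj <- .resolveBand(band)
  bandName <- if (identical(bandObj, "fused")) "fused" else bandObj@name
  banded <- stage("band", if (identical(bandObj, "fused"))
    fuseBands(set, bandPresets()[c("bandA", "bandB", "bandC", "bandD")])
    else extractBand(set, bandObj))
  maps <- stage("twodcos", mapDataset(banded, band = NULL, params = params))
  imgs <- stage("render", .renderToArray(maps, mapType, renderCfg))
  lab <- spectraLabels(set)
  names(lab) <- colnames(set)
  mem <- membership(split)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  imageManifest <- NULL
  if (writeImages)
    imageManifest <- stage("render", renderDataset(
      maps, lab[names(maps)], split, file.path(outDir, "images", bandName,
                                               mapType),
      cfg = renderCfg, mapType = mapType, bandName = bandName, force = TRUE))
  if (is.null(modelCfg)) {
    aug <- if (mapType == "sync") c("crop", "transpose") else "crop"
    modelCfg <- modelConfig(length(unique(lab)), inputSize = renderCfg@size,
                            channels = c(8L, 16L, 32L, 64L),
                            stemChannels = 4L, seed = seed,
                            augmentation = aug)
  }
  if (modelCfg@inputSize != renderCfg@size)
    stop("modelCfg input size must match the render size")
  pick <- function(setName) {
    ids <- names(mem)[mem == setName]
    list(x = imgs[, , , ids, drop = FALSE], y = lab[ids])
  }
  tr <- pick("train"); te <- pick("test"); ex <- pick("external")
  model <- stage("train", buildModel(modelCfg))
  report <- stage("train", trainModel(model, tr$x, tr$y, te$x, te$y,
                                      ex$x, ex$y))
  testEval <- stage("evaluate", evaluateModel(model, te$x, te$y))
  manifest <- list(
    band = bandName, mapType = mapType, seed = seed, ratios = ratios,
    normalization = normalization,
    perturbation = list(nSteps = params@nSteps, amplitude = params@amplitude,
                        cycles = params@cycles,
                        phaseGradient = params@phaseGradient,
                        mode = params@mode),
    render = list(size = renderCfg@size, colormap = renderCfg@colormap,
                  scaling = renderCfg@scaling, style = renderCfg@style),
    model = .configSnapshot(modelCfg),
    split = list(train = sum(mem == "train"), test = sum(mem == "test"),
                 external = sum(mem == "external"),
                 membership = as.character(mem)),
    stages = c("read", "normalize", "split", "band", "twodcos", "render",
               "train", "evaluate"),
    images = if (!is.null(imageManifest)) imageManifest$file,
    imageChecksums = if (!is.null(imageManifest))
      unname(tools::md5sum(file.path(outDir, "images", bandName, mapType,
                                     imageManifest$file))),
    results = list(loss = report@finalLoss,
                   trainAcc = report@finalTrainAcc,
                   testAcc = report@bestTestAcc,
                   finalTestAcc = report@finalTestAcc,
                   bestEpoch = report@bestEpoch,
                   externalAcc = report@externalAcc))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.csv(report@history, file.path(outDir, "curves.csv"),
                   row.names = FALSE)
  plotCurves(report, file.path(outDir, "curves.png"))
  jsonlite::write_json(c(manifest$results, list(seed = report@seed)),
                       file.path(outDir, "train_report.json"),
                       auto_unbox = TRUE, digits = NA)
  list(split = split, report = report, model = model, manifest = manifest,
       outDir = outDir)
}

#' Run a grid of (band, map type) configurations
#'
#' The package's analogue of a band-by-map-type comparison table: one row
#' per configuration with final loss and train/test/external accuracy.
#'
#' @param data a labeled [SpectraSet]
#' @param bands character vector of preset names and/or `"fused"`
#' @param mapTypes subset of `c("sync", "async", "integrative")`
#' @param ... further arguments passed to [runPipeline()]
#' @return data.frame with one row per (band, mapType)
#' @export
runGrid <- function(data, bands = c("bandA", "bandB", "bandC", "bandD",
                                    "fused", "full"),
                    mapTypes = "sync", ...) {
  rows <- list()
  for (b in bands) for (mt in mapTypes) {
    run <- runPipeline(data, band = b, mapType = mt, ...)
    r <- run$report
    rows[[length(rows) + 1L]] <- data.frame(
      band = b, mapType = mt, loss = r@finalLoss,
      trainAcc = r@finalTrainAcc, testAcc = r@bestTestAcc,
      finalTestAcc = r@finalTestAcc, externalAcc = r@externalAcc,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
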