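#' Serialize correlation maps to a binary container with a JSON header
#'
#' Writes a little-endian double array (`sync`, `async`, `integrative`
#' concatenated) to `<path>` and a JSON sidecar `<path>.json` describing the
#' grid, band and perturbation parameters, so that a maps file is
#' self-describing and reproducible.
#'
#' @param maps a [CorrelationMaps]
#' @param path output file path (binary payload; header at `<path>.json`)
#' @param band optional [Band] recorded in the header
#' @param params optional [PerturbationParams] recorded in the header
#' @return `path`, invisibly
#' @export
writeCorrelationMaps <- function(maps, path, band = NULL, params = NULL) {
  stopifnot(methods::is(maps, "CorrelationMaps"))
  p <- length(maps@wavenumbers)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(maps@sync), con, size = 8, endian = "little")
  writeBin(as.numeric(maps@async), con, size = 8, endian = "little")
  writeBin(as.numeric(maps@integrative), con, size = 8, endian = "little")
  header <- list(
    side = p, layout = c("sync", "async", "integrative"),
    dtype = "float64le", wavenumbers = maps@wavenumbers,
    band = if (!is.null(band)) list(high = band@high, low = band@low,
                                    name = band@name),
    perturbation = if (!is.null(params)) list(
      nSteps = params@nSteps, amplitude = params@amplitude,
      cycles = params@cycles, phaseGradient = params@phaseGradient,
      mode = params@mode))
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeCorrelationMaps
#' @export
readCorrelationMaps <- function(path) {
  header <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  p <- as.integer(header$side)
  con <- file(path, "rb")
  on.exit(close(con))
  readMat <- function() matrix(readBin(con, "double", p * p, size = 8,
                                       endian = "little"), p, p)
  methods::new("CorrelationMaps",
               wavenumbers = as.numeric(header$wavenumbers),
               sync = readMat(), async = readMat(), integrative = readMat())
}

#' Save / load a trained model checkpoint
#'
#' The checkpoint is the R-native serialization of all layer parameters
#' (weights, biases, batch-normalization scales and running statistics)
#' plus the class levels; a JSON snapshot of the configuration is written
#' alongside for inspection.
#'
#' @param model a model from [buildModel()]
#' @param path checkpoint file path (`.rds`; config snapshot at
#'   `<path>.json`)
#' @return `path` invisibly; `loadModel` returns the rebuilt model
#' @export
saveModel <- function(model, path) {
  cfgList <- .configSnapshot(model$cfg)
  saveRDS(list(state = .modelState(model), config = cfgList,
               inputChannels = model$inputChannels,
               classLevels = model$classLevels), path)
  jsonlite::write_json(c(cfgList, list(classLevels = model$classLevels)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  chk <- readRDS(path)
  cfg <- do.call(modelConfig, chk$config)
  model <- buildModel(cfg, inputChannels = chk$inputChannels)
  .restoreState(model, chk$state)
  model$classLevels <- chk$classLevels
  model
}

#' Plot accuracy and loss curves
#'
#' Two-panel PNG: per-epoch training/test accuracy and training/test
#' cross-entropy loss.
#'
#' @param report a [TrainReport]
#' @param path output PNG path
#' @return `path`, invisibly
#' @export
plotCurves <- function(report, path) {
  stopifnot(methods::is(report, "TrainReport"))
  h <- report@history
  grDevices::png(path, width = 900, height = 420)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  graphics::plot(h$epoch, h$trainAcc, type = "l", col = "#2166AC", lwd = 2,
                 ylim = c(0, 1), xlab = "epoch", ylab = "accuracy",
                 main = "accuracy")
  graphics::lines(h$epoch, h$testAcc, col = "#B2182B", lwd = 2)
  graphics::abline(v = report@bestEpoch, lty = 3)
  graphics::legend("bottomright", c("train", "test"), lwd = 2,
                   col = c("#2166AC", "#B2182B"), bty = "n")
  graphics::plot(h$epoch, h$trainLoss, type = "l", col = "#2166AC", lwd = 2,
                 ylim = range(c(h$trainLoss, h$testLoss)), xlab = "epoch",
                 ylab = "cross-entropy", main = "loss")
  graphics::lines(h$epoch, h$testLoss, col = "#B2182B", lwd = 2)
  invisible(path)
}
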