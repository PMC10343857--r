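#' @import methods
#' @importFrom stats rnorm runif sd setNames
#' @importFrom utils modifyList
#' @useDynLib ir2dcos, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' SpectraSet: a labeled collection of 1-D absorbance spectra
#'
#' `SpectraSet` extends [SummarizedExperiment::SummarizedExperiment] with the
#' convention that rows are wavenumbers (cm^-1, stored in `rowData()$wavenumber`,
#' strictly monotonic, conventionally descending as spectrometers report them)
#' and columns are samples.  The single assay `"absorbance"` holds absorbance
#' in arbitrary units; `colData()$label` carries the optional class label of
#' each sample.
#'
#' @seealso [SpectraSet()] for the constructor, [wavenumbers()],
#'   [absorbance()], [spectraLabels()] for accessors.
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @exportClass SpectraSet
setClass("SpectraSet", contains = "SummarizedExperiment")

setValidity("SpectraSet", function(object) {
  msg <- NULL
  if (!"absorbance" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'absorbance' is required")
  wn <- SummarizedExperiment::rowData(object)$wavenumber
  if (is.null(wn)) {
    msg <- c(msg, "rowData column 'wavenumber' is required")
  } else {
    if (!is.numeric(wn) || anyNA(wn))
      msg <- c(msg, "wavenumbers must be numeric and non-missing")
    if (length(wn) >= 2) {
      d <- diff(wn)
      if (!(all(d > 0) || all(d < 0)))
        msg <- c(msg, "wavenumbers must be strictly monotonic")
    }
  }
  lab <- SummarizedExperiment::colData(object)$label
  if (!is.null(lab) && length(lab) != ncol(object))
    msg <- c(msg, "one label per sample is required")
  if (is.null(msg)) TRUE else msg
})

#' Wavenumber band
#'
#' A closed wavenumber interval `[low, high]` in cm^-1 used to restrict
#' spectra to a characteristic region before 2D-COS expansion.  Bounds are
#' inclusive at both ends.
#'
#' @slot high upper bound (cm^-1)
#' @slot low lower bound (cm^-1)
#' @slot name display name
#' @seealso [band()], [bandPresets()]
#' @exportClass Band
setClass("Band", representation(high = "numeric", low = "numeric",
                                name = "character"))

setValidity("Band", function(object) {
  if (length(object@high) != 1L || length(object@low) != 1L)
    return("high and low must be scalars")
  if (!is.finite(object@high) || !is.finite(object@low))
    return("band bounds must be finite")
  if (object@high <= object@low) return("high must exceed low")
  TRUE
})

#' Sinusoidal perturbation parameters
#'
#' Parameters of the sinusoidal intensity perturbation used to expand one
#' spectrum into an n-step series for generalized 2D correlation analysis.
#' Step i (i = 1..n) at wavenumber v modulates the parent spectrum s(v) as
#' `s(v) * (1 + amplitude * sin(2*pi*cycles*(i-1)/n + phaseGradient*(v - v_ref)))`
#' (multiplicative mode; `v_ref` is the first grid point).  A nonzero
#' `phaseGradient` (radians per cm^-1) de-phases wavenumbers from one another
#' and is required for a nonzero asynchronous map.
#'
#' @slot nSteps number of perturbation steps (>= 2)
#' @slot amplitude relative modulation depth (> 0)
#' @slot cycles sinusoid periods spanned across the n steps (> 0)
#' @slot phaseGradient phase advance per cm^-1 across the grid (radians)
#' @slot mode `"multiplicative"` (default) or `"additive"`
#' @seealso [perturbationParams()]
#' @exportClass PerturbationParams
setClass("PerturbationParams",
         representation(nSteps = "integer", amplitude = "numeric",
                        cycles = "numeric", phaseGradient = "numeric",
                        mode = "character"))

setValidity("PerturbationParams", function(object) {
  msg <- NULL
  if (object@nSteps < 2L) msg <- c(msg, "nSteps must be >= 2")
  if (!(object@amplitude > 0)) msg <- c(msg, "amplitude must be > 0")
  if (!(object@cycles > 0)) msg <- c(msg, "cycles must be > 0")
  if (!object@mode %in% c("multiplicative", "additive"))
    msg <- c(msg, "mode must be 'multiplicative' or 'additive'")
  if (is.null(msg)) TRUE else msg
})

#' Dynamic spectra: a mean-centered perturbation series
#'
#' The perturbation series with its per-wavenumber mean (the reference
#' spectrum) subtracted, i.e. the dynamic spectrum matrix whose column for
#' wavenumber v holds the deviations of v's intensity across the n steps.
#'
#' @slot wavenumbers grid (cm^-1), one per column of `values`
#' @slot values nSteps x nWavenumbers matrix of mean-centered intensities
#' @slot reference the per-wavenumber mean spectrum that was subtracted
#' @seealso [makeDynamic()]
#' @exportClass DynamicSpectra
setClass("DynamicSpectra",
         representation(wavenumbers = "numeric", values = "matrix",
                        reference = "numeric"))

setValidity("DynamicSpectra", function(object) {
  msg <- NULL
  if (ncol(object@values) != length(object@wavenumbers))
    msg <- c(msg, "values must have one column per wavenumber")
  if (length(object@reference) != length(object@wavenumbers))
    msg <- c(msg, "reference must have one value per wavenumber")
  if (nrow(object@values) < 2L)
    msg <- c(msg, "at least 2 perturbation steps are required")
  cm <- colMeans(object@values)
  if (length(cm) && max(abs(cm)) > 1e-8 * (1 + max(abs(object@values))))
    msg <- c(msg, "columns must be mean-centered")
  if (is.null(msg)) TRUE else msg
})

#' 2D correlation maps of one spectrum over one band
#'
#' The three square correlation matrices over a common wavenumber grid:
#' synchronous (symmetric, in-phase covariation), asynchronous (antisymmetric
#' with zero diagonal, out-of-phase covariation through the Hilbert-Noda
#' transform) and integrative (their elementwise product).
#'
#' @slot wavenumbers grid (cm^-1), side length of all three matrices
#' @slot sync synchronous map
#' @slot async asynchronous map
#' @slot integrative elementwise sync * async
#' @seealso [computeCorrelationMaps()]
#' @exportClass CorrelationMaps
setClass("CorrelationMaps",
         representation(wavenumbers = "numeric", sync = "matrix",
                        async = "matrix", integrative = "matrix"))

setValidity("CorrelationMaps", function(object) {
  p <- length(object@wavenumbers)
  for (nm in c("sync", "async", "integrative")) {
    m <- slot(object, nm)
    if (!all(dim(m) == c(p, p)))
      return(sprintf("'%s' must be %d x %d", nm, p, p))
  }
  TRUE
})

#' Raster rendering configuration for correlation maps
#'
#' @slot size output image side in pixels (>= 32)
#' @slot colormap named diverging palette (see [divergingPalette()])
#' @slot scaling `"symmetric_max"` maps `[-max|m|, +max|m|]` onto the palette
#'   so that zero sits at the palette midpoint; `"percentile"` clips at the
#'   given percentile of `|m|` first
#' @slot style `"heatmap"` or `"filled_contour"` (value quantization into
#'   `contourLevels` bins)
#' @slot contourLevels number of bins for the filled-contour style (>= 2)
#' @slot percentile clip quantile for `scaling = "percentile"`
#' @seealso [renderConfig()], [renderMap()]
#' @exportClass RenderConfig
setClass("RenderConfig",
         representation(size = "integer", colormap = "character",
                        scaling = "character", style = "character",
                        contourLevels = "integer", percentile = "numeric"))

setValidity("RenderConfig", function(object) {
  msg <- NULL
  if (object@size < 32L) msg <- c(msg, "size must be >= 32")
  if (!object@scaling %in% c("symmetric_max", "percentile"))
    msg <- c(msg, "unknown scaling")
  if (!object@style %in% c("heatmap", "filled_contour"))
    msg <- c(msg, "unknown style")
  if (object@style == "filled_contour" && object@contourLevels < 2L)
    msg <- c(msg, "contourLevels must be >= 2")
  if (object@scaling == "percentile" &&
      (object@percentile <= 0 || object@percentile > 1))
    msg <- c(msg, "percentile must be in (0, 1]")
  if (is.null(msg)) TRUE else msg
})

#' Train/test/external-validation split assignment
#'
#' Produced by [splitDataset()]: a per-sample membership in one of the three
#' sets, obtained by a stratified random external holdout followed by a
#' Kennard-Stone selection of the training portion from the remaining model
#' set.
#'
#' @slot sampleIds sample identifiers
#' @slot membership factor with levels train/test/external, one per sample
#' @slot ratios target (train, test, external) proportions
#' @slot seed integer seed used for the random holdout
#' @exportClass SplitAssignment
setClass("SplitAssignment",
         representation(sampleIds = "character", membership = "factor",
                        ratios = "numeric", seed = "integer"))

setValidity("SplitAssignment", function(object) {
  msg <- NULL
  if (length(object@sampleIds) != length(object@membership))
    msg <- c(msg, "one membership per sample id is required")
  if (!identical(levels(object@membership), c("train", "test", "external")))
    msg <- c(msg, "membership levels must be train, test, external")
  if (length(object@ratios) != 3L || abs(sum(object@ratios) - 1) > 1e-8)
    msg <- c(msg, "ratios must be 3 proportions summing to 1")
  if (anyDuplicated(object@sampleIds))
    msg <- c(msg, "sample ids must be unique")
  if (is.null(msg)) TRUE else msg
})

#' Residual-network model configuration
#'
#' Hyperparameters of the residual CNN: a stem convolution + batch
#' normalization + ReLU, four stages each opened by one convolution residual
#' block (projection shortcut) and continued by identity residual blocks
#' (`stagePlan` identity blocks per stage; the default plan 1,2,2,1 yields
#' exactly 4 convolution and 6 identity blocks), global average pooling, and
#' a fully connected classification layer.  Training uses stochastic gradient
#' descent with momentum, weight decay and cross-entropy loss.
#'
#' @slot inputSize input image side in pixels
#' @slot nClasses number of output classes
#' @slot stagePlan identity-block count per stage (length 4)
#' @slot channels output channels per stage (length 4)
#' @slot stemChannels stem convolution output channels
#' @slot stemFilter,stemStride,stemPad stem convolution geometry
#' @slot learningRate initial SGD learning rate
#' @slot lrSchedule `"step"` (learning rate divided by 10 at 50% and 75% of
#'   the epochs, the standard recipe for this model family) or `"constant"`
#' @slot weightDecay L2 weight-decay coefficient
#' @slot momentum SGD momentum
#' @slot epochs training epochs
#' @slot batchSize minibatch size
#' @slot seed integer seed for initialization, shuffling and augmentation
#' @slot augmentation character subset of `c("crop", "transpose")`
#' @seealso [modelConfig()], [buildModel()], [trainModel()]
#' @exportClass ModelConfig
setClass("ModelConfig",
         representation(inputSize = "integer", nClasses = "integer",
                        stagePlan = "integer", channels = "integer",
                        stemChannels = "integer", stemFilter = "integer",
                        stemStride = "integer", stemPad = "integer",
                        learningRate = "numeric", lrSchedule = "character",
                        weightDecay = "numeric",
                        momentum = "numeric", epochs = "integer",
                        batchSize = "integer", seed = "integer",
                        augmentation = "character"))

setValidity("ModelConfig", function(object) {
  msg <- NULL
  if (length(object@stagePlan) != 4L || any(object@stagePlan < 0L))
    msg <- c(msg, "stagePlan must give identity-block counts for 4 stages")
  if (length(object@channels) != 4L || any(object@channels < 1L))
    msg <- c(msg, "channels must give widths for 4 stages")
  if (!(object@learningRate >= 0)) msg <- c(msg, "learningRate must be >= 0")
  if (!object@lrSchedule %in% c("step", "constant"))
    msg <- c(msg, "lrSchedule must be 'step' or 'constant'")
  if (object@nClasses < 2L) msg <- c(msg, "nClasses must be >= 2")
  if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  bad <- setdiff(object@augmentation, c("crop", "transpose"))
  if (length(bad)) msg <- c(msg, paste("unknown augmentation:", bad[1]))
  if (is.null(msg)) TRUE else msg
})

#' Training report
#'
#' Per-epoch accuracy and cross-entropy loss on the training and test sets,
#' plus the final external-validation accuracy (if an external set was
#' given), the configuration snapshot and the seed.
#'
#' @slot history data.frame with columns epoch, trainAcc, trainLoss,
#'   testAcc, testLoss
#' @slot finalTrainAcc,finalTestAcc,externalAcc final-epoch accuracies
#'   (externalAcc is `NA` when no external set was supplied)
#' @slot bestTestAcc best test accuracy over epochs
#' @slot bestEpoch epoch at which the selected (best-test) checkpoint was
#'   taken; external validation is run on that checkpoint
#' @slot finalLoss training cross-entropy at the selected checkpoint's epoch
#' @slot config configuration snapshot (list)
#' @slot seed integer seed
#' @exportClass TrainReport
setClass("TrainReport",
         representation(history = "data.frame", finalTrainAcc = "numeric",
                        finalTestAcc = "numeric", externalAcc = "numeric",
                        bestTestAcc = "numeric", bestEpoch = "integer",
                        finalLoss = "numeric",
                        config = "list", seed = "integer"))

setValidity("TrainReport", function(object) {
  h <- object@history
  need <- c("epoch", "trainAcc", "trainLoss", "testAcc", "testLoss")
  if (!all(need %in% names(h)))
    return(paste("history must have columns", paste(need, collapse = ", ")))
  acc <- c(h$trainAcc, h$testAcc)
  if (length(acc) && (min(acc) < 0 || max(acc) > 1))
    return("accuracies must lie in [0, 1]")
  if (length(h$trainLoss) && min(c(h$trainLoss, h$testLoss)) < 0)
    return("losses must be >= 0")
  TRUE
})
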