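#' Construct a SpectraSet
#'
#' @param wavenumbers numeric grid in cm^-1, strictly monotonic (spectra are
#'   stored as acquired; FT-IR grids are conventionally descending)
#' @param absorbance numeric matrix of absorbance values, either
#'   wavenumbers x samples or samples x wavenumbers (orientation is inferred
#'   from the grid length; a square matrix is taken as wavenumbers x samples)
#' @param labels optional class label per sample
#' @param sampleIds optional sample identifiers; defaults to `s0001`, ...
#' @param metadata optional list stored in `metadata()`
#' @return a [SpectraSet]
#' @examples
#' wn <- seq(4010, 365, by = -4)
#' m <- matrix(runif(length(wn) * 3), ncol = 3)
#' ss <- SpectraSet(wn, m, labels = c("a", "a", "b"))
#' ss
#' @export
SpectraSet <- function(wavenumbers, absorbance, labels = NULL,
                       sampleIds = NULL, metadata = list()) {
  wavenumbers <- as.numeric(wavenumbers)
  if (is.null(dim(absorbance))) absorbance <- matrix(absorbance, ncol = 1L)
  p <- length(wavenumbers)
  if (nrow(absorbance) != p) {
    if (ncol(absorbance) == p) absorbance <- t(absorbance)
    else stop("absorbance dimensions do not match the wavenumber grid")
  }
  n <- ncol(absorbance)
  if (is.null(sampleIds)) sampleIds <- sprintf("s%04d", seq_len(n))
  cd <- S4Vectors::DataFrame(row.names = sampleIds)
  if (!is.null(labels)) {
    if (length(labels) != n) stop("one label per sample is required")
    cd$label <- as.character(labels)
  }
  dimnames(absorbance) <- list(NULL, sampleIds)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(absorbance = absorbance),
    rowData = S4Vectors::DataFrame(wavenumber = wavenumbers),
    colData = cd, metadata = metadata)
  methods::new("SpectraSet", se)
}

#' @describeIn SpectraSet wavenumber grid accessor
#' @param x a `SpectraSet`
#' @export
setMethod("wavenumbers", "SpectraSet", function(x)
  SummarizedExperiment::rowData(x)$wavenumber)

setMethod("wavenumbers", "DynamicSpectra", function(x) x@wavenumbers)
setMethod("wavenumbers", "CorrelationMaps", function(x) x@wavenumbers)

#' @describeIn SpectraSet absorbance matrix accessor (wavenumbers x samples)
#' @export
setMethod("absorbance", "SpectraSet", function(x)
  SummarizedExperiment::assay(x, "absorbance"))

#' @describeIn SpectraSet class-label accessor
#' @export
setMethod("spectraLabels", "SpectraSet", function(x) {
  lab <- SummarizedExperiment::colData(x)$label
  if (is.null(lab)) NULL else as.character(lab)
})

setMethod("show", "SpectraSet", function(object) {
  wn <- wavenumbers(object)
  lab <- spectraLabels(object)
  cat(sprintf("SpectraSet: %d spectra x %d wavenumbers (%.0f..%.0f cm^-1)\n",
              ncol(object), nrow(object),
              if (length(wn)) wn[1] else NA, if (length(wn)) wn[length(wn)] else NA))
  if (!is.null(lab)) {
    tab <- table(lab)
    cat(sprintf("classes (%d): %s\n", length(tab),
                paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  } else cat("unlabeled\n")
})

setMethod("syncMap", "CorrelationMaps", function(x) x@sync)
setMethod("asyncMap", "CorrelationMaps", function(x) x@async)
setMethod("integrativeMapOf", "CorrelationMaps", function(x) x@integrative)

setMethod("show", "CorrelationMaps", function(object) {
  p <- length(object@wavenumbers)
  cat(sprintf("CorrelationMaps: %d x %d over %.0f..%.0f cm^-1\n", p, p,
              object@wavenumbers[1], object@wavenumbers[p]))
  cat(sprintf("  max|sync| = %.4g, max|async| = %.4g\n",
              max(abs(object@sync)), max(abs(object@async))))
})

setMethod("membership", "SplitAssignment", function(x)
  stats::setNames(x@membership, x@sampleIds))

setMethod("show", "SplitAssignment", function(object) {
  tab <- table(object@membership)
  cat(sprintf("SplitAssignment: %d samples (train=%d, test=%d, external=%d), seed=%d\n",
              length(object@sampleIds), tab[["train"]], tab[["test"]],
              tab[["external"]], object@seed))
})

setMethod("show", "TrainReport", function(object) {
  h <- object@history
  cat(sprintf("TrainReport: %d epochs, checkpoint selected at epoch %d\n",
              nrow(h), object@bestEpoch))
  cat(sprintf("  selected test acc %.3f (final-epoch %.3f), train loss %.4f\n",
              object@bestTestAcc, object@finalTestAcc, object@finalLoss))
  if (!is.na(object@externalAcc))
    cat(sprintf("  external validation acc %.3f\n", object@externalAcc))
})

#' Construct a wavenumber band
#'
#' @param high,low inclusive bounds in cm^-1 (`high > low`)
#' @param name display name
#' @return a [Band]
#' @examples
#' band(1750, 1100, "fingerprint")
#' @export
band <- function(high, low, name = sprintf("%g-%g", high, low))
  methods::new("Band", high = as.numeric(high), low = as.numeric(low),
               name = as.character(name))

#' Named band presets
#'
#' Four characteristic mid-IR regions commonly used for plant-material
#' fingerprinting -- the O-H stretch region (bandA, 3500-3000 cm^-1), the
#' methylene C-H stretch region (bandB, 3000-2750 cm^-1), the
#' ester/terpenoid/lignin fingerprint (bandC, 1750-1100 cm^-1) and the
#' saccharide region (bandD, 1100-400 cm^-1) -- plus `full` covering the
#' whole default grid (4010-365 cm^-1).
#'
#' @return named list of [Band] objects
#' @examples
#' names(bandPresets())
#' bandPreset("bandC")
#' @export
bandPresets <- function() {
  list(bandA = band(3500, 3000, "bandA"),
       bandB = band(3000, 2750, "bandB"),
       bandC = band(1750, 1100, "bandC"),
       bandD = band(1100, 400, "bandD"),
       full  = band(4010, 365, "full"))
}

#' @rdname bandPresets
#' @param name preset name, one of `bandA`, `bandB`, `bandC`, `bandD`, `full`
#' @export
bandPreset <- function(name) {
  presets <- bandPresets()
  if (!name %in% names(presets))
    stop("unknown band preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  presets[[name]]
}
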