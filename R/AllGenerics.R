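#' Extract the wavenumber grid
#'
#' @param x a [SpectraSet], [DynamicSpectra] or [CorrelationMaps] object
#' @return numeric vector of wavenumbers (cm^-1)
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' Extract the absorbance matrix
#'
#' @param x a [SpectraSet]
#' @return numeric matrix, wavenumbers x samples
#' @export
setGeneric("absorbance", function(x) standardGeneric("absorbance"))

#' Extract per-sample class labels
#'
#' @param x a [SpectraSet]
#' @return character vector of labels (or `NULL` when unlabeled)
#' @export
setGeneric("spectraLabels", function(x) standardGeneric("spectraLabels"))

#' Restrict to a wavenumber band
#'
#' Retains grid points p with `low(band) <= p <= high(band)`, bounds
#' inclusive at both ends, preserving grid order.
#'
#' @param x a [SpectraSet] or [CorrelationMaps]
#' @param band a [Band]
#' @return object of the same class on the restricted grid
#' @export
setGeneric("extractBand", function(x, band) standardGeneric("extractBand"))

#' Split membership accessor
#'
#' @param x a [SplitAssignment]
#' @return factor of train/test/external, named by sample id
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))

#' Synchronous map accessor
#' @param x a [CorrelationMaps]
#' @return square numeric matrix
#' @export
setGeneric("syncMap", function(x) standardGeneric("syncMap"))

#' Asynchronous map accessor
#' @param x a [CorrelationMaps]
#' @return square numeric matrix
#' @export
setGeneric("asyncMap", function(x) standardGeneric("asyncMap"))

#' Integrative map accessor
#' @param x a [CorrelationMaps]
#' @return square numeric matrix
#' @export
setGeneric("integrativeMapOf", function(x) standardGeneric("integrativeMapOf"))
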