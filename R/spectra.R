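#' Write a SpectraSet as a wide delimited table
#'
#' Tab-separated text: header row `label` + one column per wavenumber, then
#' one row per sample (first cell the class label, or `NA` when unlabeled).
#' Values are written with 17 significant digits so the round trip through
#' [readSpectra()] is bit-identical.  A JSON sidecar `<path>.json` records
#' the generation/processing metadata stored in the set.
#'
#' @param set a [SpectraSet]
#' @param path output file path
#' @param sidecar write the JSON metadata sidecar (default `TRUE`)
#' @return `path`, invisibly
#' @export
writeSpectra <- function(set, path, sidecar = TRUE) {
  stopifnot(methods::is(set, "SpectraSet"))
  wn <- wavenumbers(set)
  m <- absorbance(set)
  lab <- spectraLabels(set)
  if (is.null(lab)) lab <- rep(NA_character_, ncol(m))
  header <- paste(c("label", sprintf("%.17g", wn)), collapse = "\t")
  rows <- vapply(seq_len(ncol(m)), function(j)
    paste(c(lab[j], sprintf("%.17g", m[, j])), collapse = "\t"), character(1))
  writeLines(c(header, rows), path)
  if (sidecar) {
    md <- S4Vectors::metadata(set)
    jsonlite::write_json(
      list(format = "wide_table", nSamples = ncol(m), nWavenumbers = length(wn),
           metadata = md),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Read spectra from a wide delimited table
#'
#' Parses the format written by [writeSpectra()]: a header row of
#' wavenumbers (first cell a label-column marker) and one sample per row.
#' The grid is re-sorted descending if the file stores it ascending; labels
#' are preserved (`NA` labels yield an unlabeled set).
#'
#' @param path input file path
#' @param dialect table dialect; only `"wide_table"` is defined
#' @return a [SpectraSet]
#' @export
readSpectra <- function(path, dialect = "wide_table") {
  dialect <- match.arg(dialect, "wide_table")
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("wide_table needs a header and at least 1 row")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1]]
  if (length(header) < 3L)
    stop("format error in header: at least 2 grid points are required")
  wn <- suppressWarnings(as.numeric(header[-1]))
  if (anyNA(wn)) stop("format error in header: non-numeric wavenumber")
  p <- length(wn)
  n <- length(cells) - 1L
  m <- matrix(NA_real_, nrow = p, ncol = n)
  labels <- character(n)
  for (i in seq_len(n)) {
    row <- cells[[i + 1L]]
    if (length(row) != p + 1L)
      stop(sprintf("format error in row %d: expected %d cells, found %d",
                   i, p + 1L, length(row)))
    labels[i] <- row[1]
    vals <- suppressWarnings(as.numeric(row[-1]))
    if (anyNA(vals))
      stop(sprintf("format error in row %d: non-numeric absorbance cell", i))
    m[, i] <- vals
  }
  if (all(is.na(labels) | labels == "NA")) labels <- NULL
  if (is.unsorted(rev(wn), strictly = TRUE)) {
    if (is.unsorted(wn, strictly = TRUE)) {
      o <- order(wn, decreasing = TRUE)
      if (anyDuplicated(wn)) stop("duplicate wavenumbers in header")
      wn <- wn[o]; m <- m[o, , drop = FALSE]
    } else {  # strictly ascending: flip to the descending convention
      wn <- rev(wn); m <- m[rev(seq_len(p)), , drop = FALSE]
    }
  }
  SpectraSet(wn, m, labels = labels)
}

#' Normalize spectra
#'
#' Per-spectrum normalization: `"minmax"` rescales each spectrum linearly to
#' min 0 / max 1; `"vector"` divides by the Euclidean norm.  The method used
#' is recorded in `metadata(set)$normalization`.
#'
#' @param set a [SpectraSet]
#' @param method `"minmax"` (default) or `"vector"`
#' @return the normalized [SpectraSet]
#' @examples
#' ss <- generateDataset(2, 2, seed = 1)
#' range(absorbance(normalizeSpectra(ss))[, 1])
#' @export
normalizeSpectra <- function(set, method = c("minmax", "vector")) {
  method <- match.arg(method)
  m <- absorbance(set)
  m2 <- apply(m, 2, normalizeIntensities, method = method)
  md <- S4Vectors::metadata(set)
  md$normalization <- method
  SpectraSet(wavenumbers(set), m2, labels = spectraLabels(set),
             sampleIds = colnames(set), metadata = md)
}

#' @rdname normalizeSpectra
#' @param x numeric intensity vector
#' @return for `normalizeIntensities`, the normalized numeric vector
#' @examples
#' normalizeIntensities(c(2, 4, 6))          # 0 0.5 1
#' normalizeIntensities(c(3, 4), "vector")   # 0.6 0.8
#' @export
normalizeIntensities <- function(x, method = c("minmax", "vector")) {
  method <- match.arg(method)
  if (method == "minmax") {
    r <- range(x)
    if (r[2] - r[1] == 0)
      stop("minmax normalization undefined for a constant spectrum (zero range)")
    (x - r[1]) / (r[2] - r[1])
  } else {
    nrm <- sqrt(sum(x^2))
    if (nrm == 0) stop("vector normalization undefined for an all-zero spectrum")
    x / nrm
  }
}

#' Average spectra, optionally per class
#'
#' Pointwise mean over the shared grid; with `byLabel = TRUE` (default) one
#' average spectrum per class label, otherwise a single global average.
#'
#' @param set a [SpectraSet]
#' @param byLabel average within labels (requires a labeled set)
#' @return a [SpectraSet] of the average spectra
#' @export
averageSpectra <- function(set, byLabel = TRUE) {
  m <- absorbance(set)
  if (byLabel) {
    lab <- spectraLabels(set)
    if (is.null(lab)) stop("byLabel = TRUE requires a labeled set")
    u <- unique(lab)
    avg <- vapply(u, function(l) rowMeans(m[, lab == l, drop = FALSE]),
                  numeric(nrow(m)))
    SpectraSet(wavenumbers(set), avg, labels = u, sampleIds = paste0("avg_", u),
               metadata = S4Vectors::metadata(set))
  } else {
    SpectraSet(wavenumbers(set), matrix(rowMeans(m), ncol = 1),
               sampleIds = "avg", metadata = S4Vectors::metadata(set))
  }
}

#' @describeIn extractBand restrict a SpectraSet to one band (inclusive
#'   bounds); errors when no grid point falls inside the band
#' @export
setMethod("extractBand", signature("SpectraSet", "Band"), function(x, band) {
  wn <- wavenumbers(x)
  keep <- wn >= band@low & wn <= band@high
  if (!any(keep))
    stop(sprintf("band %s [%g, %g] contains no grid point",
                 band@name, band@low, band@high))
  SpectraSet(wn[keep], absorbance(x)[keep, , drop = FALSE],
             labels = spectraLabels(x), sampleIds = colnames(x),
             metadata = S4Vectors::metadata(x))
})

#' Concatenate several band extractions into one fused spectrum set
#'
#' Band-extracts `set` for each band and concatenates the pieces along the
#' wavenumber axis (bands are processed in order of descending upper bound;
#' a wavenumber shared by two adjacent bands is kept once, so the fused grid
#' stays strictly decreasing).  Used for fused-feature-band models.
#'
#' @param set a [SpectraSet]
#' @param bands list of [Band] objects
#' @return a [SpectraSet] on the fused grid
#' @export
fuseBands <- function(set, bands) {
  stopifnot(length(bands) >= 1L)
  bands <- bands[order(vapply(bands, function(b) b@high, numeric(1)),
                       decreasing = TRUE)]
  pieces <- lapply(bands, function(b) extractBand(set, b))
  wn <- unlist(lapply(pieces, wavenumbers))
  m <- do.call(rbind, lapply(pieces, absorbance))
  keep <- !duplicated(wn)
  SpectraSet(wn[keep], m[keep, , drop = FALSE], labels = spectraLabels(set),
             sampleIds = colnames(set), metadata = S4Vectors::metadata(set))
}
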