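#' Construct perturbation parameters
#'
#' @param nSteps number of perturbation steps n (>= 2); default 16
#' @param amplitude relative modulation depth (> 0); default 0.05
#' @param cycles sinusoid periods spanned by the n steps (> 0); default 1
#' @param phaseGradient phase advance in radians per cm^-1 across the grid;
#'   default 0 (all wavenumbers modulated in phase, which makes the
#'   asynchronous map identically zero -- set a nonzero gradient to obtain
#'   informative asynchronous maps)
#' @param mode `"multiplicative"` (modulates the spectrum, so dynamic
#'   amplitude is proportional to local absorbance) or `"additive"`
#' @return a [PerturbationParams]
#' @examples
#' perturbationParams()
#' @export
perturbationParams <- function(nSteps = 16L, amplitude = 0.05, cycles = 1,
                               phaseGradient = 0,
                               mode = c("multiplicative", "additive")) {
  mode <- match.arg(mode)
  if (as.integer(nSteps) < 2L) stop("nSteps must be >= 2")
  methods::new("PerturbationParams", nSteps = as.integer(nSteps),
               amplitude = as.numeric(amplitude), cycles = as.numeric(cycles),
               phaseGradient = as.numeric(phaseGradient), mode = mode)
}

setMethod("show", "PerturbationParams", function(object) {
  cat(sprintf(
    "PerturbationParams: n=%d, amplitude=%g, cycles=%g, phaseGradient=%g rad/cm^-1, %s\n",
    object@nSteps, object@amplitude, object@cycles, object@phaseGradient,
    object@mode))
})

#' Expand a spectrum into a sinusoidal perturbation series
#'
#' Row i (i = 1..n) at grid point v is
#' `s(v) * (1 + A * sin(2*pi*cycles*(i-1)/n + g*(v - v_ref)))`
#' in multiplicative mode, or `s(v) + A * sin(...)` in additive mode, with
#' `A = amplitude`, `g = phaseGradient` and `v_ref` the first grid point.
#' The construction is fully deterministic.
#'
#' @param intensities absorbance vector s(v)
#' @param wavenumbers matching grid (cm^-1)
#' @param params a [PerturbationParams]
#' @return nSteps x length(grid) matrix
#' @examples
#' buildPerturbationSeries(rep(1, 4), c(4, 3, 2, 1),
#'                         perturbationParams(nSteps = 4, amplitude = 0.1))
#' @export
buildPerturbationSeries <- function(intensities, wavenumbers, params) {
  stopifnot(methods::is(params, "PerturbationParams"))
  methods::validObject(params)
  if (length(intensities) != length(wavenumbers))
    stop("intensities and wavenumbers must have equal length")
  n <- params@nSteps
  phaseT <- 2 * pi * params@cycles * (seq_len(n) - 1) / n
  phaseV <- params@phaseGradient * (wavenumbers - wavenumbers[1])
  modul <- params@amplitude * sin(outer(phaseT, phaseV, `+`))
  if (params@mode == "multiplicative")
    sweep(1 + modul, 2, intensities, `*`)
  else
    sweep(modul, 2, intensities, `+`)
}

#' Mean-center a perturbation series into dynamic spectra
#'
#' Subtracts the per-wavenumber (per-column) mean over the perturbation
#' steps and stores that mean as the reference spectrum.
#'
#' @param series nSteps x nWavenumbers matrix (rows = steps)
#' @param wavenumbers grid (cm^-1); defaults to column indices
#' @return a [DynamicSpectra]
#' @examples
#' d <- makeDynamic(matrix(c(1, 3), ncol = 1))
#' d@values   # -1, +1
#' @export
makeDynamic <- function(series, wavenumbers = NULL) {
  series <- as.matrix(series)
  if (nrow(series) < 2L) stop("at least 2 perturbation steps are required")
  if (is.null(wavenumbers)) wavenumbers <- seq_len(ncol(series))
  if (length(wavenumbers) != ncol(series))
    stop("one wavenumber per series column is required")
  ref <- colMeans(series)
  methods::new("DynamicSpectra", wavenumbers = as.numeric(wavenumbers),
               values = sweep(series, 2, ref), reference = ref)
}

#' The discrete Hilbert-Noda matrix
#'
#' `N[j, k] = 0` when `j == k` and `1 / (pi * (k - j))` otherwise: the
#' antisymmetric kernel that effects a discrete Hilbert transform across
#' perturbation steps, turning in-phase into quadrature components for the
#' asynchronous map.
#'
#' @param n number of perturbation steps (>= 2)
#' @return n x n numeric matrix
#' @examples
#' hilbertNoda(3)
#' @export
hilbertNoda <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("n must be >= 2")
  jk <- outer(seq_len(n), seq_len(n), function(j, k) k - j)
  m <- 1 / (pi * jk)
  m[jk == 0L] <- 0
  m
}

#' Synchronous correlation map
#'
#' `Phi(v1, v2) = (1/(n-1)) * sum_i ytilde(v1, t_i) * ytilde(v2, t_i)`:
#' the covariance-like map of in-phase intensity variation.  Symmetric with
#' non-negative diagonal (auto-peaks).
#'
#' @param d a [DynamicSpectra]
#' @return square matrix over `d`'s grid
#' @export
synchronousMap <- function(d) {
  stopifnot(methods::is(d, "DynamicSpectra"))
  n <- nrow(d@values)
  if (n < 2L) stop("at least 2 perturbation steps are required")
  crossprod(d@values) / (n - 1)
}

#' Asynchronous correlation map
#'
#' `Psi(v1, v2) = (1/(n-1)) * ytilde(v1)^T N ytilde(v2)` with `N` the
#' [hilbertNoda()] matrix: the map of out-of-phase (quadrature) intensity
#' variation.  Antisymmetric with zero diagonal.
#'
#' @param d a [DynamicSpectra]
#' @return square matrix over `d`'s grid
#' @export
asynchronousMap <- function(d) {
  stopifnot(methods::is(d, "DynamicSpectra"))
  n <- nrow(d@values)
  if (n < 2L) stop("at least 2 perturbation steps are required")
  crossprod(d@values, hilbertNoda(n) %*% d@values) / (n - 1)
}

#' Integrative correlation map
#'
#' The elementwise product of the synchronous and asynchronous maps;
#' antisymmetric because it multiplies a symmetric by an antisymmetric
#' matrix elementwise.
#'
#' @param sync synchronous map
#' @param async asynchronous map of the same dimension
#' @return square matrix
#' @export
integrativeMap <- function(sync, async) {
  if (!all(dim(sync) == dim(async)))
    stop("sync and async must have identical dimensions")
  sync * async
}

#' Compute all three correlation maps for one spectrum
#'
#' Pipeline: optional band extraction, sinusoidal perturbation expansion,
#' mean-centering, then the synchronous, asynchronous and integrative maps.
#' Deterministic: identical inputs give bit-identical maps.
#'
#' @param intensities absorbance vector (or a 1-column [SpectraSet] via
#'   [mapDataset()] for whole sets)
#' @param wavenumbers matching grid (cm^-1)
#' @param band optional [Band] to restrict to first
#' @param params a [PerturbationParams]
#' @return a [CorrelationMaps]
#' @examples
#' ss <- generateDataset(1, 1, seed = 1)
#' cm <- computeCorrelationMaps(absorbance(ss)[, 1], wavenumbers(ss),
#'                              bandPreset("bandC"), perturbationParams())
#' cm
#' @export
computeCorrelationMaps <- function(intensities, wavenumbers, band = NULL,
                                   params = perturbationParams()) {
  if (!is.null(band)) {
    stopifnot(methods::is(band, "Band"))
    keep <- wavenumbers >= band@low & wavenumbers <= band@high
    if (!any(keep))
      stop(sprintf("band [%g, %g] contains no grid point", band@low, band@high))
    intensities <- intensities[keep]
    wavenumbers <- wavenumbers[keep]
  }
  series <- buildPerturbationSeries(intensities, wavenumbers, params)
  d <- makeDynamic(series, wavenumbers)
  sync <- synchronousMap(d)
  async <- asynchronousMap(d)
  methods::new("CorrelationMaps", wavenumbers = as.numeric(wavenumbers),
               sync = sync, async = async,
               integrative = integrativeMap(sync, async))
}

#' Correlation maps for every sample of a set
#'
#' One [CorrelationMaps] per sample: each sample's spectrum seeds its own
#' perturbation series.
#'
#' @param set a [SpectraSet]
#' @param band optional [Band]
#' @param params a [PerturbationParams]
#' @return named list of [CorrelationMaps], one per sample
#' @export
mapDataset <- function(set, band = NULL, params = perturbationParams()) {
  m <- absorbance(set)
  wn <- wavenumbers(set)
  out <- lapply(seq_len(ncol(m)), function(j)
    computeCorrelationMaps(m[, j], wn, band = band, params = params))
  names(out) <- colnames(set)
  out
}
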