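# Characteristic mid-IR fingerprint positions used by the default recipes:
# O-H stretch (3292), methylene asym./sym. C-H stretch (2922/2849), ester C=O
# (1732), terpenoid C-C (1610), lignin ring skeleton (1510, 1422), methylene
# deformation (1371), saccharide C-OH (1030) and C-H bending (920) cm^-1.
.fingerprintCenters <- c(3292, 2922, 2849, 1732, 1610, 1510, 1422, 1371,
                         1030, 920)
# half-widths (cm^-1): broad O-H, narrow C-H stretches, medium fingerprint
.fingerprintWidths <- c(95, 20, 18, 18, 25, 15, 20, 15, 40, 20)
# base amplitudes (a.u.), roughly the relative prominence seen in dried
# plant-material spectra (strong O-H and saccharide bands)
.fingerprintAmplitudes <- c(0.90, 0.55, 0.45, 0.50, 0.60, 0.40, 0.45, 0.35,
                            0.85, 0.30)

#' Describe one spectral peak
#'
#' @param center peak position (cm^-1)
#' @param width half-width at half-maximum-like scale parameter (cm^-1, > 0);
#'   for the gaussian shape it is the standard deviation, for the lorentzian
#'   the half-width at half maximum
#' @param amplitude peak height (a.u., >= 0)
#' @param shape `"gaussian"` or `"lorentzian"`
#' @return one-row data.frame with columns center, width, amplitude, shape
#' @examples
#' peakSpec(1732, 18, 0.5)
#' @export
peakSpec <- function(center, width, amplitude, shape = "gaussian") {
  stopifnot(length(center) == 1L, length(width) == 1L, length(amplitude) == 1L)
  if (!(width > 0)) stop("width must be > 0")
  if (amplitude < 0) stop("amplitude must be >= 0")
  shape <- match.arg(shape, c("gaussian", "lorentzian"))
  data.frame(center = as.numeric(center), width = as.numeric(width),
             amplitude = as.numeric(amplitude), shape = shape,
             stringsAsFactors = FALSE)
}

#' Describe one synthetic class
#'
#' A class recipe is the generative model of one species-like class: a set of
#' peaks ([peakSpec()] rows), a linear baseline slope and an additive noise
#' standard deviation.
#'
#' @param label class identifier
#' @param peaks data.frame of stacked [peakSpec()] rows (>= 1 peak)
#' @param baselineSlope baseline slope in a.u. per cm^-1
#' @param noiseSd standard deviation of i.i.d. zero-mean gaussian noise (a.u.)
#' @return a list of class `"ClassRecipe"`
#' @export
classRecipe <- function(label, peaks, baselineSlope = 0, noiseSd = 0) {
  if (!is.data.frame(peaks) || nrow(peaks) < 1L)
    stop("at least one peak is required")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (any(peaks$width <= 0)) stop("peak widths must be > 0")
  if (any(peaks$amplitude < 0)) stop("peak amplitudes must be >= 0")
  structure(list(label = as.character(label), peaks = peaks,
                 baselineSlope = as.numeric(baselineSlope),
                 noiseSd = as.numeric(noiseSd)),
            class = "ClassRecipe")
}

#' @export
print.ClassRecipe <- function(x, ...) {
  cat(sprintf("ClassRecipe '%s': %d peaks, baseline %.2g a.u./cm^-1, noise sd %.3g\n",
              x$label, nrow(x$peaks), x$baselineSlope, x$noiseSd))
  invisible(x)
}

#' Default multi-class recipes with shared peak positions
#'
#' Builds `nClasses` recipes that share the ten characteristic fingerprint
#' peak positions (3292, 2922, 2849, 1732, 1610, 1510, 1422, 1371, 1030,
#' 920 cm^-1) and differ only in peak amplitudes: each class multiplies the
#' base amplitudes by reproducible log-normal factors with log-sd
#' `amplitudeSpread`.  This mirrors the situation in closely related plant
#' species, whose spectra show near-identical peak positions but
#' class-specific peak intensities.  Optional `centerJitter` (off by default)
#' adds a small class-specific shift to peak positions.
#'
#' @param nClasses number of classes (1..26; labeled `classA`, `classB`, ...)
#' @param seed integer seed; recipes are a pure function of
#'   `(nClasses, seed, amplitudeSpread, centerJitter)`
#' @param amplitudeSpread sd of the per-class, per-peak log amplitude
#'   multiplier (0 collapses all classes onto one mean spectrum)
#' @param centerJitter sd in cm^-1 of class-specific peak-position shifts
#'   (default 0: positions exactly shared)
#' @param noiseSd per-spectrum additive noise sd (a.u.)
#' @return list of [classRecipe()] objects
#' @examples
#' r <- defaultRecipes(7, seed = 1)
#' length(r)
#' r[[1]]$peaks$center
#' @export
defaultRecipes <- function(nClasses, seed, amplitudeSpread = 0.25,
                           centerJitter = 0, noiseSd = 0.005) {
  nClasses <- as.integer(nClasses)
  if (is.na(nClasses) || nClasses < 1L || nClasses > 26L)
    stop("nClasses must be between 1 and 26")
  rng <- .localRNG(seed)
  labels <- paste0("class", LETTERS[seq_len(nClasses)])
  lapply(seq_len(nClasses), function(i) {
    mult <- exp(rng$rnorm(length(.fingerprintCenters), 0, amplitudeSpread))
    centers <- .fingerprintCenters +
      if (centerJitter > 0) rng$rnorm(length(.fingerprintCenters), 0, centerJitter) else 0
    peaks <- do.call(rbind, lapply(seq_along(centers), function(j)
      peakSpec(centers[j], .fingerprintWidths[j],
               .fingerprintAmplitudes[j] * mult[j])))
    slope <- rng$runif(1, -2e-5, 2e-5)
    classRecipe(labels[i], peaks, baselineSlope = slope, noiseSd = noiseSd)
  })
}

# Seeded RNG stream that never touches the global .Random.seed.
.localRNG <- function(seed) {
  seed <- as.integer(seed)
  env <- new.env()
  local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  withState <- function(f) function(...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    f(...)
  }
  list(rnorm = withState(stats::rnorm), runif = withState(stats::runif),
       sample = withState(base::sample))
}

#' Evaluate one synthetic spectrum on a grid
#'
#' The spectrum is the sum of the recipe's peak profiles, a linear baseline
#' `baselineSlope * (v - min(v))`, and i.i.d. zero-mean gaussian noise with
#' sd `noiseSd`.
#'
#' @param recipe a [classRecipe()]
#' @param grid wavenumber grid (cm^-1), non-empty
#' @param seed integer seed for the noise draw
#' @return numeric absorbance vector over `grid`
#' @examples
#' g <- seq(2000, 1000, by = -4)
#' r <- classRecipe("x", peakSpec(1500, 20, 1))
#' s <- generateSpectrum(r, g, seed = 1)
#' g[which.max(s)]
#' @export
generateSpectrum <- function(recipe, grid, seed) {
  if (!inherits(recipe, "ClassRecipe")) stop("recipe must be a ClassRecipe")
  grid <- as.numeric(grid)
  if (!length(grid)) stop("grid must be non-empty")
  y <- .peakSum(recipe$peaks, grid) + recipe$baselineSlope * (grid - min(grid))
  if (recipe$noiseSd > 0) {
    rng <- .localRNG(seed)
    y <- y + rng$rnorm(length(grid), 0, recipe$noiseSd)
  }
  y
}

.peakSum <- function(peaks, grid) {
  y <- numeric(length(grid))
  for (j in seq_len(nrow(peaks))) {
    d <- grid - peaks$center[j]
    w <- peaks$width[j]
    y <- y + if (peaks$shape[j] == "gaussian")
      peaks$amplitude[j] * exp(-0.5 * (d / w)^2)
    else
      peaks$amplitude[j] * w^2 / (d^2 + w^2)
  }
  y
}

#' Build a wavenumber grid from start/stop/step
#'
#' Points run from `start` towards `stop` in steps of `step` cm^-1, both
#' endpoints inclusive when hit exactly; a final partial step is dropped.
#' The default spectrometer-style grid 4010 -> 365 at 4 cm^-1 therefore has
#' 912 points and ends at 366 cm^-1.
#'
#' @param start,stop range bounds (cm^-1); `start > stop` gives the
#'   conventional descending grid
#' @param step grid spacing (cm^-1, > 0)
#' @return numeric grid
#' @examples
#' length(wavenumberGrid())  # 912
#' @export
wavenumberGrid <- function(start = 4010, stop = 365, step = 4) {
  if (!(step > 0)) stop("step must be > 0")
  if (start == stop) stop("start and stop must differ")
  seq(start, stop, by = if (start > stop) -step else step)
}

#' Generate a labeled multi-class synthetic dataset
#'
#' Draws `nPerClass` spectra from each of `nClasses` class recipes (shared
#' peak positions, class-specific amplitudes; see [defaultRecipes()]).  On
#' top of the per-spectrum noise of the recipe, each sample's peak
#' amplitudes receive a small multiplicative log-normal jitter
#' (`sampleJitter` log-sd) emulating replicate-to-replicate scatter.
#'
#' @param nClasses,nPerClass positive counts
#' @param gridSpec list or named vector with `start`, `stop`, `step`
#'   (cm^-1); default 4010 -> 365 at 4
#' @param seed integer seed governing recipes, jitter and noise
#' @param recipes optional recipe list overriding [defaultRecipes()]
#' @param amplitudeSpread,centerJitter,noiseSd passed to [defaultRecipes()]
#' @param sampleJitter log-sd of per-sample amplitude jitter (0 disables)
#' @return a [SpectraSet] with `nClasses * nPerClass` spectra
#' @examples
#' ss <- generateDataset(3, 4, seed = 1)
#' dim(absorbance(ss))
#' table(spectraLabels(ss))
#' @export
generateDataset <- function(nClasses, nPerClass,
                            gridSpec = list(start = 4010, stop = 365, step = 4),
                            seed = 1L, recipes = NULL,
                            amplitudeSpread = 0.25, centerJitter = 0,
                            noiseSd = 0.005, sampleJitter = 0.03) {
  nClasses <- as.integer(nClasses); nPerClass <- as.integer(nPerClass)
  if (is.na(nClasses) || nClasses < 1L) stop("nClasses must be positive")
  if (is.na(nPerClass) || nPerClass < 1L) stop("nPerClass must be positive")
  gridSpec <- as.list(gridSpec)
  grid <- wavenumberGrid(gridSpec$start, gridSpec$stop, gridSpec$step)
  if (is.null(recipes))
    recipes <- defaultRecipes(nClasses, seed, amplitudeSpread = amplitudeSpread,
                              centerJitter = centerJitter, noiseSd = noiseSd)
  if (length(recipes) != nClasses)
    stop("recipes must have one entry per class")
  rng <- .localRNG(seed + 1000003L)
  mats <- vector("list", nClasses * nPerClass)
  labels <- character(nClasses * nPerClass)
  k <- 0L
  for (i in seq_len(nClasses)) {
    rec <- recipes[[i]]
    for (s in seq_len(nPerClass)) {
      k <- k + 1L
      r <- rec
      if (sampleJitter > 0)
        r$peaks$amplitude <- r$peaks$amplitude *
          exp(rng$rnorm(nrow(r$peaks), 0, sampleJitter))
      noiseSeed <- as.integer((seed * 97L + i * 131L + s * 7919L) %% .Machine$integer.max)
      mats[[k]] <- generateSpectrum(r, grid, seed = noiseSeed)
      labels[k] <- rec$label
    }
  }
  SpectraSet(grid, do.call(cbind, mats), labels = labels,
             metadata = list(generator = list(
               nClasses = nClasses, nPerClass = nPerClass, seed = seed,
               gridSpec = gridSpec, amplitudeSpread = amplitudeSpread,
               centerJitter = centerJitter, noiseSd = noiseSd,
               sampleJitter = sampleJitter)))
}
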