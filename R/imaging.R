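#' Construct a render configuration
#'
#' @param size output image side in pixels (>= 32); default 224
#' @param colormap palette name understood by [divergingPalette()]
#' @param scaling `"symmetric_max"` (default) or `"percentile"`
#' @param style `"heatmap"` (default) or `"filled_contour"`
#' @param contourLevels bins for the filled-contour style
#' @param percentile clip quantile when `scaling = "percentile"`
#' @return a [RenderConfig]
#' @export
renderConfig <- function(size = 224L, colormap = "blueWhiteRed",
                         scaling = c("symmetric_max", "percentile"),
                         style = c("heatmap", "filled_contour"),
                         contourLevels = 10L, percentile = 0.99) {
  methods::new("RenderConfig", size = as.integer(size), colormap = colormap,
               scaling = match.arg(scaling), style = match.arg(style),
               contourLevels = as.integer(contourLevels),
               percentile = as.numeric(percentile))
}

#' Deterministic diverging palettes
#'
#' Fixed-anchor palettes interpolated with [grDevices::colorRampPalette];
#' the midpoint of each palette is a neutral color so that zero-centered
#' scaling puts zero at neutral.
#'
#' @param name `"blueWhiteRed"`, `"purpleWhiteGreen"` or `"blueYellowRed"`
#' @param n number of colors
#' @return matrix n x 3 of RGB values in `[0, 1]`
#' @export
divergingPalette <- function(name = "blueWhiteRed", n = 256L) {
  anchors <- switch(name,
    blueWhiteRed = c("#2166AC", "#F7F7F7", "#B2182B"),
    purpleWhiteGreen = c("#762A83", "#F7F7F7", "#1B7837"),
    blueYellowRed = c("#2C7BB6", "#FFFFBF", "#D7191C"),
    stop("unknown colormap '", name, "'"))
  cols <- grDevices::colorRampPalette(anchors, space = "Lab")(n)
  t(grDevices::col2rgb(cols)) / 255
}

# Bilinear resampling of a matrix to size x size, cell-centered coordinates.
# The row and column mappings are identical, so resampling commutes with
# matrix transposition.
.resampleBilinear <- function(m, size) {
  p <- nrow(m)
  if (p == size) return(m)
  # target pixel centers mapped into source cell-center coordinates (1..p)
  pos <- (seq_len(size) - 0.5) * p / size + 0.5
  lo <- as.integer(pmax(1L, pmin(p - 1L, floor(pos))))
  frac <- pmin(1, pmax(0, pos - lo))
  # interpolate rows then columns with the same weights
  a <- m[lo, , drop = FALSE] * (1 - frac) + m[lo + 1L, , drop = FALSE] * frac
  a[, lo, drop = FALSE] * rep(1 - frac, each = size) +
    a[, lo + 1L, drop = FALSE] * rep(frac, each = size)
}

#' Render a correlation matrix as an RGB image
#'
#' Deterministic matrix-to-image mapping: the matrix is scaled to `[-1, 1]`
#' (symmetric about zero, so zero lands on the palette midpoint), optionally
#' quantized into contour levels, bilinearly resampled to `size x size`, and
#' passed through the diverging palette.  Under `symmetric_max` scaling the
#' image is invariant to multiplying the matrix by any positive constant.
#'
#' @param m square numeric matrix
#' @param cfg a [RenderConfig]
#' @param zeroFloor matrices whose maximal absolute entry does not exceed
#'   this value are rendered flat at the palette midpoint instead of being
#'   rescaled; callers that render families of maps (e.g. [renderDataset()])
#'   use it to keep maps that are zero up to floating-point roundoff --
#'   such as the asynchronous map of an in-phase perturbation -- from having
#'   their roundoff noise amplified to full contrast.  Default 0 (any
#'   nonzero matrix is rescaled)
#' @return numeric array `size x size x 3`, values in `[0, 1]`
#' @examples
#' img <- renderMap(diag(4), renderConfig(size = 32))
#' dim(img)
#' @export
renderMap <- function(m, cfg = renderConfig(), zeroFloor = 0) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("input matrix must be square")
  stopifnot(methods::is(cfg, "RenderConfig"))
  methods::validObject(cfg)
  scale <- if (cfg@scaling == "symmetric_max") max(abs(m))
           else stats::quantile(abs(m), cfg@percentile, names = FALSE)
  v <- if (scale > max(0, zeroFloor)) pmin(pmax(m / scale, -1), 1) else m * 0
  u <- (v + 1) / 2
  u <- .resampleBilinear(u, cfg@size)
  if (cfg@style == "filled_contour") {   # quantize after resampling so the
    k <- cfg@contourLevels               # image has exactly k levels
    u <- (pmin(floor(u * k), k - 1L) + 0.5) / k
  }
  pal <- divergingPalette(cfg@colormap, 256L)
  idx <- matrix(pmin(256L, pmax(1L, as.integer(round(u * 255)) + 1L)),
                nrow = cfg@size)
  array(pal[idx, ], dim = c(cfg@size, cfg@size, 3L))
}

#' Save / load an image losslessly
#'
#' PNG round trips are exact for 8-bit channel data; `renderMap()` output is
#' quantized to the 256-entry palette, so save/load reproduces pixel values.
#'
#' @param img numeric array H x W x 3 in `[0, 1]`
#' @param path file path (`.png`)
#' @param force overwrite an existing file (default `FALSE`: refuse)
#' @return `path` invisibly (for `saveImage`); the image array (for
#'   `loadImage`)
#' @export
saveImage <- function(img, path, force = FALSE) {
  if (file.exists(path) && !force)
    stop("refusing to overwrite '", path, "' (use force = TRUE)")
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  png::writePNG(img, path)
  invisible(path)
}

#' @rdname saveImage
#' @export
loadImage <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3L))
  img[, , 1:3, drop = FALSE]
}

#' Render a list of correlation maps into a class-partitioned directory tree
#'
#' Writes `<outDir>/<set>/<label>/<sampleId>_<mapType>.png` for every sample,
#' where `<set>` is the sample's split membership, plus a `manifest.json`
#' listing every file with its sample, label, map type and split.
#'
#' @param maps named list of [CorrelationMaps] (one per sample, names =
#'   sample ids), as returned by [mapDataset()]
#' @param labels class label per sample (same order as `maps`)
#' @param split a [SplitAssignment] covering the sample ids
#' @param outDir output directory
#' @param cfg a [RenderConfig]
#' @param mapType `"sync"`, `"async"` or `"integrative"`
#' @param bandName recorded in the manifest
#' @param force overwrite existing files
#' @return manifest as a data.frame, invisibly
#' @export
renderDataset <- function(maps, labels, split, outDir, cfg = renderConfig(),
                          mapType = c("sync", "async", "integrative"),
                          bandName = "full", force = FALSE) {
  mapType <- match.arg(mapType)
  stopifnot(methods::is(split, "SplitAssignment"))
  ids <- names(maps)
  if (is.null(ids)) stop("maps must be named by sample id")
  mem <- membership(split)
  if (!all(ids %in% names(mem))) stop("split does not cover all samples")
  rows <- vector("list", length(maps))
  for (i in seq_along(maps)) {
    m <- switch(mapType, sync = maps[[i]]@sync, async = maps[[i]]@async,
                integrative = maps[[i]]@integrative)
    floor_i <- 1e-8 * max(abs(maps[[i]]@sync), abs(maps[[i]]@async))
    rel <- file.path(as.character(mem[[ids[i]]]), labels[i],
                     sprintf("%s_%s.png", ids[i], mapType))
    saveImage(renderMap(m, cfg, zeroFloor = floor_i), file.path(outDir, rel),
              force = force)
    rows[[i]] <- data.frame(file = rel, sample = ids[i], label = labels[i],
                            mapType = mapType, band = bandName,
                            split = as.character(mem[[ids[i]]]),
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
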