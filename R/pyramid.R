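#' @include AllClasses.R
NULL

## Images are numeric matrices [height, width] or arrays
## [height, width, channels] with values in [0, 1]; pixel (x, y) uses
## 0-based level-0 coordinates, origin top-left, y downwards, and all
## pixel windows are half-open.

#' Deep Zoom maximum level
#'
#' The deepest pyramid level index: the smallest L such that halving
#' `max(width, height)` L times (ceiling division) reaches 1.  Level L
#' holds the full-resolution image, level 0 is a single pixel, so the
#' pyramid has `L + 1` levels.
#'
#' @param x image width in pixels, or a [PyramidSpec-class].
#' @param ... `height` when `x` is a width.
#' @return integer level index >= 0.
#' @examples
#' maxLevel(1024, 768)  # 10
#' @export
setMethod("maxLevel", "numeric", function(x, ...) {
  height <- c(...)[1L]
  if (length(x) != 1L || length(height) != 1L ||
      !is.finite(x) || !is.finite(height) || x < 1 || height < 1)
    stop("width and height must be positive")
  m <- max(x, height)
  as.integer(ceiling(log2(m)))
})

#' @rdname maxLevel-numeric-method
#' @export
setMethod("maxLevel", "PyramidSpec", function(x, ...)
  maxLevel(as.numeric(x@width), as.numeric(x@height)))

#' Pixel dimensions of one pyramid level
#'
#' @param x a [PyramidSpec-class].
#' @param level level index in `0..maxLevel(x)`.
#' @return integer `c(width, height)` of the level, each the ceiling of
#'   the level-0 dimension divided by `2^(maxLevel - level)`.
#' @export
setMethod("levelDimensions", "PyramidSpec", function(x, level) {
  L <- maxLevel(x)
  if (length(level) != 1L || level < 0L || level > L)
    stop(sprintf("level must be in [0, %d], got %s", L, level))
  s <- 2^(L - level)
  as.integer(ceiling(c(x@width, x@height) / s))
})

#' Tile grid of one pyramid level
#'
#' @inheritParams levelDimensions-PyramidSpec-method
#' @return integer `c(columns, rows)`: ceiling of the level dimensions
#'   divided by the tile size.
#' @export
setMethod("tileGrid", "PyramidSpec", function(x, level) {
  d <- levelDimensions(x, level)
  as.integer(ceiling(d / x@tileSize))
})

#' Extract one Deep Zoom tile from a level image
#'
#' Copies the pixel window
#' `[col*tileSize - overlap, (col+1)*tileSize + overlap)` by
#' `[row*tileSize - overlap, (row+1)*tileSize + overlap)`, clipped to the
#' level bounds.  Interior tiles therefore have side
#' `tileSize + 2*overlap`; border tiles are smaller.
#'
#' @param image pixel matrix/array of the *level* being tiled (its
#'   dimensions decide clipping, not the level-0 size).
#' @param spec a [PyramidSpec-class] (tile size and overlap).
#' @param level,col,row tile address; `col`/`row` are 0-based.
#' @return the tile pixel array, with attributes `level`, `col`, `row`.
#' @export
getTile <- function(image, spec, level, col, row) {
  h <- dim(image)[1L]; w <- dim(image)[2L]
  ts <- spec@tileSize; ov <- spec@overlap
  ncol_t <- ceiling(w / ts); nrow_t <- ceiling(h / ts)
  if (col < 0L || col >= ncol_t)
    stop(sprintf("tile col %d outside grid [0, %d)", col, ncol_t))
  if (row < 0L || row >= nrow_t)
    stop(sprintf("tile row %d outside grid [0, %d)", row, nrow_t))
  x0 <- max(0L, col * ts - ov); x1 <- min(w, (col + 1L) * ts + ov)
  y0 <- max(0L, row * ts - ov); y1 <- min(h, (row + 1L) * ts + ov)
  tile <- if (length(dim(image)) == 3L)
    image[(y0 + 1L):y1, (x0 + 1L):x1, , drop = FALSE]
  else
    image[(y0 + 1L):y1, (x0 + 1L):x1, drop = FALSE]
  attr(tile, "level") <- as.integer(level)
  attr(tile, "col") <- as.integer(col)
  attr(tile, "row") <- as.integer(row)
  tile
}

#' Downsample an image by 2 with area averaging
#'
#' Output dimensions are the ceiling of half the input dimensions; each
#' output pixel is the mean of its 2x2 source block, with odd-sized
#' edges averaging the available pixels only.
#'
#' @param image matrix or h x w x c array in `[0, 1]`.
#' @return downsampled image of the same kind.
#' @export
downsample2x <- function(image) {
  ds <- function(m) {
    h <- nrow(m); w <- ncol(m)
    if (h %% 2L == 1L) m <- rbind(m, m[h, , drop = FALSE])
    if (w %% 2L == 1L) m <- cbind(m, m[, ncol(m), drop = FALSE])
    h2 <- nrow(m); w2 <- ncol(m)
    (m[seq(1L, h2, 2L), seq(1L, w2, 2L), drop = FALSE] +
     m[seq(2L, h2, 2L), seq(1L, w2, 2L), drop = FALSE] +
     m[seq(1L, h2, 2L), seq(2L, w2, 2L), drop = FALSE] +
     m[seq(2L, h2, 2L), seq(2L, w2, 2L), drop = FALSE]) / 4
  }
  if (length(dim(image)) == 3L) {
    ch <- lapply(seq_len(dim(image)[3L]), function(k) ds(image[, , k]))
    array(unlist(ch), dim = c(dim(ch[[1L]]), length(ch)))
  } else ds(image)
}

#' DZI descriptor XML for a pyramid
#'
#' @param spec a [PyramidSpec-class].
#' @return a single XML string in the Deep Zoom descriptor schema.
#' @export
dziDescriptor <- function(spec) {
  sprintf(paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<Image xmlns="http://schemas.microsoft.com/deepzoom/2008" ',
    'Format="%s" Overlap="%d" TileSize="%d">',
    '<Size Width="%d" Height="%d"/></Image>'),
    spec@format, spec@overlap, spec@tileSize, spec@width, spec@height)
}

#' Encode / decode one tile as an image file byte stream
#'
#' @param tile pixel matrix/array in `[0, 1]`.
#' @param format `"png"` (lossless) or `"jpeg"`.
#' @return `encodeTile()`: a raw vector; `decodeTile()`: the pixel array.
#' @export
encodeTile <- function(tile, format = "png") {
  attributes(tile)[c("level", "col", "row")] <- NULL
  switch(format,
         png = png::writePNG(tile),
         jpeg = jpeg::writeJPEG(tile, quality = 0.9),
         stop(sprintf("unsupported tile format '%s'", format)))
}

#' @param bytes raw vector as produced by `encodeTile()`.
#' @rdname encodeTile
#' @export
decodeTile <- function(bytes, format = "png") {
  switch(format,
         png = png::readPNG(bytes),
         jpeg = jpeg::readJPEG(bytes),
         stop(sprintf("unsupported tile format '%s'", format)))
}

#' Build a full Deep Zoom pyramid on disk
#'
#' Writes every tile of every level (adjacent levels related by 2x area
#' averaging) under `{outDir}/{name}_files/{level}/{col}_{row}.{fmt}`
#' plus the DZI descriptor `{outDir}/{name}.dzi`.
#'
#' @param image level-0 pixel matrix/array; dimensions must match `spec`.
#' @param spec a [PyramidSpec-class].
#' @param outDir output directory (created if needed).
#' @param name layer name used for the descriptor and tile directory.
#' @return invisibly, a list with `dzi` (descriptor path), `tileDir` and
#'   `nTiles`.
#' @export
buildPyramid <- function(image, spec, outDir, name = "image") {
  if (dim(image)[1L] != spec@height || dim(image)[2L] != spec@width)
    stop("image dimensions do not match spec")
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create output directory '%s'", outDir))
  tileDir <- file.path(outDir, paste0(name, "_files"))
  L <- maxLevel(spec)
  nTiles <- 0L
  cur <- image
  for (level in L:0) {
    lvDir <- file.path(tileDir, level)
    dir.create(lvDir, recursive = TRUE, showWarnings = FALSE)
    grid <- c(ceiling(dim(cur)[2L] / spec@tileSize),
              ceiling(dim(cur)[1L] / spec@tileSize))
    for (row in 0:(grid[2L] - 1L)) for (col in 0:(grid[1L] - 1L)) {
      tile <- getTile(cur, spec, level, col, row)
      path <- file.path(lvDir, sprintf("%d_%d.%s", col, row, spec@format))
      ok <- try(writeBin(encodeTile(tile, spec@format), path), silent = TRUE)
      if (inherits(ok, "try-error"))
        stop(sprintf("cannot write tile '%s'", path))
      nTiles <- nTiles + 1L
    }
    if (level > 0L) cur <- downsample2x(cur)
  }
  dziPath <- file.path(outDir, paste0(name, ".dzi"))
  writeLines(dziDescriptor(spec), dziPath, sep = "")
  invisible(list(dzi = dziPath, tileDir = tileDir, nTiles = nTiles))
}

#' Cross-layer patch extraction
#'
#' Extracts the same axis-aligned square window, centered at a clicked
#' level-0 pixel, from every image layer at full resolution -- the
#' signal-inspection view for multiplexed image stacks.  The window is
#' clipped at image borders.
#'
#' @param layers list of images sharing level-0 dimensions.
#' @param x,y 0-based center pixel.
#' @param size window side in pixels (>= 1); the window spans
#'   `x - floor((size-1)/2) .. x + floor(size/2)` and likewise in y.
#' @return a list with one patch per layer (equal shapes).
#' @export
getPatch <- function(layers, x, y, size) {
  if (!length(layers)) stop("no layers")
  if (size < 1L) stop("size must be >= 1")
  h <- dim(layers[[1L]])[1L]; w <- dim(layers[[1L]])[2L]
  for (l in layers)
    if (dim(l)[1L] != h || dim(l)[2L] != w)
      stop("all layers must share level-0 dimensions")
  if (x < 0 || x >= w || y < 0 || y >= h)
    stop(sprintf("point (%g, %g) outside image %d x %d", x, y, w, h))
  x0 <- max(0L, as.integer(x) - (size - 1L) %/% 2L)
  x1 <- min(w - 1L, as.integer(x) + size %/% 2L)
  y0 <- max(0L, as.integer(y) - (size - 1L) %/% 2L)
  y1 <- min(h - 1L, as.integer(y) + size %/% 2L)
  lapply(layers, function(l) {
    if (length(dim(l)) == 3L) l[(y0 + 1L):(y1 + 1L), (x0 + 1L):(x1 + 1L), ,
                                drop = FALSE]
    else l[(y0 + 1L):(y1 + 1L), (x0 + 1L):(x1 + 1L), drop = FALSE]
  })
}

#' Per-layer display parameters
#'
#' Identity defaults leave pixels unchanged.  Adjustment order when
#' compositing: contrast, then brightness, then gamma, then color and
#' opacity.
#'
#' @param brightness additive offset in `[-1, 1]`.
#' @param contrast multiplicative gain >= 0.
#' @param gamma exponent > 0.
#' @param opacity layer opacity in `[0, 1]`.
#' @param color length-3 RGB triple in `[0, 1]`, or a color name.
#' @return a named list of validated parameters.
#' @export
displayParams <- function(brightness = 0, contrast = 1, gamma = 1,
                          opacity = 1, color = c(1, 1, 1)) {
  if (is.character(color)) color <- as.numeric(col2rgb(color)) / 255
  stopifnot(length(color) == 3L, all(color >= 0 & color <= 1),
            brightness >= -1, brightness <= 1, contrast >= 0, gamma > 0,
            opacity >= 0, opacity <= 1)
  list(brightness = brightness, contrast = contrast, gamma = gamma,
       opacity = opacity, color = color)
}

#' Composite single-channel layers into one RGB image
#'
#' Each layer pixel `p` in `[0, 1]` is mapped to
#' `clamp(p * contrast + brightness)^gamma * color * opacity`; layers
#' are then summed additively and clamped to `[0, 1]`.
#'
#' @param patches list of single-channel images of equal shape.
#' @param params list of [displayParams()] lists, one per layer.
#' @return an h x w x 3 RGB array.
#' @export
compositeLayers <- function(patches, params) {
  if (length(patches) != length(params))
    stop("one DisplayParams per layer required")
  d <- dim(patches[[1L]])[1:2]
  out <- array(0, dim = c(d, 3L))
  for (i in seq_along(patches)) {
    p <- patches[[i]]
    if (length(dim(p)) == 3L) {
      if (dim(p)[3L] != 1L) stop("patches must be single-channel")
      p <- p[, , 1L]
    }
    if (!all(dim(p) == d)) stop("patch shape mismatch")
    pp <- params[[i]]
    v <- pmin(1, pmax(0, p * pp$contrast + pp$brightness))^pp$gamma
    for (ch in 1:3)
      out[, , ch] <- out[, , ch] + v * pp$color[ch] * pp$opacity
  }
  pmin(pmax(out, 0), 1)   # argument order keeps the array dims
}

#' Read / write an image file (PNG, TIFF or JPEG, by extension)
#'
#' @param path file path; the extension selects the codec.
#' @return `readImageFile()`: pixel matrix/array in `[0, 1]`.
#' @export
readImageFile <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    jpg = , jpeg = jpeg::readJPEG(path),
    stop(sprintf("unsupported image extension '.%s'", ext)))
  img
}

#' @param image pixel matrix/array in `[0, 1]`.
#' @rdname readImageFile
#' @export
writeImageFile <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(image, path),
    tif = , tiff = tiff::writeTIFF(image, path, bits.per.sample = 8L),
    jpg = , jpeg = jpeg::writeJPEG(image, path, quality = 0.9),
    stop(sprintf("unsupported image extension '.%s'", ext)))
  invisible(path)
}
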