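#' @include AllClasses.R
NULL

#' Create a viewer project configuration
#'
#' The project schema (versioned JSON, conventionally saved with a
#' `.tmap` extension) lists image layers with display parameters,
#' marker tabs with column roles and style defaults, region files and
#' the initial viewport.
#'
#' @param layers list of layer lists: `name`, `source` (image path),
#'   optional `displayParams` (see [displayParams()]), `mode`
#'   (`"composite"` or `"collection"`) and `offset` (side-by-side
#'   placement in collection mode).
#' @param markerTabs list of tab lists: `name`, `path` (CSV), `roles`,
#'   optional `style`.
#' @param regionFiles character vector of GeoJSON paths.
#' @param view initial viewport `list(x, y, width, height)` in level-0
#'   pixels.
#' @param tileSize,overlap,format pyramid parameters shared by the
#'   layers.
#' @return a validated project list (`schemaVersion` 1).
#' @export
makeProject <- function(layers, markerTabs = list(),
                        regionFiles = character(), view = NULL,
                        tileSize = 254L, overlap = 1L, format = "png") {
  proj <- list(schemaVersion = 1L,
               tileSize = as.integer(tileSize),
               overlap = as.integer(overlap), format = format,
               layers = layers, markerTabs = markerTabs,
               regionFiles = as.character(regionFiles), view = view)
  validateProject(proj)
  proj
}

validateProject <- function(proj, dir = ".") {
  if (is.null(proj$schemaVersion)) stop("project lacks schemaVersion")
  resolve <- function(p) if (file.exists(p)) p else file.path(dir, p)
  for (ly in proj$layers) {
    if (is.null(ly$name) || is.null(ly$source)) stop("layer needs name/source")
    if (!file.exists(resolve(ly$source)))
      stop(sprintf("layer source '%s' does not exist", ly$source))
  }
  for (tb in proj$markerTabs)
    if (!file.exists(resolve(tb$path)))
      stop(sprintf("marker tab path '%s' does not exist", tb$path))
  for (rf in proj$regionFiles)
    if (!file.exists(resolve(rf)))
      stop(sprintf("region file '%s' does not exist", rf))
  invisible(TRUE)
}

#' Read / write a project file
#'
#' @param path project JSON (`.tmap`) path.
#' @return `readProject()`: the project list, validated against the
#'   files referenced (relative paths resolve against the project
#'   directory).
#' @export
readProject <- function(path) {
  proj <- jsonlite::read_json(path, simplifyVector = FALSE)
  proj$regionFiles <- as.character(unlist(proj$regionFiles))
  validateProject(proj, dir = dirname(path))
  proj
}

#' @param proj a project list from [makeProject()].
#' @rdname readProject
#' @export
writeProject <- function(proj, path) {
  jsonlite::write_json(proj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

resample_nearest <- function(img, outW, outH) {
  h <- dim(img)[1L]; w <- dim(img)[2L]
  xi <- pmin(w, pmax(1L, floor((seq_len(outW) - 0.5) * w / outW) + 1L))
  yi <- pmin(h, pmax(1L, floor((seq_len(outH) - 0.5) * h / outH) + 1L))
  if (length(dim(img)) == 3L) img[yi, xi, , drop = FALSE]
  else img[yi, xi, drop = FALSE]
}

#' Capture a viewport as an RGB image
#'
#' Crops the composited layers to the viewport, resamples to the output
#' size (nearest neighbor) and optionally rasterises markers as filled
#' discs of their style size/color -- a simple software rasteriser, not
#' the GPU renderer.
#'
#' @param layers list of single-channel level-0 images.
#' @param params list of [displayParams()], one per layer.
#' @param viewport `c(x, y, width, height)` in level-0 pixels; must be
#'   non-empty and within bounds.
#' @param outputSize `c(width, height)` of the result (default: the
#'   viewport size).
#' @param markers optional [MarkerTable-class] with x/y roles to draw.
#' @param markerStyle list: `color` (R color), `size` (disc diameter,
#'   px).
#' @return an outputHeight x outputWidth x 3 RGB array.
#' @export
captureViewport <- function(layers, params, viewport, outputSize = NULL,
                            markers = NULL,
                            markerStyle = list(color = "red", size = 3)) {
  h <- dim(layers[[1L]])[1L]; w <- dim(layers[[1L]])[2L]
  vx <- viewport[1L]; vy <- viewport[2L]
  vw <- viewport[3L]; vh <- viewport[4L]
  if (vw <= 0 || vh <= 0) stop("empty viewport")
  if (vx < 0 || vy < 0 || vx + vw > w || vy + vh > h)
    stop("viewport outside level-0 bounds")
  crops <- lapply(layers, function(l)
    l[(vy + 1L):(vy + vh), (vx + 1L):(vx + vw), drop = FALSE])
  rgb <- compositeLayers(crops, params)
  if (is.null(outputSize)) outputSize <- c(vw, vh)
  rgb <- resample_nearest(rgb, outputSize[1L], outputSize[2L])
  if (!is.null(markers)) {
    xy <- marker_xy(markers)
    col <- as.numeric(col2rgb(markerStyle$color)) / 255
    sx <- outputSize[1L] / vw; sy <- outputSize[2L] / vh
    rad <- markerStyle$size / 2
    for (i in seq_len(nrow(xy))) {
      mx <- (xy[i, 1L] - vx) * sx; my <- (xy[i, 2L] - vy) * sy
      if (mx < 0 || my < 0 || mx >= outputSize[1L] || my >= outputSize[2L])
        next
      x0 <- max(1L, floor(mx - rad) + 1L); x1 <- min(outputSize[1L],
                                                     ceiling(mx + rad) + 1L)
      y0 <- max(1L, floor(my - rad) + 1L); y1 <- min(outputSize[2L],
                                                     ceiling(my + rad) + 1L)
      for (yy in y0:y1) for (xx in x0:x1)
        if ((xx - 1 - mx)^2 + (yy - 1 - my)^2 <= rad^2)
          rgb[yy, xx, ] <- col
    }
  }
  rgb
}
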