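#' @include AllClasses.R
NULL

ring_from_coords <- function(coords) {
  ring <- matrix(unlist(lapply(coords, function(pt)
    c(as.numeric(pt[[1L]]), as.numeric(pt[[2L]])))), ncol = 2L, byrow = TRUE)
  if (nrow(ring) < 4L || any(ring[1L, ] != ring[nrow(ring), ]))
    stop("GeoJSON rings must be closed (first point = last point)")
  ring
}

#' Read a GeoJSON FeatureCollection of regions
#'
#' Accepts Polygon and MultiPolygon features (with holes) in level-0
#' pixel coordinates; properties pass through untouched, so e.g.
#' QuPath-exported GeoJSON loads as-is.  Point/LineString geometries are
#' rejected by name.
#'
#' @param x GeoJSON text, a file path, or an already-parsed list.
#' @return a [RegionSet-class].
#' @export
readGeoJSON <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x))
    x <- paste(readLines(x, warn = FALSE), collapse = "\n")
  obj <- if (is.character(x))
    jsonlite::fromJSON(x, simplifyVector = FALSE) else x
  if (!identical(obj$type, "FeatureCollection"))
    stop("expected a GeoJSON FeatureCollection")
  feats <- lapply(obj$features, function(f) {
    g <- f$geometry
    polys <- switch(g$type,
      Polygon = list(lapply(g$coordinates, ring_from_coords)),
      MultiPolygon = lapply(g$coordinates, function(poly)
        lapply(poly, ring_from_coords)),
      stop(sprintf("unsupported geometry type '%s'", g$type)))
    props <- f$properties
    if (is.null(props)) props <- list()
    list(geometry = polys, properties = props,
         multi = identical(g$type, "MultiPolygon"))
  })
  RegionSet(feats)
}

#' Write a RegionSet as canonical GeoJSON
#'
#' @param regions a [RegionSet-class].
#' @param path optional file path; when NULL the GeoJSON text is
#'   returned.
#' @return the GeoJSON string (invisibly when written to `path`).
#' @export
writeGeoJSON <- function(regions, path = NULL) {
  feats <- lapply(regions@features, function(f) {
    ring_list <- function(ring)
      lapply(seq_len(nrow(ring)), function(i) as.list(ring[i, ]))
    multi <- isTRUE(f$multi) || length(f$geometry) > 1L
    coords <- if (multi)
      lapply(f$geometry, function(poly) lapply(poly, ring_list))
    else lapply(f$geometry[[1L]], ring_list)
    props <- f$properties
    if (!length(props)) props <- structure(list(), names = character())
    list(type = "Feature",
         geometry = list(type = if (multi) "MultiPolygon" else "Polygon",
                         coordinates = coords),
         properties = props)
  })
  txt <- jsonlite::toJSON(list(type = "FeatureCollection", features = feats),
                          auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(as.character(txt)))
  }
  as.character(txt)
}

## normalize a geometry argument to a list of polygons (each a list of
## closed rings): accepts a ring matrix, a polygon, a multipolygon or a
## whole feature geometry
as_polygons <- function(geometry) {
  if (is.matrix(geometry)) return(list(list(geometry)))
  if (is.list(geometry) && length(geometry) && is.matrix(geometry[[1L]]))
    return(list(geometry))
  geometry
}

#' Even-odd point-in-region test
#'
#' Ray-casting with the even-odd fill rule: a point inside a hole is
#' outside; points within `tol` of any edge count as inside.
#'
#' @param geometry a closed ring matrix, a polygon (list of rings:
#'   outer first, then holes) or a multipolygon (list of polygons).
#' @param points n x 2 coordinate matrix.
#' @param tol on-edge tolerance in pixels (default 1e-9).
#' @return logical mask of length n.
#' @export
pointInRegion <- function(geometry, points, tol = 1e-9) {
  points <- matrix(as.numeric(points), ncol = 2L)
  px <- points[, 1L]; py <- points[, 2L]
  n <- length(px)
  inside <- logical(n)
  onEdge <- logical(n)
  for (poly in as_polygons(geometry)) for (ring in poly) {
    nv <- nrow(ring) - 1L   # closed: last vertex repeats the first
    for (e in seq_len(nv)) {
      x1 <- ring[e, 1L]; y1 <- ring[e, 2L]
      x2 <- ring[e + 1L, 1L]; y2 <- ring[e + 1L, 2L]
      crosses <- ((y1 > py) != (y2 > py))
      if (any(crosses)) {
        xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
        flip <- crosses & (px < xint)
        inside[flip] <- !inside[flip]
      }
      ## distance from point to segment <= tol -> on edge
      dx <- x2 - x1; dy <- y2 - y1
      L2 <- dx * dx + dy * dy
      t <- if (L2 > 0) pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / L2))
           else 0
      qx <- x1 + t * dx; qy <- y1 + t * dy
      onEdge <- onEdge | ((px - qx)^2 + (py - qy)^2 <= tol^2)
    }
  }
  inside | onEdge
}

#' Shoelace area of a region geometry
#'
#' Absolute shoelace area of the outer ring(s) minus the hole rings;
#' invariant to ring orientation and vertex rotation.
#'
#' @inheritParams pointInRegion
#' @return area in square pixels (>= 0).
#' @export
regionArea <- function(geometry) {
  shoelace <- function(ring) {
    if (any(ring[1L, ] != ring[nrow(ring), ])) stop("open ring")
    x <- ring[-nrow(ring), 1L]; y <- ring[-nrow(ring), 2L]
    xs <- c(x[-1L], x[1L]); ys <- c(y[-1L], y[1L])
    abs(sum(x * ys - xs * y)) / 2
  }
  tot <- 0
  for (poly in as_polygons(geometry)) {
    tot <- tot + shoelace(poly[[1L]])
    for (ring in poly[-1L]) tot <- tot - shoelace(ring)
  }
  max(tot, 0)
}

geometry_bbox <- function(geometry) {
  pts <- do.call(rbind, unlist(as_polygons(geometry), recursive = FALSE))
  c(min(pts[, 1L]), min(pts[, 2L]), max(pts[, 1L]), max(pts[, 2L]))
}

#' Uniform-grid spatial index over a RegionSet
#'
#' Cells cover the joint bounding box; every feature whose bounding box
#' overlaps a cell is listed as a candidate for that cell.  The default
#' cell size is the bounding-box diagonal divided by 64.
#'
#' @param regions a [RegionSet-class].
#' @param cellSize cell side in pixels (default diagonal / 64).
#' @return a spatial-index list used by [assignRegions()].
#' @export
buildSpatialIndex <- function(regions, cellSize = NULL) {
  nf <- length(regions@features)
  boxes <- lapply(regions@features, function(f) geometry_bbox(f$geometry))
  bb <- c(min(vapply(boxes, `[`, 0, 1L)), min(vapply(boxes, `[`, 0, 2L)),
          max(vapply(boxes, `[`, 0, 3L)), max(vapply(boxes, `[`, 0, 4L)))
  if (is.null(cellSize)) {
    diag <- sqrt((bb[3L] - bb[1L])^2 + (bb[4L] - bb[2L])^2)
    cellSize <- max(diag / 64, .Machine$double.eps)
  }
  nx <- max(1L, ceiling((bb[3L] - bb[1L]) / cellSize))
  ny <- max(1L, ceiling((bb[4L] - bb[2L]) / cellSize))
  cells <- vector("list", nx * ny)
  for (fi in seq_len(nf)) {
    b <- boxes[[fi]]
    cx0 <- max(0L, floor((b[1L] - bb[1L]) / cellSize))
    cx1 <- min(nx - 1L, floor((b[3L] - bb[1L]) / cellSize))
    cy0 <- max(0L, floor((b[2L] - bb[2L]) / cellSize))
    cy1 <- min(ny - 1L, floor((b[4L] - bb[2L]) / cellSize))
    for (cy in cy0:cy1) for (cx in cx0:cx1) {
      k <- cy * nx + cx + 1L
      cells[[k]] <- c(cells[[k]], fi)
    }
  }
  list(bbox = bb, cellSize = cellSize, nx = nx, ny = ny, cells = cells)
}

#' Assign points to regions (first feature in document order wins)
#'
#' Grid-accelerated point-to-region assignment with results identical
#' to testing every feature: per point, candidate features from the
#' point's grid cell are tried in document order, and the first
#' containing feature is reported.
#'
#' @param regions a [RegionSet-class].
#' @param points n x 2 coordinate matrix.
#' @param index optional pre-built [buildSpatialIndex()] result.
#' @param tol on-edge tolerance passed to [pointInRegion()].
#' @return integer vector of 1-based feature ids, `NA` where a point is
#'   in no region.
#' @export
assignRegions <- function(regions, points, index = NULL, tol = 1e-9) {
  points <- matrix(as.numeric(points), ncol = 2L)
  n <- nrow(points)
  out <- rep(NA_integer_, n)
  if (!length(regions@features) || !n) return(out)
  if (is.null(index)) index <- buildSpatialIndex(regions)
  bb <- index$bbox
  cx <- floor((points[, 1L] - bb[1L]) / index$cellSize)
  cy <- floor((points[, 2L] - bb[2L]) / index$cellSize)
  okCell <- cx >= 0 & cx < index$nx & cy >= 0 & cy < index$ny
  cellOf <- ifelse(okCell, cy * index$nx + cx + 1L, NA_integer_)
  ## evaluate candidates feature-major so each geometry is tested once
  ## per point set, preserving document-order priority
  byCell <- split(seq_len(n)[okCell], cellOf[okCell])
  for (cellKey in names(byCell)) {
    pts <- byCell[[cellKey]]
    for (fi in index$cells[[as.integer(cellKey)]]) {
      todo <- pts[is.na(out[pts]) | out[pts] > fi]
      if (!length(todo)) next
      hit <- pointInRegion(regions@features[[fi]]$geometry,
                           points[todo, , drop = FALSE], tol = tol)
      out[todo[hit]] <- pmin(out[todo[hit]], fi, na.rm = TRUE)
    }
  }
  out
}
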