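#' @include AllGenerics.R
NULL

#' Geometry of a Deep Zoom image pyramid
#'
#' A `PyramidSpec` fixes the level-0 (full resolution) size of an image
#' together with the tiling parameters of its Deep Zoom pyramid.  In the
#' Deep Zoom convention the deepest level `maxLevel` holds the image at
#' full resolution and each shallower level halves both dimensions
#' (ceiling division) until level 0 is a single pixel.
#'
#' @slot width,height level-0 image size in pixels (integers >= 1).
#' @slot tileSize tile side in pixels, excluding overlap (default 254).
#' @slot overlap extra pixels added on every interior tile edge
#'   (default 1); must satisfy `0 <= overlap < tileSize`.
#' @slot format tile encoding, `"png"` (lossless, used in all tests) or
#'   `"jpeg"`.
#'
#' @seealso [maxLevel()], [levelDimensions()], [tileGrid()], [getTile()],
#'   [buildPyramid()]
#' @export
setClass("PyramidSpec",
  representation(width = "integer", height = "integer",
                 tileSize = "integer", overlap = "integer",
                 format = "character"))

setValidity("PyramidSpec", function(object) {
  msg <- character()
  if (length(object@width) != 1L || is.na(object@width) || object@width < 1L)
    msg <- c(msg, "width must be a single integer >= 1")
  if (length(object@height) != 1L || is.na(object@height) || object@height < 1L)
    msg <- c(msg, "height must be a single integer >= 1")
  if (length(object@tileSize) != 1L || object@tileSize < 1L)
    msg <- c(msg, "tileSize must be >= 1")
  if (length(object@overlap) != 1L || object@overlap < 0L ||
      object@overlap >= object@tileSize)
    msg <- c(msg, "overlap must satisfy 0 <= overlap < tileSize")
  if (!(object@format %in% c("png", "jpeg")))
    msg <- c(msg, "format must be \"png\" or \"jpeg\"")
  if (length(msg)) msg else TRUE
})

#' @param width,height level-0 image size in pixels.
#' @param tileSize,overlap,format see slots.
#' @return `PyramidSpec()` returns a validated PyramidSpec object.
#' @rdname PyramidSpec-class
#' @export
PyramidSpec <- function(width, height, tileSize = 254L, overlap = 1L,
                        format = "png") {
  if (length(width) != 1L || length(height) != 1L ||
      !is.finite(width) || !is.finite(height) || width < 1 || height < 1)
    stop("image dimensions must be positive")
  new("PyramidSpec", width = as.integer(width), height = as.integer(height),
      tileSize = as.integer(tileSize), overlap = as.integer(overlap),
      format = as.character(format))
}

setMethod("show", "PyramidSpec", function(object) {
  cat(sprintf("PyramidSpec: %d x %d px, tileSize %d, overlap %d, format %s\n",
              object@width, object@height, object@tileSize, object@overlap,
              object@format))
  cat(sprintf("  levels: %d (0..%d)\n", maxLevel(object) + 1L,
              maxLevel(object)))
})


#' Columnar marker table (struct-of-arrays)
#'
#' A `MarkerTable` stores N marker rows column-wise: one contiguous array
#' per attribute.  Numeric columns are 64-bit doubles (missing values are
#' `NaN`); all other columns are categorical character vectors (missing
#' values are `""`).  Column roles declare which columns carry the x/y
#' pixel coordinates and optional grouping / styling attributes.
#'
#' @slot columns named list of equal-length double or character vectors.
#' @slot nRows number of marker rows.
#' @slot roles named list with optional entries `x`, `y`, `group`,
#'   `color`, `size`, `opacity`, `shape` (column names) and `pieSectors`
#'   (ordered character vector of numeric column names).
#' @slot provenance free-form list recording source path and load options.
#'
#' @seealso [streamLoadCsv()], [loadH5Columns()], [packMarkers()]
#' @export
setClass("MarkerTable",
  representation(columns = "list", nRows = "integer", roles = "list",
                 provenance = "list"))

setValidity("MarkerTable", function(object) {
  msg <- character()
  nm <- names(object@columns)
  if (length(object@columns) && (is.null(nm) || any(nm == "") ||
                                 anyDuplicated(nm)))
    msg <- c(msg, "columns must have unique non-empty names")
  lens <- vapply(object@columns, length, 0L)
  if (length(lens) && any(lens != object@nRows))
    msg <- c(msg, "all columns must have exactly nRows entries")
  ok <- vapply(object@columns, function(c) is.double(c) || is.character(c),
               NA)
  if (length(ok) && !all(ok))
    msg <- c(msg, "columns must be double (numeric) or character (categorical)")
  for (r in c("x", "y")) {
    cn <- object@roles[[r]]
    if (!is.null(cn)) {
      if (!cn %in% nm) msg <- c(msg, sprintf("role '%s' names a missing column", r))
      else if (!is.double(object@columns[[cn]]))
        msg <- c(msg, sprintf("role '%s' must resolve to a numeric column", r))
    }
  }
  for (r in c("group", "color", "size", "opacity", "shape")) {
    cn <- object@roles[[r]]
    if (!is.null(cn) && !cn %in% nm)
      msg <- c(msg, sprintf("role '%s' names a missing column", r))
  }
  ps <- object@roles[["pieSectors"]]
  if (!is.null(ps)) {
    if (!all(ps %in% nm)) msg <- c(msg, "pieSectors name missing columns")
    else if (!all(vapply(object@columns[ps], is.double, NA)))
      msg <- c(msg, "pieSectors must be numeric columns")
  }
  if (length(msg)) msg else TRUE
})

#' @param columns named list of vectors (coerced: numeric to double,
#'   everything else to character) or a data.frame.
#' @param roles,provenance see slots.
#' @return `MarkerTable()` returns a validated MarkerTable.
#' @rdname MarkerTable-class
#' @export
MarkerTable <- function(columns = list(), roles = list(),
                        provenance = list()) {
  if (is.data.frame(columns)) columns <- as.list(columns)
  columns <- lapply(columns, function(v) {
    if (is.numeric(v)) as.double(v)
    else if (is.factor(v)) as.character(v)
    else if (is.character(v)) v
    else as.character(v)
  })
  n <- if (length(columns)) length(columns[[1L]]) else 0L
  new("MarkerTable", columns = columns, nRows = as.integer(n),
      roles = roles, provenance = provenance)
}

setMethod("show", "MarkerTable", function(object) {
  num <- vapply(object@columns, is.double, NA)
  cat(sprintf("MarkerTable: %d rows, %d columns (%d numeric, %d categorical)\n",
              object@nRows, length(object@columns), sum(num), sum(!num)))
  if (length(object@columns))
    cat("  columns:", paste(names(object@columns), collapse = ", "), "\n")
  if (length(object@roles)) {
    rl <- vapply(object@roles, function(v) paste(v, collapse = "+"), "")
    cat("  roles:", paste(sprintf("%s=%s", names(rl), rl), collapse = ", "),
        "\n")
  }
})

setMethod("nRows", "MarkerTable", function(x) x@nRows)
setMethod("columnNames", "MarkerTable", function(x) names(x@columns))
setMethod("markerColumn", "MarkerTable", function(x, name) {
  if (!name %in% names(x@columns))
    stop(sprintf("no column '%s'; available: %s", name,
                 paste(names(x@columns), collapse = ", ")))
  x@columns[[name]]
})
setMethod("columnRoles", "MarkerTable", function(x) x@roles)
setMethod("columnRoles<-", "MarkerTable", function(x, value) {
  x@roles <- value
  validObject(x)
  x
})

#' Coerce a MarkerTable to data.frame
#'
#' @param x a MarkerTable.
#' @param row.names,optional,... passed through for S3 compatibility.
#' @export
as.data.frame.MarkerTable <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  as.data.frame(x@columns, optional = TRUE, stringsAsFactors = FALSE,
                check.names = FALSE)
}


#' Packed render buffer (32 bytes per drawn marker)
#'
#' Emulates the viewer's GPU vertex buffer: one fixed 32-byte binary
#' record per drawn marker, appended in chunks of at most `chunkSize`
#' records.  See [vertexLayout()] for the field map.
#'
#' @slot bytes raw vector, `32 * nRecords` bytes.
#' @slot nRecords number of packed records.
#' @slot layout data.frame describing the record byte map
#'   (field/offset/type/size).
#' @slot uploadLog data.frame with one row per upload chunk
#'   (`offset` = record offset of the chunk start, `recordCount`).
#' @slot nSkipped rows dropped for non-finite coordinates.
#' @export
setClass("PackedBuffer",
  representation(bytes = "raw", nRecords = "integer", layout = "data.frame",
                 uploadLog = "data.frame", nSkipped = "integer"))

setValidity("PackedBuffer", function(object) {
  msg <- character()
  if (length(object@bytes) != 32L * object@nRecords)
    msg <- c(msg, "buffer length must equal 32 * nRecords")
  if (nrow(object@uploadLog)) {
    if (sum(object@uploadLog$recordCount) != object@nRecords)
      msg <- c(msg, "upload chunks must cover all records")
    starts <- cumsum(c(0L, object@uploadLog$recordCount))
    if (!all(object@uploadLog$offset == starts[-length(starts)]))
      msg <- c(msg, "upload chunks must be contiguous and ordered")
  } else if (object@nRecords > 0L) {
    msg <- c(msg, "non-empty buffer needs at least one logged chunk")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "PackedBuffer", function(object) {
  cat(sprintf("PackedBuffer: %d records, %d bytes, %d chunk(s), %d skipped\n",
              object@nRecords, length(object@bytes), nrow(object@uploadLog),
              object@nSkipped))
})

setMethod("nRecords", "PackedBuffer", function(x) x@nRecords)
setMethod("packedBytes", "PackedBuffer", function(x) x@bytes)
setMethod("uploadLog", "PackedBuffer", function(x) x@uploadLog)


#' GeoJSON-backed region set
#'
#' An ordered collection of polygonal regions in level-0 pixel
#' coordinates.  Each feature holds a geometry (Polygon or MultiPolygon,
#' with optional holes) and a free-form property map.  Geometries are
#' stored as lists of polygons; each polygon is a list of closed rings
#' (n x 2 coordinate matrices whose first and last vertex coincide); the
#' first ring is the outer boundary, subsequent rings are holes.
#'
#' @slot features list of `list(geometry = list(<polygon>, ...),
#'   properties = list(...))`.
#'
#' @seealso [readGeoJSON()], [writeGeoJSON()], [assignRegions()]
#' @export
setClass("RegionSet", representation(features = "list"))

setValidity("RegionSet", function(object) {
  for (i in seq_along(object@features)) {
    f <- object@features[[i]]
    if (!is.list(f) || !all(c("geometry", "properties") %in% names(f)))
      return(sprintf("feature %d lacks geometry/properties", i))
    for (poly in f$geometry) for (ring in poly) {
      if (!is.matrix(ring) || ncol(ring) != 2L || nrow(ring) < 4L)
        return(sprintf("feature %d: rings must be n x 2 matrices, n >= 4", i))
      if (!isTRUE(all.equal(ring[1L, ], ring[nrow(ring), ])))
        return(sprintf("feature %d has an open ring", i))
    }
  }
  TRUE
})

#' @param features see slot.
#' @return `RegionSet()` returns a validated RegionSet.
#' @rdname RegionSet-class
#' @export
RegionSet <- function(features = list()) new("RegionSet", features = features)

setMethod("show", "RegionSet", function(object) {
  np <- sum(vapply(object@features, function(f) length(f$geometry), 0L))
  cat(sprintf("RegionSet: %d feature(s), %d polygon(s)\n",
              length(object@features), np))
})

setMethod("nFeatures", "RegionSet", function(x) length(x@features))
setMethod("featureProperties", "RegionSet", function(x, i)
  x@features[[i]]$properties)
setMethod("featureGeometry", "RegionSet", function(x, i)
  x@features[[i]]$geometry)


#' Spatial neighbor graph over marker positions
#'
#' Undirected graph on n marker nodes, stored as a 2-column matrix of
#' 1-based index pairs with `i < j`; no self loops, each pair at most
#' once.
#'
#' @slot nNodes number of nodes.
#' @slot edges integer matrix, 2 columns, `edges[,1] < edges[,2]`.
#' @slot params build parameters (`method`, `k` or `r`).
#' @seealso [buildNeighborGraph()], [neighborhoodEnrichment()]
#' @export
setClass("NeighborGraph",
  representation(nNodes = "integer", edges = "matrix", params = "list"))

setValidity("NeighborGraph", function(object) {
  e <- object@edges
  if (ncol(e) != 2L) return("edges must have 2 columns")
  if (nrow(e)) {
    if (any(e < 1L) || any(e > object@nNodes)) return("edge index out of range")
    if (any(e[, 1L] >= e[, 2L])) return("edges must satisfy i < j (no loops)")
    if (anyDuplicated(e[, 1L] * (object@nNodes + 1) + e[, 2L]))
      return("duplicate edges")
  }
  TRUE
})

setMethod("show", "NeighborGraph", function(object) {
  cat(sprintf("NeighborGraph: %d nodes, %d undirected edges (%s)\n",
              object@nNodes, nrow(object@edges),
              paste(sprintf("%s=%s", names(object@params), object@params),
                    collapse = ", ")))
})

setMethod("graphEdges", "NeighborGraph", function(x) x@edges)


#' Neighborhood enrichment result
#'
#' Symmetric z-score matrix over marker-category pairs from a label
#' permutation test on a spatial neighbor graph.  Entry (a, b) is
#' positive when a- and b-labelled markers are graph-adjacent more often
#' than label-shuffled chance, negative when less often.
#'
#' @slot categories ordered category labels.
#' @slot z,observed,nullMean,nullSd symmetric category x category
#'   matrices; `observed` counts edges joining the two categories
#'   (within-category on the diagonal).
#' @slot degenerate logical matrix, TRUE where the permutation null had
#'   zero standard deviation (z forced to 0).
#' @slot nPerm,seed permutation parameters.
#' @seealso [neighborhoodEnrichment()]
#' @export
setClass("EnrichmentResult",
  representation(categories = "character", z = "matrix", observed = "matrix",
                 nullMean = "matrix", nullSd = "matrix",
                 degenerate = "matrix", nPerm = "integer", seed = "integer"))

setValidity("EnrichmentResult", function(object) {
  k <- length(object@categories)
  for (s in c("z", "observed", "nullMean", "nullSd", "degenerate")) {
    m <- slot(object, s)
    if (!all(dim(m) == k)) return(sprintf("%s must be %d x %d", s, k, k))
  }
  if (!isTRUE(all.equal(object@z, t(object@z)))) return("z must be symmetric")
  TRUE
})

setMethod("show", "EnrichmentResult", function(object) {
  cat(sprintf(
    "EnrichmentResult: %d categories, %d permutations (seed %d)\n",
    length(object@categories), object@nPerm, object@seed))
  print(round(object@z, 2))
})

setMethod("categories", "EnrichmentResult", function(x) x@categories)
setMethod("enrichmentZ", "EnrichmentResult", function(x) x@z)
setMethod("observedCounts", "EnrichmentResult", function(x) x@observed)


#' Marker-to-region clustering result
#'
#' Output of the binned-composition K-means pipeline: every marker that
#' falls into a non-empty spatial bin inherits the cluster label of its
#' bin; markers outside any binned area are `NA`.
#'
#' @slot labels integer per-marker region label in `1..K` (`NA` =
#'   unassigned).
#' @slot binComposition non-empty-bin x category L1-normalised
#'   composition matrix (after smoothing).
#' @slot binInfo data.frame: bin grid coordinates (`binX`, `binY`,
#'   0-based) and `cluster` per non-empty bin.
#' @slot params list: `binSize`, `smoothingRadius` (pixels), `K`, `seed`.
#' @slot polygons RegionSet of contoured cluster outlines, or NULL.
#' @seealso [points2Regions()]
#' @export
setClass("RegionClusteringResult",
  representation(labels = "integer", binComposition = "matrix",
                 binInfo = "data.frame", params = "list",
                 polygons = "ANY"))

setMethod("show", "RegionClusteringResult", function(object) {
  cat(sprintf(
    "RegionClusteringResult: %d markers, K = %d, binSize = %g px (seed %d)\n",
    length(object@labels), object@params$K, object@params$binSize,
    object@params$seed))
  print(table(cluster = object@labels, useNA = "ifany"))
})

setMethod("regionLabels", "RegionClusteringResult", function(x) x@labels)
setMethod("regionPolygons", "RegionClusteringResult", function(x) x@polygons)


#' Two-classifier confusion matrix over matched markers
#'
#' Markers from two tables are matched by coordinates (exactly, or
#' one-to-one nearest neighbor within a tolerance); `counts[a, b]` is the
#' number of matched markers labelled `a` by method A and `b` by method
#' B.  Per-cell row-index lists support drill-down display.
#'
#' @slot rowLabels,colLabels category labels of methods A and B.
#' @slot counts rowLabels x colLabels count matrix.
#' @slot cells list-matrix-like list indexed `[[a]][[b]]`, each entry a
#'   list with matched row indices `a` (in table A) and `b` (in table B).
#' @slot nMatched total matched markers.
#' @seealso [markerConfusion()]
#' @export
setClass("ConfusionResult",
  representation(rowLabels = "character", colLabels = "character",
                 counts = "matrix", cells = "list", nMatched = "integer"))

setValidity("ConfusionResult", function(object) {
  if (sum(object@counts) != object@nMatched)
    return("counts must sum to the number of matched markers")
  TRUE
})

setMethod("show", "ConfusionResult", function(object) {
  cat(sprintf("ConfusionResult: %d matched markers\n", object@nMatched))
  print(object@counts)
})

setMethod("confusionCounts", "ConfusionResult", function(x) x@counts)
setMethod("cellIndices", "ConfusionResult", function(x, a, b)
  x@cells[[a]][[b]])
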