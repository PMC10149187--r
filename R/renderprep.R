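#' @include AllClasses.R
NULL

#' The 32-byte vertex record layout
#'
#' Field map of one packed marker record, 32 bytes exactly, all values
#' little-endian:
#'
#' | field        | offset | type               | bytes |
#' |--------------|-------:|--------------------|------:|
#' | x            |      0 | float32            |     4 |
#' | y            |      4 | float32            |     4 |
#' | markerIndex  |      8 | uint32 (0-based)   |     4 |
#' | color        |     12 | 4 x uint8 RGBA     |     4 |
#' | opacity      |     16 | float32            |     4 |
#' | size         |     20 | float32            |     4 |
#' | groupId      |     24 | uint16             |     2 |
#' | shapeId      |     26 | uint16             |     2 |
#' | sectorStart  |     28 | uint16 fixed-point |     2 |
#' | sectorExtent |     30 | uint16 fixed-point |     2 |
#'
#' Sector fractions are stored as `round(fraction * 65535)`; plain
#' (non-pie) markers carry start 0, extent 1.
#'
#' @return a data.frame with columns field, offset, type, size.
#' @export
vertexLayout <- function() {
  data.frame(
    field = c("x", "y", "markerIndex", "color", "opacity", "size",
              "groupId", "shapeId", "sectorStart", "sectorExtent"),
    offset = c(0L, 4L, 8L, 12L, 16L, 20L, 24L, 26L, 28L, 30L),
    type = c("float32", "float32", "uint32", "rgba8", "float32", "float32",
             "uint16", "uint16", "ufixed16", "ufixed16"),
    size = c(4L, 4L, 4L, 4L, 4L, 4L, 2L, 2L, 2L, 2L),
    stringsAsFactors = FALSE)
}

f32_bytes <- function(x) matrix(writeBin(as.numeric(x), raw(), size = 4L,
                                         endian = "little"), nrow = 4L)
u32_bytes <- function(x) matrix(writeBin(as.integer(x), raw(), size = 4L,
                                         endian = "little"), nrow = 4L)
u16_bytes <- function(x) {
  x <- as.integer(round(x))
  x[x > 65535L] <- 65535L; x[x < 0L] <- 0L
  ## two's-complement low 16 bits == unsigned representation
  x[x > 32767L] <- x[x > 32767L] - 65536L
  matrix(suppressWarnings(writeBin(x, raw(), size = 2L, endian = "little")),
         nrow = 2L)
}

resolve_colors <- function(table, roles, default) {
  n <- table@nRows
  cn <- roles[["color"]]
  if (is.null(cn)) {
    rgb <- col2rgb(default, alpha = TRUE)
    return(matrix(rep(as.integer(rgb), n), nrow = 4L))
  }
  col <- markerColumn(table, cn)
  if (is.double(col)) {
    v <- pmin(1, pmax(0, col))
    v[!is.finite(col)] <- 0
    g <- as.integer(round(v * 255))
    rbind(g, g, g, rep(255L, n))
  } else {
    ok <- tryCatch(col2rgb(col, alpha = TRUE), error = function(e)
      stop(sprintf("invalid color spec in column '%s': %s", cn,
                   conditionMessage(e))))
    matrix(as.integer(ok), nrow = 4L)
  }
}

#' Pack a marker table into a 32-byte-per-marker render buffer
#'
#' Emits one fixed 32-byte record per drawn marker, in row order, with
#' no sub-sampling: every finite-coordinate row is packed.  Records are
#' appended in chunks of at most `chunkSize` records (the viewer's
#' chunked vertex-buffer upload), each chunk logged with its record
#' offset; the buffer content is independent of the chunk size.
#'
#' If the table carries the columns produced by [expandPie()]
#' (`parent_index`, `sector_start`, `sector_extent`), the packed
#' `markerIndex` is the 0-based parent row and the sector fields encode
#' the pie-sector fractions.
#'
#' @param table a [MarkerTable-class] with x/y roles set.
#' @param roles optional override of `columnRoles(table)`.
#' @param defaults style defaults: `color` (any R color spec), `size`,
#'   `opacity`, `shape`, `group` used where no role column is set.
#' @param chunkSize maximum records per upload chunk (default 100000).
#' @return a [PackedBuffer-class].
#' @export
packMarkers <- function(table, roles = columnRoles(table),
                        defaults = list(color = "white", size = 1,
                                        opacity = 1, shape = 0L, group = 0L),
                        chunkSize = 100000L) {
  if (is.null(roles$x) || is.null(roles$y))
    stop("x and y roles must be set")
  chunkSize <- as.integer(chunkSize)
  if (chunkSize < 1L) stop("chunkSize must be >= 1")
  x <- markerColumn(table, roles$x)
  y <- markerColumn(table, roles$y)
  keep <- is.finite(x) & is.finite(y)
  nSkipped <- sum(!keep)
  sub <- selectRows(table, which(keep))
  n <- sub@nRows

  grab_num <- function(role, default) {
    cn <- roles[[role]]
    if (is.null(cn)) rep(default, n)
    else {
      v <- markerColumn(sub, cn)
      if (!is.double(v)) stop(sprintf("role '%s' must be numeric", role))
      v
    }
  }
  grab_id <- function(role, default) {
    cn <- roles[[role]]
    if (is.null(cn)) rep(as.integer(default), n)
    else {
      v <- markerColumn(sub, cn)
      if (is.double(v)) as.integer(v)
      else as.integer(factor(v, levels = unique(v))) - 1L
    }
  }

  size <- grab_num("size", defaults$size)
  if (any(size > 256))
    warning("marker size exceeds the 256 px point-sprite limit")
  opacity <- grab_num("opacity", defaults$opacity)
  groupId <- grab_id("group", defaults$group)
  shapeId <- grab_id("shape", defaults$shape)
  colors <- resolve_colors(sub, roles, defaults$color)

  hasPie <- all(c("parent_index", "sector_start", "sector_extent") %in%
                names(sub@columns))
  idx0 <- if (hasPie) as.integer(markerColumn(sub, "parent_index")) - 1L
          else which(keep) - 1L
  sectorStart <- if (hasPie) markerColumn(sub, "sector_start") * 65535
                 else rep(0, n)
  sectorExtent <- if (hasPie) markerColumn(sub, "sector_extent") * 65535
                  else rep(65535, n)

  xs <- markerColumn(sub, roles$x)
  ys <- markerColumn(sub, roles$y)
  recs <- rbind(f32_bytes(xs), f32_bytes(ys), u32_bytes(idx0),
                matrix(as.raw(colors), nrow = 4L),
                f32_bytes(opacity), f32_bytes(size),
                u16_bytes(groupId), u16_bytes(shapeId),
                u16_bytes(sectorStart), u16_bytes(sectorExtent))
  stopifnot(nrow(recs) == 32L)

  ## chunked append emulation
  nChunks <- if (n) ceiling(n / chunkSize) else 0L
  parts <- vector("list", nChunks)
  log <- data.frame(offset = integer(nChunks), recordCount = integer(nChunks))
  for (ci in seq_len(nChunks)) {
    from <- (ci - 1L) * chunkSize + 1L
    to <- min(n, ci * chunkSize)
    parts[[ci]] <- as.raw(recs[, from:to])
    log$offset[ci] <- from - 1L
    log$recordCount[ci] <- to - from + 1L
  }
  new("PackedBuffer", bytes = unlist(parts, use.names = FALSE) %||% raw(),
      nRecords = as.integer(n), layout = vertexLayout(), uploadLog = log,
      nSkipped = as.integer(nSkipped))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Decode packed vertex records back to values
#'
#' Inverse of the [packMarkers()] encoding: reproduces each record's
#' coordinates (to float32 precision), 0-based marker index and resolved
#' style.
#'
#' @param buffer a [PackedBuffer-class].
#' @return a data.frame with one row per record.
#' @export
decodeRecords <- function(buffer) {
  n <- buffer@nRecords
  if (!n)
    return(data.frame(x = numeric(), y = numeric(), markerIndex = integer()))
  m <- matrix(buffer@bytes, nrow = 32L)
  f32 <- function(rows) readBin(as.raw(m[rows, ]), "double", n = n,
                                size = 4L, endian = "little")
  u16 <- function(rows) readBin(as.raw(m[rows, ]), "integer", n = n,
                                size = 2L, signed = FALSE, endian = "little")
  data.frame(
    x = f32(1:4), y = f32(5:8),
    markerIndex = readBin(as.raw(m[9:12, ]), "integer", n = n, size = 4L,
                          endian = "little"),
    r = as.integer(m[13L, ]), g = as.integer(m[14L, ]),
    b = as.integer(m[15L, ]), a = as.integer(m[16L, ]),
    opacity = f32(17:20), size = f32(21:24),
    groupId = u16(25:26), shapeId = u16(27:28),
    sectorStart = u16(29:30) / 65535, sectorExtent = u16(31:32) / 65535)
}

#' Dump / load a packed buffer with a JSON layout sidecar
#'
#' Writes `{path}` (raw record bytes) and `{path}.json` (the field
#' layout, record count and upload log) so buffer conformance can be
#' checked across implementations.
#'
#' @param buffer a [PackedBuffer-class].
#' @param path output path for the binary blob.
#' @return `dumpBuffer()`: invisibly `path`; `loadBuffer()`: the
#'   [PackedBuffer-class].
#' @export
dumpBuffer <- function(buffer, path) {
  writeBin(buffer@bytes, path)
  side <- list(recordBytes = 32L, nRecords = buffer@nRecords,
               layout = buffer@layout, uploadLog = buffer@uploadLog,
               nSkipped = buffer@nSkipped)
  jsonlite::write_json(side, paste0(path, ".json"), dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname dumpBuffer
#' @export
loadBuffer <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  bytes <- readBin(path, "raw", n = file.size(path))
  ul <- as.data.frame(side$uploadLog)
  ul$offset <- as.integer(ul$offset)
  ul$recordCount <- as.integer(ul$recordCount)
  new("PackedBuffer", bytes = bytes, nRecords = as.integer(side$nRecords),
      layout = as.data.frame(side$layout), uploadLog = ul,
      nSkipped = as.integer(side$nSkipped))
}

#' Duplicate markers into pie-chart sector rows
#'
#' For pie-chart display every marker is duplicated once per sector:
#' n rows with k sector columns become n*k rows.  Each output row
#' carries its 1-based `parent_index`, 1-based `sector_id`, and the
#' sector's `sector_start` (cumulative fraction) and `sector_extent`
#' (value / row sum); extents per parent sum to 1.  Zero-valued sectors
#' keep their row with extent 0, so the n*k count is exact.
#'
#' @param table a [MarkerTable-class].
#' @param sectorCols ordered names of numeric sector-value columns; if
#'   omitted, the `pieSectors` role is used.
#' @return a [MarkerTable-class] with `n * k` rows: all original
#'   columns replicated plus the four sector columns.
#' @export
expandPie <- function(table, sectorCols = columnRoles(table)$pieSectors) {
  if (is.null(sectorCols) || !length(sectorCols))
    stop("no sector columns given")
  vals <- vapply(sectorCols, function(cn) {
    v <- markerColumn(table, cn)
    if (!is.double(v)) stop(sprintf("sector column '%s' is not numeric", cn))
    v
  }, numeric(table@nRows))
  vals <- matrix(vals, nrow = table@nRows)
  if (any(vals < 0, na.rm = TRUE))
    stop(sprintf("negative sector value at row %d",
                 which(apply(vals < 0, 1L, any))[1L]))
  tot <- rowSums(vals)
  if (any(tot == 0) || any(!is.finite(tot)))
    stop(sprintf("all-zero or non-finite sector row(s): %s",
                 paste(which(tot == 0 | !is.finite(tot)), collapse = ", ")))
  n <- table@nRows; k <- length(sectorCols)
  frac <- vals / tot
  starts <- matrix(0, n, k)
  if (k > 1L) for (j in 2:k) starts[, j] <- starts[, j - 1L] + frac[, j - 1L]
  parent <- rep(seq_len(n), each = k)
  cols <- lapply(table@columns, function(col) col[parent])
  cols$parent_index <- as.double(parent)
  cols$sector_id <- as.double(rep(seq_len(k), times = n))
  cols$sector_start <- as.double(t(starts))[seq_len(n * k)]
  cols$sector_extent <- as.double(t(frac))[seq_len(n * k)]
  roles <- table@roles
  roles$pieSectors <- NULL
  new("MarkerTable", columns = cols, nRows = as.integer(n * k),
      roles = roles, provenance = c(table@provenance, list(pie = sectorCols)))
}

#' Triangle geometry for graph edges
#'
#' Each edge is built from two triangles forming the rectangle of the
#' given thickness around the segment (the instanced-rendering layout
#' for anti-aliased edges).  Zero-length edges produce zero-area
#' triangles, not errors.
#'
#' @param points n x 2 coordinate matrix.
#' @param edges m x 2 matrix of 1-based index pairs.
#' @param thickness edge thickness in pixels (> 0).
#' @return a `(6 m) x 2` vertex matrix: 6 consecutive vertices (two
#'   triangles) per edge.
#' @export
buildEdgeGeometry <- function(points, edges, thickness = 1) {
  if (thickness <= 0) stop("thickness must be > 0")
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (!nrow(edges)) return(matrix(numeric(), ncol = 2L))
  if (any(edges < 1L) || any(edges > nrow(points)))
    stop("edge index out of range")
  p1 <- points[edges[, 1L], , drop = FALSE]
  p2 <- points[edges[, 2L], , drop = FALSE]
  d <- p2 - p1
  len <- sqrt(rowSums(d^2))
  perp <- cbind(-d[, 2L], d[, 1L]) / ifelse(len > 0, len, 1)
  off <- perp * (thickness / 2)
  A <- p1 + off; B <- p1 - off; C <- p2 + off; D <- p2 - off
  m <- nrow(edges)
  out <- matrix(0, nrow = 6L * m, ncol = 2L)
  out[seq(1L, 6L * m, 6L), ] <- A
  out[seq(2L, 6L * m, 6L), ] <- B
  out[seq(3L, 6L * m, 6L), ] <- C
  out[seq(4L, 6L * m, 6L), ] <- B
  out[seq(5L, 6L * m, 6L), ] <- D
  out[seq(6L, 6L * m, 6L), ] <- C
  out
}

#' Edge list from per-marker neighbor lists
#'
#' Parses a categorical column of delimited marker indices (the
#' network-diagram input convention: one list of neighbor indices per
#' marker) into a deduplicated, lexicographically sorted undirected
#' edge list.
#'
#' @param table a [MarkerTable-class].
#' @param neighborCol name of the categorical column of delimited lists.
#' @param delimiter list separator inside a cell (default `";"`).
#' @param zeroBased whether indices in the file are 0-based (default),
#'   as the viewer's CSVs are.
#' @return m x 2 integer matrix of 1-based pairs with `i < j`.
#' @export
edgesFromNeighborLists <- function(table, neighborCol, delimiter = ";",
                                   zeroBased = TRUE) {
  lists <- markerColumn(table, neighborCol)
  if (is.double(lists)) lists <- as.character(lists)
  n <- table@nRows
  ai <- integer(); bi <- integer()
  for (i in seq_len(n)) {
    s <- trimws(lists[i])
    if (s == "") next
    parts <- trimws(strsplit(s, delimiter, fixed = TRUE)[[1L]])
    parts <- parts[parts != ""]
    if (!length(parts)) next
    if (!all(grepl("^[0-9]+$", parts)))
      stop(sprintf("malformed neighbor list at row %d: '%s'", i, lists[i]))
    j <- as.integer(parts) + if (zeroBased) 1L else 0L
    if (any(j < 1L | j > n))
      stop(sprintf("neighbor index out of range at row %d", i))
    ai <- c(ai, rep(i, length(j))); bi <- c(bi, j)
  }
  lo <- pmin(ai, bi); hi <- pmax(ai, bi)
  keep <- lo < hi
  e <- unique(cbind(lo[keep], hi[keep]))
  e <- e[order(e[, 1L], e[, 2L]), , drop = FALSE]
  matrix(as.integer(e), ncol = 2L)
}

#' Build a quad-tree over points
#'
#' The legacy sub-sampling structure: nodes hold at most `capacity`
#' points or split into 4 children at the box midpoint (points are
#' routed by `>=` comparisons, so leaves partition the box and every
#' point lands in exactly one leaf).
#'
#' @param points n x 2 coordinate matrix.
#' @param capacity maximum points per leaf.
#' @param bbox bounding box `c(x0, y0, x1, y1)`; computed from the
#'   points if omitted.
#' @return a nested-list tree (`leaf` nodes carry point indices).
#' @export
buildQuadTree <- function(points, capacity = 16L, bbox = NULL) {
  if (is.null(bbox))
    bbox <- c(min(points[, 1L]), min(points[, 2L]),
              max(points[, 1L]), max(points[, 2L]))
  build <- function(idx, box, depth) {
    if (length(idx) <= capacity || depth > 32L)
      return(list(leaf = TRUE, bbox = box, idx = idx))
    mx <- (box[1L] + box[3L]) / 2; my <- (box[2L] + box[4L]) / 2
    right <- points[idx, 1L] >= mx; down <- points[idx, 2L] >= my
    quads <- list(idx[!right & !down], idx[right & !down],
                  idx[!right & down], idx[right & down])
    boxes <- list(c(box[1L], box[2L], mx, my), c(mx, box[2L], box[3L], my),
                  c(box[1L], my, mx, box[4L]), c(mx, my, box[3L], box[4L]))
    list(leaf = FALSE, bbox = box,
         children = lapply(1:4, function(q)
           build(quads[[q]], boxes[[q]], depth + 1L)))
  }
  build(seq_len(nrow(points)), as.numeric(bbox), 0L)
}

boxes_intersect <- function(a, b)
  a[1L] <= b[3L] && b[1L] <= a[3L] && a[2L] <= b[4L] && b[2L] <= a[4L]

#' Seeded quad-tree sub-sampling within a viewport
#'
#' Descends the tree breadth-first, collects the leaves intersecting
#' the viewport, and draws points seeded-uniformly within leaves
#' (round-robin across leaves) until `maxPoints` are taken.  With a
#' quota at least the number of viewport points, all of them are
#' returned.
#'
#' @param tree a [buildQuadTree()] result.
#' @param points the coordinate matrix the tree was built on.
#' @param viewport box `c(x0, y0, x1, y1)`.
#' @param maxPoints sample quota (>= 0).
#' @param seed integer seed; sampling uses no global randomness.
#' @return sorted integer vector of selected 1-based point indices.
#' @export
quadtreeSample <- function(tree, points, viewport, maxPoints, seed = 1L) {
  if (maxPoints < 0L) stop("maxPoints must be >= 0")
  if (maxPoints == 0L) return(integer())
  ## breadth-first leaf collection
  queue <- list(tree); leaves <- list()
  while (length(queue)) {
    node <- queue[[1L]]; queue <- queue[-1L]
    if (!boxes_intersect(node$bbox, viewport)) next
    if (node$leaf) leaves[[length(leaves) + 1L]] <- node
    else queue <- c(queue, node$children)
  }
  inView <- lapply(leaves, function(nd) {
    idx <- nd$idx
    if (!length(idx)) return(integer())
    p <- points[idx, , drop = FALSE]
    idx[p[, 1L] >= viewport[1L] & p[, 1L] <= viewport[3L] &
        p[, 2L] >= viewport[2L] & p[, 2L] <= viewport[4L]]
  })
  total <- sum(lengths(inView))
  if (total <= maxPoints) return(sort(unlist(inView, use.names = FALSE)))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  shuffled <- lapply(inView, function(v) if (length(v) > 1L) sample(v) else v)
  picked <- integer(maxPoints)
  k <- 0L; pos <- 1L
  while (k < maxPoints) {
    for (li in seq_along(shuffled)) {
      v <- shuffled[[li]]
      if (pos <= length(v)) {
        k <- k + 1L
        picked[k] <- v[pos]
        if (k == maxPoints) break
      }
    }
    pos <- pos + 1L
  }
  sort(picked)
}
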