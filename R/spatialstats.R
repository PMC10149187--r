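#' @include AllClasses.R
NULL

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

marker_xy <- function(table) {
  roles <- table@roles
  if (is.null(roles$x) || is.null(roles$y))
    stop("x and y roles must be set on the marker table")
  cbind(markerColumn(table, roles$x), markerColumn(table, roles$y))
}

#' Category histogram of markers inside a region
#'
#' Counts the markers whose coordinates fall inside the given region
#' geometry, keyed by a categorical column (e.g. gene); zero-count
#' categories are omitted.
#'
#' @param table a [MarkerTable-class] with x/y roles set.
#' @param geometry region geometry accepted by [pointInRegion()], or a
#'   [RegionSet-class] feature geometry.
#' @param categoryCol name of the categorical column to count by.
#' @return named integer vector (category -> count), sorted by category.
#' @export
regionHistogram <- function(table, geometry, categoryCol) {
  cats <- markerColumn(table, categoryCol)
  if (is.double(cats)) stop("categoryCol must be categorical")
  inside <- pointInRegion(geometry, marker_xy(table))
  tab <- table(cats[inside])
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts[counts > 0L]
}

#' Write a region histogram as CSV
#'
#' @param counts named counts from [regionHistogram()].
#' @param path output path.
#' @export
writeHistogramCsv <- function(counts, path) {
  utils::write.csv(data.frame(category = names(counts),
                              count = as.integer(counts)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build a spatial neighbor graph
#'
#' `"knn"`: each point is connected to its `k` nearest neighbors
#' (Euclidean), symmetrized by union; equal distances are broken by
#' lower point index.  `"radius"`: all pairs with distance <= `r`.
#'
#' @param points n x 2 coordinate matrix (n >= 2).
#' @param method `"knn"` or `"radius"`.
#' @param param `k` (integer < n) or radius `r` in pixels (> 0).
#' @return a [NeighborGraph-class].
#' @export
buildNeighborGraph <- function(points, method = c("knn", "radius"), param) {
  method <- match.arg(method)
  points <- matrix(as.numeric(points), ncol = 2L)
  n <- nrow(points)
  if (n < 2L) stop("need at least 2 points")
  D <- as.matrix(dist(points))
  if (method == "knn") {
    k <- as.integer(param)
    if (k >= n) stop(sprintf("k = %d must be < n = %d", k, n))
    if (k < 1L) stop("k must be >= 1")
    ai <- integer(); bi <- integer()
    for (i in seq_len(n)) {
      ord <- order(D[i, -i], seq_len(n)[-i])  # ties: lower index wins
      nb <- (seq_len(n)[-i])[ord[seq_len(k)]]
      ai <- c(ai, rep(i, k)); bi <- c(bi, nb)
    }
    lo <- pmin(ai, bi); hi <- pmax(ai, bi)
    e <- unique(cbind(lo, hi))
    params <- list(method = "knn", k = k)
  } else {
    r <- as.numeric(param)
    if (r <= 0) stop("radius must be > 0")
    w <- which(upper.tri(D) & D <= r, arr.ind = TRUE)
    e <- cbind(w[, 1L], w[, 2L])
    params <- list(method = "radius", r = r)
  }
  e <- e[order(e[, 1L], e[, 2L]), , drop = FALSE]
  dimnames(e) <- NULL
  new("NeighborGraph", nNodes = n,
      edges = matrix(as.integer(e), ncol = 2L), params = params)
}

pair_counts <- function(codes, ei, ej, K) {
  la <- codes[ei]; lb <- codes[ej]
  key <- (pmin(la, lb) - 1L) * K + pmax(la, lb)
  tabulate(key, K * K)
}

key_to_matrix <- function(v, K, categories) {
  M <- matrix(0, K, K, dimnames = list(categories, categories))
  M[upper.tri(M, diag = TRUE)] <- 0
  for (a in seq_len(K)) for (b in a:K) {
    M[a, b] <- v[(a - 1L) * K + b]
    M[b, a] <- M[a, b]
  }
  M
}

#' Neighborhood enrichment permutation test
#'
#' For every pair of marker categories (a, b), the observed statistic is
#' the number of graph edges joining an a-node and a b-node (edges
#' within the category on the diagonal).  The null distribution is the
#' same count under `nPerms` uniform random permutations of the label
#' vector; the z-score is `(observed - mean_null) / sd_null` with the
#' population standard deviation over permutations.  Pairs whose null
#' has zero spread get z = 0 and are flagged degenerate.  Positive z
#' means the two categories are spatially closer than label-shuffled
#' chance; negative z, further apart.
#'
#' @param graph a [NeighborGraph-class].
#' @param labels category label per node (character or factor).
#' @param nPerms number of permutations (>= 1, default 1000).
#' @param seed integer seed (mandatory; no global randomness is used).
#' @return an [EnrichmentResult-class].
#' @export
neighborhoodEnrichment <- function(graph, labels, nPerms = 1000L, seed) {
  if (missing(seed)) stop("seed is required")
  n <- graph@nNodes
  labels <- as.character(labels)
  if (length(labels) != n) stop("labels length must equal nNodes")
  categories <- sort(unique(labels))
  K <- length(categories)
  if (K < 2L) stop("single category: nothing to compare")
  if (nPerms < 1L) stop("nPerms must be >= 1")
  codes <- match(labels, categories)
  ei <- graph@edges[, 1L]; ej <- graph@edges[, 2L]
  obs <- pair_counts(codes, ei, ej, K)
  s1 <- numeric(K * K); s2 <- numeric(K * K)
  with_seed(seed, {
    for (p in seq_len(nPerms)) {
      pc <- codes[sample.int(n)]
      cnt <- pair_counts(pc, ei, ej, K)
      s1 <- s1 + cnt
      s2 <- s2 + cnt * cnt
    }
  })
  mu <- s1 / nPerms
  va <- pmax(0, s2 / nPerms - mu * mu)
  sdv <- sqrt(va)
  z <- ifelse(sdv > 0, (obs - mu) / sdv, 0)
  deg <- sdv == 0
  new("EnrichmentResult", categories = categories,
      z = key_to_matrix(z, K, categories),
      observed = key_to_matrix(obs, K, categories),
      nullMean = key_to_matrix(mu, K, categories),
      nullSd = key_to_matrix(sdv, K, categories),
      degenerate = key_to_matrix(deg, K, categories) > 0,
      nPerm = as.integer(nPerms), seed = as.integer(seed))
}

#' Export an enrichment z-matrix as CSV
#'
#' Categories appear as both header row and first column, the layout
#' consumed by the interactive matrix display.
#'
#' @param result an [EnrichmentResult-class].
#' @param path output path.
#' @export
writeEnrichmentCsv <- function(result, path) {
  m <- result@z
  utils::write.csv(data.frame(category = rownames(m), m,
                              check.names = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

gaussian_smooth_grid <- function(g, sigma) {
  if (sigma <= 0) return(g)
  hw <- max(1L, ceiling(3 * sigma))
  kern <- exp(-((-hw:hw)^2) / (2 * sigma^2))
  kern <- kern / sum(kern)
  conv1 <- function(m) {   # along rows (first dim), zero-padded
    out <- matrix(0, nrow(m), ncol(m))
    for (d in -hw:hw) {
      lo <- max(1L, 1L - d); hi <- min(nrow(m), nrow(m) - d)
      if (lo > hi) next
      src <- lo:hi
      out[src + d, ] <- out[src + d, ] + kern[d + hw + 1L] * m[src, ]
    }
    out
  }
  t(conv1(t(conv1(g))))
}

#' Cluster markers into molecular regions (binned composition K-means)
#'
#' The pipeline: (1) markers are assigned to square spatial bins of
#' side `binSize`; (2) each bin gets a category-count vector; (3)
#' counts are smoothed across bins with a Gaussian kernel of the given
#' radius (radius 0 = no smoothing); (4) bin vectors are L1-normalised
#' to compositions; (5) seeded K-means (10 restarts, best inertia)
#' clusters the non-empty bins into K molecular regions; (6) every
#' marker inherits its bin's cluster; (7) optionally, connected
#' same-label bin components are contoured into polygons.
#'
#' @param table a [MarkerTable-class] with x/y roles set.
#' @param binSize bin side in pixels (> 0).
#' @param smoothingRadius Gaussian sigma in pixels (default `binSize`).
#' @param K number of clusters (>= 1, at most the non-empty bin count).
#' @param seed integer seed for K-means.
#' @param categoryCol categorical column defining the composition
#'   space (defaults to the `group` role).
#' @param contour also trace cluster outlines into a
#'   [RegionSet-class] (default FALSE).
#' @return a [RegionClusteringResult-class].
#' @export
points2Regions <- function(table, binSize, smoothingRadius = binSize, K,
                           seed, categoryCol = columnRoles(table)$group,
                           contour = FALSE) {
  if (missing(seed)) stop("seed is required")
  if (binSize <= 0) stop("binSize must be > 0")
  if (K < 1L) stop("K must be >= 1")
  if (is.null(categoryCol)) stop("categoryCol (or a group role) is required")
  xy <- marker_xy(table)
  cats <- markerColumn(table, categoryCol)
  if (is.double(cats)) stop("categoryCol must be categorical")
  genes <- sort(unique(cats))
  gcode <- match(cats, genes)
  finite <- is.finite(xy[, 1L]) & is.finite(xy[, 2L])

  bx <- floor(xy[finite, 1L] / binSize)
  by <- floor(xy[finite, 2L] / binSize)
  bx0 <- min(bx); by0 <- min(by)
  nbx <- max(bx) - bx0 + 1L; nby <- max(by) - by0 + 1L
  lin <- (bx - bx0) * nby + (by - by0) + 1L      # column-major [by, bx]
  nG <- length(genes)
  grids <- vector("list", nG)
  for (g in seq_len(nG)) {
    cnt <- tabulate(lin[gcode[finite] == g], nbx * nby)
    grids[[g]] <- matrix(cnt, nrow = nby, ncol = nbx)
  }
  occupied <- Reduce(`+`, grids) > 0
  occIdx <- which(occupied)          # linear [by, bx] indices
  if (K > length(occIdx))
    stop(sprintf("K = %d exceeds the %d non-empty bins", K, length(occIdx)))
  sigma <- smoothingRadius / binSize
  if (sigma > 0) grids <- lapply(grids, gaussian_smooth_grid, sigma = sigma)
  comp <- vapply(grids, function(g) g[occIdx], numeric(length(occIdx)))
  comp <- matrix(comp, nrow = length(occIdx))
  rs <- rowSums(comp)
  comp <- comp / ifelse(rs > 0, rs, 1)

  km <- with_seed(seed, {
    res <- tryCatch(kmeans(comp, centers = K, nstart = 10L, iter.max = 100L),
                    error = function(e) NULL)
    if (is.null(res))
      res <- kmeans(comp, centers = K, nstart = 10L, iter.max = 100L,
                    algorithm = "Lloyd")
    res
  })
  clusterOfBin <- rep(NA_integer_, nbx * nby)
  clusterOfBin[occIdx] <- km$cluster

  labels <- rep(NA_integer_, table@nRows)
  labels[which(finite)] <- clusterOfBin[lin]

  binInfo <- data.frame(
    binX = (occIdx - 1L) %/% nby + bx0,
    binY = (occIdx - 1L) %% nby + by0,
    cluster = km$cluster)
  polys <- if (contour)
    contour_bins(binInfo, binSize, K) else NULL

  new("RegionClusteringResult", labels = labels,
      binComposition = `dimnames<-`(comp, list(NULL, genes)),
      binInfo = binInfo,
      params = list(binSize = binSize, smoothingRadius = smoothingRadius,
                    K = as.integer(K), seed = as.integer(seed)),
      polygons = polys)
}

## Trace connected (4-neighbor) same-cluster bin components into closed
## rings of axis-aligned boundary segments; one MultiPolygon feature per
## cluster.  Ring vertices are in pixel units (bin corners).
contour_bins <- function(binInfo, binSize, K) {
  feats <- list()
  cellKey <- function(x, y) paste(x, y)
  for (k in seq_len(K)) {
    cells <- binInfo[binInfo$cluster == k, c("binX", "binY")]
    if (!nrow(cells)) next
    have <- new.env(parent = emptyenv())
    for (i in seq_len(nrow(cells)))
      assign(cellKey(cells$binX[i], cells$binY[i]), i, envir = have)
    seen <- logical(nrow(cells))
    polys <- list()
    for (s in seq_len(nrow(cells))) {
      if (seen[s]) next
      ## flood fill one component
      comp <- integer(); queue <- s; seen[s] <- TRUE
      while (length(queue)) {
        i <- queue[[1L]]; queue <- queue[-1L]
        comp <- c(comp, i)
        for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
          key <- cellKey(cells$binX[i] + d[1L], cells$binY[i] + d[2L])
          j <- mget(key, envir = have, ifnotfound = list(NULL))[[1L]]
          if (!is.null(j) && !seen[j]) { seen[j] <- TRUE; queue <- c(queue, j) }
        }
      }
      ## boundary edges, interior kept on a consistent side
      starts <- character(); ends <- character()
      sx <- numeric(); sy <- numeric(); ex <- numeric(); ey <- numeric()
      addEdge <- function(x1, y1, x2, y2) {
        sx[length(sx) + 1L] <<- x1; sy[length(sy) + 1L] <<- y1
        ex[length(ex) + 1L] <<- x2; ey[length(ey) + 1L] <<- y2
      }
      for (i in comp) {
        x <- cells$binX[i]; y <- cells$binY[i]
        if (is.null(mget(cellKey(x, y - 1L), have,
                         ifnotfound = list(NULL))[[1L]]))
          addEdge(x, y, x + 1L, y)               # top
        if (is.null(mget(cellKey(x + 1L, y), have,
                         ifnotfound = list(NULL))[[1L]]))
          addEdge(x + 1L, y, x + 1L, y + 1L)     # right
        if (is.null(mget(cellKey(x, y + 1L), have,
                         ifnotfound = list(NULL))[[1L]]))
          addEdge(x + 1L, y + 1L, x, y + 1L)     # bottom
        if (is.null(mget(cellKey(x - 1L, y), have,
                         ifnotfound = list(NULL))[[1L]]))
          addEdge(x, y + 1L, x, y)               # left
      }
      ## stitch directed edges into closed rings
      from <- paste(sx, sy)
      used <- logical(length(sx))
      lookup <- split(seq_along(from), from)
      rings <- list()
      for (e0 in seq_along(from)) {
        if (used[e0]) next
        ringX <- sx[e0]; ringY <- sy[e0]
        cur <- e0
        repeat {
          used[cur] <- TRUE
          ringX <- c(ringX, ex[cur]); ringY <- c(ringY, ey[cur])
          nxtKey <- paste(ex[cur], ey[cur])
          cand <- lookup[[nxtKey]]
          cand <- cand[!used[cand]]
          if (!length(cand)) break
          cur <- cand[1L]
        }
        rings[[length(rings) + 1L]] <-
          cbind(ringX, ringY) * binSize
      }
      ## outer ring (largest area) first
      areas <- vapply(rings, function(r)
        regionArea(list(list(r))), 0)
      polys[[length(polys) + 1L]] <- rings[order(-areas)]
    }
    feats[[length(feats) + 1L]] <- list(
      geometry = polys,
      properties = list(name = sprintf("cluster_%d", k), cluster = k),
      multi = length(polys) > 1L)
  }
  RegionSet(feats)
}

#' Gate a marker selection in feature or physical space
#'
#' Selects the rows whose coordinates -- in the chosen space -- fall
#' inside the polygon.  Row identity links the two spaces: the returned
#' index set addresses the same markers in both.
#'
#' @param table a [MarkerTable-class].
#' @param embeddingCols names of the two numeric embedding columns
#'   (e.g. UMAP axes); used when `space = "feature"`.
#' @param polygon selection geometry accepted by [pointInRegion()].
#' @param space `"feature"` or `"spatial"` (x/y roles).
#' @return sorted integer vector of selected 1-based row indices.
#' @export
gateSelection <- function(table, embeddingCols, polygon,
                          space = c("feature", "spatial")) {
  space <- match.arg(space)
  coords <- if (space == "feature") {
    if (length(embeddingCols) != 2L)
      stop("embeddingCols must name 2 numeric columns")
    u <- markerColumn(table, embeddingCols[1L])
    v <- markerColumn(table, embeddingCols[2L])
    if (!is.double(u) || !is.double(v))
      stop("embedding columns must be numeric")
    cbind(u, v)
  } else marker_xy(table)
  which(pointInRegion(polygon, coords))
}

#' Confusion matrix between two classifications of the same markers
#'
#' Markers are matched across the two tables by coordinates: exact
#' equality when `tolerance = 0`, otherwise greedy one-to-one nearest
#' neighbor within the tolerance (A rows in order; equal distances go
#' to the lower B index).  `counts[a, b]` is the number of matched
#' markers labelled `a` by method A and `b` by method B; per-cell index
#' lists support drill-down display.
#'
#' @param tableA,tableB [MarkerTable-class] objects with x/y roles.
#' @param labelACol,labelBCol categorical label columns.
#' @param tolerance match radius in pixels (default 0 = exact).
#' @return a [ConfusionResult-class].
#' @export
markerConfusion <- function(tableA, tableB, labelACol, labelBCol,
                            tolerance = 0) {
  xyA <- marker_xy(tableA); xyB <- marker_xy(tableB)
  la <- markerColumn(tableA, labelACol)
  lb <- markerColumn(tableB, labelBCol)
  mA <- integer(); mB <- integer()
  if (tolerance == 0) {
    keyA <- sprintf("%.17g_%.17g", xyA[, 1L], xyA[, 2L])
    keyB <- sprintf("%.17g_%.17g", xyB[, 1L], xyB[, 2L])
    byB <- split(seq_along(keyB), keyB)
    usedB <- logical(nrow(xyB))
    for (i in seq_along(keyA)) {
      cand <- byB[[keyA[i]]]
      cand <- cand[!usedB[cand]]
      if (length(cand)) {
        mA <- c(mA, i); mB <- c(mB, cand[1L])
        usedB[cand[1L]] <- TRUE
      }
    }
  } else {
    usedB <- logical(nrow(xyB))
    for (i in seq_len(nrow(xyA))) {
      d2 <- (xyB[, 1L] - xyA[i, 1L])^2 + (xyB[, 2L] - xyA[i, 2L])^2
      d2[usedB] <- Inf
      j <- which.min(d2)            # ties: lower index first
      if (length(j) && d2[j] <= tolerance^2) {
        mA <- c(mA, i); mB <- c(mB, j)
        usedB[j] <- TRUE
      }
    }
  }
  if (!length(mA)) stop("no markers matched between the two tables")
  rl <- sort(unique(la[mA])); cl <- sort(unique(lb[mB]))
  counts <- matrix(0L, length(rl), length(cl), dimnames = list(rl, cl))
  cells <- setNames(lapply(rl, function(a)
    setNames(vector("list", length(cl)), cl)), rl)
  for (t in seq_along(mA)) {
    a <- la[mA[t]]; b <- lb[mB[t]]
    counts[a, b] <- counts[a, b] + 1L
    cells[[a]][[b]]$a <- c(cells[[a]][[b]]$a, mA[t])
    cells[[a]][[b]]$b <- c(cells[[a]][[b]]$b, mB[t])
  }
  new("ConfusionResult", rowLabels = rl, colLabels = cl, counts = counts,
      cells = cells, nMatched = length(mA))
}
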