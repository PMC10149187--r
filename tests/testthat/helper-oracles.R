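# Independent brute-force oracles used to cross-check the package's
# optimized implementations.  These deliberately re-derive results by the
# most literal route available.

# Deep Zoom level count: repeatedly ceiling-halve the larger dimension
# until it reaches 1.
oracle_max_level <- function(width, height) {
  m <- max(width, height)
  L <- 0L
  while (m > 1) {
    m <- ceiling(m / 2)
    L <- L + 1L
  }
  L
}

oracle_level_dims <- function(width, height, level) {
  L <- oracle_max_level(width, height)
  w <- width; h <- height
  for (i in seq_len(L - level)) {
    w <- ceiling(w / 2); h <- ceiling(h / 2)
  }
  c(w, h)
}

# Scalar even-odd ray casting, one point and one ring at a time; on-edge
# points are classified inside via an explicit point-segment distance.
oracle_point_in_polys <- function(polys, px, py, tol = 1e-9) {
  inside <- FALSE
  onedge <- FALSE
  for (poly in polys) for (ring in poly) {
    nv <- nrow(ring) - 1L
    j <- nv
    for (i in seq_len(nv)) {
      xi <- ring[i, 1]; yi <- ring[i, 2]
      xj <- ring[j, 1]; yj <- ring[j, 2]
      if ((yi > py) != (yj > py) &&
          px < (xj - xi) * (py - yi) / (yj - yi) + xi)
        inside <- !inside
      dx <- xj - xi; dy <- yj - yi
      L2 <- dx * dx + dy * dy
      t <- if (L2 > 0) min(1, max(0, ((px - xi) * dx + (py - yi) * dy) / L2))
           else 0
      if ((px - (xi + t * dx))^2 + (py - (yi + t * dy))^2 <= tol^2)
        onedge <- TRUE
      j <- i
    }
  }
  inside || onedge
}

oracle_assign_regions <- function(regions, points) {
  out <- rep(NA_integer_, nrow(points))
  for (p in seq_len(nrow(points))) {
    for (fi in seq_len(nFeatures(regions))) {
      polys <- featureGeometry(regions, fi)
      if (oracle_point_in_polys(polys, points[p, 1], points[p, 2])) {
        out[p] <- fi
        break
      }
    }
  }
  out
}

# All-pairs knn with lower-index tie-break, the O(n^2) route.
oracle_knn_edges <- function(points, k) {
  n <- nrow(points)
  pairs <- matrix(integer(), ncol = 2)
  for (i in seq_len(n)) {
    d <- sqrt((points[, 1] - points[i, 1])^2 +
              (points[, 2] - points[i, 2])^2)
    ord <- order(d[-i], (seq_len(n))[-i])
    nb <- ((seq_len(n))[-i])[ord[seq_len(k)]]
    pairs <- rbind(pairs, cbind(pmin(i, nb), pmax(i, nb)))
  }
  pairs <- unique(pairs)
  pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
}

# Exhaustive permutation null for the edge-count statistic: enumerate
# every permutation of the label vector.
all_permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in all_permutations(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

oracle_exhaustive_pair_z <- function(edges, labels, a, b) {
  count_ab <- function(lab) {
    la <- lab[edges[, 1]]; lb <- lab[edges[, 2]]
    if (a == b) sum(la == a & lb == a)
    else sum((la == a & lb == b) | (la == b & lb == a))
  }
  obs <- count_ab(labels)
  null <- vapply(all_permutations(labels), count_ab, 0)
  mu <- mean(null)
  sdv <- sqrt(mean(null^2) - mu^2)
  list(observed = obs, mean = mu, sd = sdv,
       z = if (sdv > 0) (obs - mu) / sdv else 0)
}

# Random star-shaped simple polygon (optionally with a scaled hole),
# used by the geometry property tests.
random_polygon_feature <- function(center, radius, nv = 8L,
                                   hole = FALSE) {
  ang <- sort(runif(nv, 0, 2 * pi))
  r <- runif(nv, 0.4 * radius, radius)
  ring <- cbind(center[1] + r * cos(ang), center[2] + r * sin(ang))
  ring <- rbind(ring, ring[1, ])
  rings <- list(ring)
  if (hole) {
    hr <- ring
    hr[, 1] <- center[1] + (ring[, 1] - center[1]) * 0.4
    hr[, 2] <- center[2] + (ring[, 2] - center[2]) * 0.4
    rings[[2]] <- hr
  }
  list(geometry = list(rings), properties = list(), multi = FALSE)
}

random_region_scene <- function(seed, nPolys = 20L, nPoints = 1000L,
                                extent = 100) {
  set.seed(seed)
  feats <- lapply(seq_len(nPolys), function(i)
    random_polygon_feature(runif(2, 0, extent), runif(1, 3, 12),
                           nv = sample(5:10, 1), hole = i %% 3 == 0))
  list(regions = RegionSet(feats),
       points = cbind(runif(nPoints, 0, extent), runif(nPoints, 0, extent)))
}

# Stitch the top-level tiles of a built pyramid back into one image,
# stripping overlaps.
stitch_top_level <- function(tileDir, spec) {
  L <- maxLevel(spec)
  ts <- spec@tileSize
  w <- spec@width; h <- spec@height
  grid <- tileGrid(spec, L)
  recon <- matrix(0, h, w)
  for (row in 0:(grid[2] - 1)) for (col in 0:(grid[1] - 1)) {
    p <- png::readPNG(file.path(tileDir, L,
                                sprintf("%d_%d.png", col, row)))
    if (length(dim(p)) == 3L) p <- p[, , 1]
    x0 <- col * ts; y0 <- row * ts
    sx <- if (col == 0) 1L else spec@overlap + 1L
    sy <- if (row == 0) 1L else spec@overlap + 1L
    cw <- min(ts, w - x0); chh <- min(ts, h - y0)
    recon[(y0 + 1):(y0 + chh), (x0 + 1):(x0 + cw)] <-
      p[sy:(sy + chh - 1), sx:(sx + cw - 1)]
  }
  recon
}

# AnnData-like HDF5 fixture written at test time (categorical obs group,
# C-order obsm matrix emulated by the transposed R layout).
write_h5ad_fixture <- function(path, n = 20L) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "obs")
  rhdf5::h5createGroup(path, "obs/cell_type")
  cats <- c("astro", "micro", "neuron")
  codes <- rep_len(0:2, n)
  rhdf5::h5write(cats, path, "obs/cell_type/categories")
  rhdf5::h5write(as.integer(codes), path, "obs/cell_type/codes")
  fid <- rhdf5::H5Fopen(path)
  gid <- rhdf5::H5Gopen(fid, "obs/cell_type")
  rhdf5::h5writeAttribute("categorical", gid, "encoding-type",
                          asScalar = TRUE)
  rhdf5::H5Gclose(gid)
  rhdf5::H5Fclose(fid)
  rhdf5::h5createGroup(path, "obsm")
  spatial <- matrix(as.double(seq_len(2L * n)), nrow = 2L)  # (2, n) = C-order (n, 2)
  rhdf5::h5write(spatial, path, "obsm/spatial")
  rhdf5::h5write(as.double(seq_len(n)) / 7, path, "quality")
  rhdf5::h5closeAll()
  list(categories = cats, codes = codes, spatial = spatial)
}
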