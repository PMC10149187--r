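square_ring <- function(x0, y0, x1, y1)
  rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1), c(x0, y0))

test_that("region histograms count in-region markers by category", {
  tab <- MarkerTable(list(x = c(1, 2, 3, 50), y = c(1, 2, 3, 50),
                          gene = c("A", "A", "B", "C")),
                     roles = list(x = "x", y = "y"))
  roi <- square_ring(0, 0, 10, 10)
  h <- regionHistogram(tab, roi, "gene")
  expect_identical(h, c(A = 2L, B = 1L))
  expect_length(regionHistogram(tab, square_ring(90, 90, 99, 99), "gene"), 0L)
  all_h <- regionHistogram(tab, square_ring(0, 0, 100, 100), "gene")
  expect_identical(all_h, c(A = 2L, B = 1L, C = 1L))
  expect_identical(sum(all_h),
                   sum(pointInRegion(square_ring(0, 0, 100, 100),
                                     cbind(c(1, 2, 3, 50), c(1, 2, 3, 50)))))
  noroles <- MarkerTable(list(x = 1, gene = "A"))
  expect_error(regionHistogram(noroles, roi, "gene"), "roles")
})

test_that("neighbor graphs match the brute-force construction", {
  g2 <- buildNeighborGraph(rbind(c(0, 0), c(1, 0)), "knn", 1)
  expect_identical(graphEdges(g2), matrix(c(1L, 2L), ncol = 2))
  gl <- buildNeighborGraph(cbind(c(0, 1, 2), 0), "radius", 1)
  expect_identical(graphEdges(gl), rbind(c(1L, 2L), c(2L, 3L)))
  set.seed(21)
  pts <- cbind(runif(50, 0, 10), runif(50, 0, 10))
  for (k in c(1, 3, 6)) {
    got <- graphEdges(buildNeighborGraph(pts, "knn", k))
    want <- oracle_knn_edges(pts, k)
    expect_identical(got, matrix(as.integer(want), ncol = 2))
  }
  expect_error(buildNeighborGraph(pts, "knn", 50), "must be <")
  expect_error(buildNeighborGraph(pts, "radius", 0), "> 0")
})

test_that("the worked 4-node enrichment example matches its exhaustive permutation oracle", {
  ## path a-b-c-d with labels A,A,B,B
  edges <- rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L))
  g <- new("NeighborGraph", nNodes = 4L, edges = edges,
           params = list(method = "manual"))
  labels <- c("A", "A", "B", "B")
  exh <- oracle_exhaustive_pair_z(edges, labels, "A", "B")
  expect_identical(exh$observed, 1L)
  ## sampled permutation z converges to the exhaustive z
  res <- neighborhoodEnrichment(g, labels, nPerms = 20000, seed = 4)
  zAB <- enrichmentZ(res)["A", "B"]
  se <- 3 / sqrt(20000)   # conservative 3-standard-error band
  expect_lt(abs(zAB - exh$z), max(0.05, 10 * se))
  expect_identical(observedCounts(res)["A", "B"], 1)
})

test_that("enrichment z-matrices are symmetric and invariant to category renaming", {
  set.seed(5)
  pts <- cbind(runif(120, 0, 50), runif(120, 0, 50))
  g <- buildNeighborGraph(pts, "knn", 5)
  lab <- sample(c("A", "B", "C"), 120, replace = TRUE)
  r1 <- neighborhoodEnrichment(g, lab, nPerms = 300, seed = 9)
  z <- enrichmentZ(r1)
  expect_identical(z, t(z))
  ## renaming categories permutes the matrix consistently
  ren <- c(A = "zeta", B = "alpha", C = "mid")
  r2 <- neighborhoodEnrichment(g, unname(ren[lab]), nPerms = 300, seed = 9)
  z2 <- enrichmentZ(r2)
  for (a in names(ren)) for (b in names(ren))
    expect_identical(z2[ren[[a]], ren[[b]]], z[a, b])
  expect_error(neighborhoodEnrichment(g, rep("A", 120), 10, seed = 1),
               "single category")
})

test_that("spatially separated categories score negative cross-enrichment, cohesive ones positive", {
  set.seed(6)
  a <- cbind(runif(80, 0, 20), runif(80, 0, 20))
  b <- cbind(runif(80, 80, 100), runif(80, 80, 100))
  pts <- rbind(a, b)
  g <- buildNeighborGraph(pts, "radius", 10)
  res <- neighborhoodEnrichment(g, rep(c("A", "B"), each = 80),
                                nPerms = 500, seed = 2)
  z <- enrichmentZ(res)
  expect_lt(z["A", "B"], 0)
  expect_gt(z["A", "A"], 0)
  expect_gt(z["B", "B"], 0)
})

test_that("degenerate permutation nulls yield z = 0 with a flag", {
  ## complete graph on 4 nodes: every labeling gives identical pair counts
  edges <- t(combn(4L, 2L))
  g <- new("NeighborGraph", nNodes = 4L,
           edges = matrix(as.integer(edges), ncol = 2),
           params = list(method = "manual"))
  res <- neighborhoodEnrichment(g, c("A", "A", "B", "B"), nPerms = 50,
                                seed = 1)
  expect_true(all(enrichmentZ(res) == 0))
  expect_true(all(res@degenerate))
})

test_that("points2Regions recovers planted spatial domains", {
  sc <- simulateMarkers(8000, c("g1", "g2"), "domains", seed = 3)
  res <- points2Regions(sc$table, binSize = 50, K = 2, seed = 1)
  skip_if_not_installed("mclust")
  ari <- mclust::adjustedRandIndex(regionLabels(res), sc$groundTruth)
  expect_gte(ari, 0.99)
  ## label histogram covers every binned marker
  expect_identical(sum(table(regionLabels(res))), 8000L)
})

test_that("points2Regions handles the degenerate single-cluster case and bad K", {
  sc <- simulateMarkers(500, "g1", "domains",
                        params = list(nDomains = 1), seed = 2)
  res <- points2Regions(sc$table, binSize = 100, K = 1, seed = 1)
  expect_true(all(regionLabels(res) == 1L))
  expect_error(points2Regions(sc$table, binSize = 1000, K = 50, seed = 1),
               "non-empty bins")
})

test_that("points2Regions is invariant to input row order under the same seed", {
  sc <- simulateMarkers(2000, c("g1", "g2"), "domains", seed = 5)
  perm <- sample(2000)
  shuffled <- selectRows(sc$table, perm)
  r1 <- points2Regions(sc$table, binSize = 50, K = 2, seed = 7)
  r2 <- points2Regions(shuffled, binSize = 50, K = 2, seed = 7)
  expect_identical(regionLabels(r1)[perm], regionLabels(r2))
})

test_that("contoured cluster polygons rasterize back to the bin label map", {
  sc <- simulateMarkers(3000, c("g1", "g2"), "domains", seed = 11)
  res <- points2Regions(sc$table, binSize = 100, K = 2, seed = 1,
                        contour = TRUE)
  polys <- regionPolygons(res)
  expect_s4_class(polys, "RegionSet")
  info <- res@binInfo
  centers <- cbind((info$binX + 0.5) * 100, (info$binY + 0.5) * 100)
  for (fi in seq_len(nFeatures(polys))) {
    k <- featureProperties(polys, fi)$cluster
    mask <- pointInRegion(featureGeometry(polys, fi), centers)
    expect_identical(mask, info$cluster == k)
  }
})

test_that("gating selects the same rows in feature and physical space", {
  set.seed(9)
  n <- 100
  tab <- MarkerTable(list(x = runif(n, 0, 50), y = runif(n, 0, 50),
                          u = rnorm(n), v = rnorm(n)),
                     roles = list(x = "x", y = "y"))
  all_poly <- square_ring(-10, -10, 10, 10)
  expect_identical(gateSelection(tab, c("u", "v"), all_poly, "feature"),
                   seq_len(n))
  none <- gateSelection(tab, c("u", "v"), square_ring(90, 90, 99, 99),
                        "feature")
  expect_length(none, 0L)
  ## feature-space selection, then the spatial hull of those points,
  ## re-selected spatially, contains the original set
  sel <- gateSelection(tab, c("u", "v"), square_ring(-1, -1, 1, 1),
                       "feature")
  xy <- cbind(markerColumn(tab, "x"), markerColumn(tab, "y"))[sel, ]
  hull <- square_ring(min(xy[, 1]), min(xy[, 2]), max(xy[, 1]), max(xy[, 2]))
  spat <- gateSelection(tab, NULL, hull, "spatial")
  expect_true(all(sel %in% spat))
  expect_error(gateSelection(tab, c("u", "nope"), all_poly, "feature"),
               "nope")
})

test_that("confusion matrices enumerate matched label pairs with drill-down indices", {
  A <- MarkerTable(list(x = c(0, 1, 2), y = c(0, 0, 0),
                        lab = c("x", "x", "y")),
                   roles = list(x = "x", y = "y"))
  B <- MarkerTable(list(x = c(0, 1, 2), y = c(0, 0, 0),
                        lab = c("x", "y", "y")),
                   roles = list(x = "x", y = "y"))
  cm <- markerConfusion(A, B, "lab", "lab")
  expect_identical(confusionCounts(cm),
                   matrix(c(1L, 0L, 1L, 1L), 2,
                          dimnames = list(c("x", "y"), c("x", "y"))))
  expect_identical(cellIndices(cm, "x", "y")$a, 2L)
  expect_identical(cm@nMatched, 3L)
  ## identical labels give a diagonal matrix
  cd <- markerConfusion(A, A, "lab", "lab")
  expect_true(all(confusionCounts(cd)[lower.tri(confusionCounts(cd))] == 0))
  expect_identical(sum(diag(confusionCounts(cd))), 3L)
})

test_that("coordinate matching honours the tolerance", {
  A <- MarkerTable(list(x = c(0, 10), y = c(0, 0), lab = c("p", "q")),
                   roles = list(x = "x", y = "y"))
  Bj <- MarkerTable(list(x = c(0.3, 10.2), y = c(0.1, 0), lab = c("p", "q")),
                    roles = list(x = "x", y = "y"))
  expect_error(markerConfusion(A, Bj, "lab", "lab", tolerance = 0),
               "no markers matched")
  cm <- markerConfusion(A, Bj, "lab", "lab", tolerance = 0.5)
  expect_identical(cm@nMatched, 2L)
  expect_identical(sum(diag(confusionCounts(cm))), 2L)
})
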