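rand_style_table <- function(n, seed = 1) {
  set.seed(seed)
  MarkerTable(list(
    x = runif(n, 0, 4096), y = runif(n, 0, 4096),
    gene = sample(c("a", "b", "c"), n, replace = TRUE),
    sz = runif(n, 0.5, 20), op = runif(n),
    col = sample(c("#FF0000", "#00FF80", "steelblue"), n, replace = TRUE)),
    roles = list(x = "x", y = "y", group = "gene", size = "sz",
                 opacity = "op", color = "col"))
}

test_that("the vertex layout is exactly 32 bytes with fixed offsets", {
  lay <- vertexLayout()
  expect_identical(sum(lay$size), 32L)
  expect_identical(lay$offset, cumsum(c(0L, head(lay$size, -1))))
  tab <- rand_style_table(3)
  buf <- packMarkers(tab)
  expect_identical(length(packedBytes(buf)), 96L)
  expect_identical(nrow(uploadLog(buf)), 1L)
})

test_that("empty tables pack to empty buffers with no chunks", {
  tab <- MarkerTable(list(x = numeric(), y = numeric()),
                     roles = list(x = "x", y = "y"))
  buf <- packMarkers(tab)
  expect_identical(nRecords(buf), 0L)
  expect_identical(length(packedBytes(buf)), 0L)
  expect_identical(nrow(uploadLog(buf)), 0L)
})

test_that("decode of encode reproduces coordinates, index and style", {
  tab <- rand_style_table(200, seed = 7)
  buf <- packMarkers(tab)
  dec <- decodeRecords(buf)
  expect_identical(dec$markerIndex, 0:199)
  expect_equal(dec$x, markerColumn(tab, "x"), tolerance = 1e-6)
  expect_equal(dec$y, markerColumn(tab, "y"), tolerance = 1e-6)
  expect_equal(dec$size, markerColumn(tab, "sz"), tolerance = 1e-6)
  expect_equal(dec$opacity, markerColumn(tab, "op"), tolerance = 1e-6)
  rgb <- col2rgb(markerColumn(tab, "col"))
  expect_identical(dec$r, as.integer(rgb[1, ]))
  expect_identical(dec$g, as.integer(rgb[2, ]))
  expect_identical(dec$b, as.integer(rgb[3, ]))
  gid <- as.integer(factor(markerColumn(tab, "gene"),
                           levels = unique(markerColumn(tab, "gene")))) - 1L
  expect_identical(dec$groupId, gid)
  expect_equal(dec$sectorExtent, rep(1, 200), tolerance = 1e-4)
})

test_that("buffer bytes are independent of chunk size and chunks are logged contiguously", {
  tab <- rand_style_table(10, seed = 3)
  ref <- packMarkers(tab)
  b4 <- packMarkers(tab, chunkSize = 4)
  expect_identical(packedBytes(b4), packedBytes(ref))
  expect_identical(uploadLog(b4)$recordCount, c(4L, 4L, 2L))
  expect_identical(uploadLog(b4)$offset, c(0L, 4L, 8L))
})

test_that("non-finite coordinates are skipped and counted, never packed", {
  tab <- MarkerTable(list(x = c(1, NaN, 3, Inf), y = c(1, 2, 3, 4)),
                     roles = list(x = "x", y = "y"))
  buf <- packMarkers(tab)
  expect_identical(nRecords(buf), 2L)
  expect_identical(buf@nSkipped, 2L)
  expect_identical(decodeRecords(buf)$markerIndex, c(0L, 2L))
})

test_that("buffers survive a dump/load round trip with their JSON sidecar", {
  tab <- rand_style_table(17, seed = 9)
  buf <- packMarkers(tab, chunkSize = 5)
  path <- withr::local_tempfile(fileext = ".bin")
  dumpBuffer(buf, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- loadBuffer(path)
  expect_identical(packedBytes(back), packedBytes(buf))
  expect_identical(uploadLog(back)$recordCount, uploadLog(buf)$recordCount)
  expect_identical(decodeRecords(back), decodeRecords(buf))
})

test_that("pie expansion duplicates rows per sector and conserves mass", {
  set.seed(5)
  n <- 10
  tab <- MarkerTable(list(x = runif(n), y = runif(n),
                          s1 = runif(n), s2 = runif(n),
                          s3 = runif(n), s4 = runif(n)),
                     roles = list(x = "x", y = "y",
                                  pieSectors = c("s1", "s2", "s3", "s4")))
  pe <- expandPie(tab)
  expect_identical(nRows(pe), 40L)
  ext <- markerColumn(pe, "sector_extent")
  sums <- tapply(ext, markerColumn(pe, "parent_index"), sum)
  expect_true(all(abs(sums - 1) < 1e-12))

  one <- MarkerTable(list(x = c(0, 1), y = c(0, 0), s = c(2, 5)),
                     roles = list(x = "x", y = "y", pieSectors = "s"))
  expect_identical(markerColumn(expandPie(one), "sector_extent"), c(1, 1))

  tri <- MarkerTable(list(x = 0, y = 0, a = 1, b = 1, c = 2))
  ep <- expandPie(tri, c("a", "b", "c"))
  expect_equal(markerColumn(ep, "sector_extent"), c(0.25, 0.25, 0.5))
  expect_equal(markerColumn(ep, "sector_start"), c(0, 0.25, 0.5))
})

test_that("pie expansion rejects all-zero and negative sector rows by index", {
  bad <- MarkerTable(list(x = c(0, 1), y = c(0, 0),
                          a = c(1, 0), b = c(1, 0)))
  expect_error(expandPie(bad, c("a", "b")), "2")
  neg <- MarkerTable(list(x = 0, y = 0, a = -1, b = 2))
  expect_error(expandPie(neg, c("a", "b")), "negative")
})

test_that("zero-valued sectors keep their records so n*k counting is exact", {
  tab <- MarkerTable(list(x = 0, y = 0, a = 1, b = 0, c = 1))
  ep <- expandPie(tab, c("a", "b", "c"))
  expect_identical(nRows(ep), 3L)
  expect_equal(markerColumn(ep, "sector_extent"), c(0.5, 0, 0.5))
})

test_that("packed pie records carry parent index and sector fractions", {
  tab <- MarkerTable(list(x = c(10, 20), y = c(1, 2),
                          a = c(1, 3), b = c(3, 1)),
                     roles = list(x = "x", y = "y",
                                  pieSectors = c("a", "b")))
  dec <- decodeRecords(packMarkers(expandPie(tab)))
  expect_identical(dec$markerIndex, c(0L, 0L, 1L, 1L))
  expect_equal(dec$sectorExtent, c(0.25, 0.75, 0.75, 0.25), tolerance = 1e-4)
  expect_equal(dec$sectorStart, c(0, 0.25, 0, 0.75), tolerance = 1e-4)
})

test_that("edge geometry emits two triangles per edge with the right corners", {
  pts <- rbind(c(0, 0), c(10, 0), c(5, 5))
  v <- buildEdgeGeometry(pts, rbind(c(1, 2)), thickness = 2)
  expect_identical(dim(v), c(6L, 2L))
  corners <- unique(v)
  expect_setequal(split(corners, row(corners)[, 1]),
                  list(c(0, 1), c(0, -1), c(10, 1), c(10, -1)))
  expect_identical(dim(buildEdgeGeometry(pts, matrix(integer(), ncol = 2))),
                   c(0L, 2L))
  degen <- buildEdgeGeometry(rbind(c(1, 1), c(1, 1)), rbind(c(1, 2)), 2)
  expect_true(all(degen[, 1] == 1 & degen[, 2] == 1))
  expect_error(buildEdgeGeometry(pts, rbind(c(1, 9)), 1), "out of range")
})

test_that("neighbor-list columns parse to deduplicated sorted undirected edges", {
  tab <- MarkerTable(list(x = c(0, 1, 2), y = c(0, 0, 0),
                          nb = c("1", "0", "")))
  expect_identical(edgesFromNeighborLists(tab, "nb"),
                   matrix(c(1L, 2L), ncol = 2))
  tab2 <- MarkerTable(list(x = c(0, 1, 2), y = c(0, 0, 0),
                           nb = c("1;2", "", "")))
  expect_identical(edgesFromNeighborLists(tab2, "nb"),
                   rbind(c(1L, 2L), c(1L, 3L)))
  tab3 <- MarkerTable(list(x = c(0, 1), y = c(0, 0), nb = c("", "")))
  expect_identical(nrow(edgesFromNeighborLists(tab3, "nb")), 0L)
  tab4 <- MarkerTable(list(x = c(0, 1), y = c(0, 0), nb = c("x;1", "")))
  expect_error(edgesFromNeighborLists(tab4, "nb"), "row 1")
})

test_that("quad-tree sampling returns true viewport points, caps at the quota and is seeded", {
  set.seed(8)
  pts <- cbind(runif(300, 0, 100), runif(300, 0, 100))
  qt <- buildQuadTree(pts, capacity = 8)
  all_idx <- quadtreeSample(qt, pts, c(0, 0, 100, 100), 1000, seed = 1)
  expect_identical(all_idx, 1:300)
  expect_identical(quadtreeSample(qt, pts, c(0, 0, 100, 100), 0, seed = 1),
                   integer())
  vp <- c(10, 10, 60, 60)
  truth <- which(pts[, 1] >= 10 & pts[, 1] <= 60 &
                 pts[, 2] >= 10 & pts[, 2] <= 60)
  for (seed in 1:5) {
    s <- quadtreeSample(qt, pts, vp, 25, seed = seed)
    expect_length(s, 25L)
    expect_true(all(s %in% truth))
    expect_identical(s, quadtreeSample(qt, pts, vp, 25, seed = seed))
  }
  ## tiny tree: 5 points, capacity 4 -> root splits into 4 children
  p5 <- rbind(c(1, 1), c(9, 1), c(1, 9), c(9, 9), c(5, 5))
  t5 <- buildQuadTree(p5, capacity = 4)
  expect_false(t5$leaf)
  expect_length(t5$children, 4L)
  for (seed in 1:10)
    expect_true(all(quadtreeSample(t5, p5, c(0, 0, 10, 10), 3,
                                   seed = seed) %in% 1:5))
})
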