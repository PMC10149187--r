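make_project_dir <- function(dim = c(120, 90)) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  img <- makeImage(dim[1], dim[2], "noise", seed = 13)
  writeImageFile(img, file.path(dir, "layer1.png"))
  writeLines(c("x,y,gene", "10,10,a", "50,60,b", "70,20,a"),
             file.path(dir, "markers.csv"))
  proj <- makeProject(
    layers = list(list(name = "layer1",
                       source = file.path(dir, "layer1.png"),
                       mode = "composite")),
    markerTabs = list(list(name = "tab1",
                           path = file.path(dir, "markers.csv"),
                           roles = list(x = "x", y = "y", group = "gene"))))
  writeProject(proj, file.path(dir, "proj.tmap"))
  list(dir = dir, img = img, proj = proj)
}

start_server <- function(dir, maxRequests) {
  ready <- file.path(dir, "ready")
  port <- 20000L + sample.int(20000L, 1)
  libs <- paste(sprintf("'%s'", .libPaths()), collapse = ",")
  code <- sprintf(
    ".libPaths(c(%s)); spatview::serveProject(spatview::readProject('%s'), port=%d, maxRequests=%d, readyFile='%s', projectDir='%s')",
    libs, file.path(dir, "proj.tmap"), port, maxRequests, ready, dir)
  system2(file.path(R.home("bin"), "Rscript"), c("-e", shQuote(code)),
          wait = FALSE, stdout = file.path(dir, "server.log"),
          stderr = file.path(dir, "server.log"))
  for (i in 1:150) {
    if (file.exists(ready)) return(port)
    Sys.sleep(0.1)
  }
  stop("server did not come up: ",
       paste(readLines(file.path(dir, "server.log")), collapse = "; "))
}

test_that("project files round trip and validate referenced paths", {
  pd <- make_project_dir()
  back <- readProject(file.path(pd$dir, "proj.tmap"))
  expect_identical(back$schemaVersion, 1L)
  expect_identical(back$layers[[1]]$name, "layer1")
  expect_error(makeProject(layers = list(list(name = "x",
                                              source = "/nope.png"))),
               "does not exist")
})

test_that("served descriptors and tiles equal the offline pyramid byte for byte", {
  pd <- make_project_dir()
  port <- start_server(pd$dir, maxRequests = 7)
  base <- sprintf("http://127.0.0.1:%d", port)

  spec <- PyramidSpec(120, 90)
  dzi <- rawToChar(httpFetch(paste0(base, "/layer1.dzi")))
  expect_identical(dzi, dziDescriptor(spec))

  L <- maxLevel(spec)
  for (addr in list(c(L, 0, 0), c(L - 1, 0, 0), c(0, 0, 0))) {
    got <- httpFetch(sprintf("%s/layer1_files/%d/%d_%d.png", base,
                             addr[1], addr[2], addr[3]))
    expect_identical(attr(got, "status"), 200L)
    img <- pd$img
    for (i in seq_len(L - addr[1])) img <- downsample2x(img)
    off <- encodeTile(getTile(img, spec, addr[1], addr[2], addr[3]), "png")
    expect_identical(as.raw(got), off)
  }
  ## repeated request is byte-identical (second fetch hits the LRU cache)
  again <- httpFetch(sprintf("%s/layer1_files/%d/0_0.png", base, L))
  first <- encodeTile(getTile(pd$img, spec, L, 0, 0), "png")
  expect_identical(as.raw(again), first)
  ## out-of-grid tile and unknown layer give 404
  bad <- httpFetch(sprintf("%s/layer1_files/%d/9_9.png", base, L))
  expect_identical(attr(bad, "status"), 404L)
  none <- httpFetch(paste0(base, "/ghost.dzi"))
  expect_identical(attr(none, "status"), 404L)
})

test_that("the marker endpoint transfers only the requested columns", {
  pd <- make_project_dir()
  port <- start_server(pd$dir, maxRequests = 3)
  base <- sprintf("http://127.0.0.1:%d", port)
  one <- httpFetch(paste0(base, "/markers/tab1?columns=x"))
  full <- httpFetch(paste0(base, "/markers/tab1"))
  expect_lt(length(one), length(full))
  parsed <- jsonlite::fromJSON(rawToChar(one))
  expect_identical(names(parsed), "x")
  expect_equal(parsed$x, c(10, 50, 70))
  pr <- jsonlite::fromJSON(rawToChar(httpFetch(paste0(base, "/project"))))
  expect_identical(pr$schemaVersion, 1L)
})

test_that("viewport capture crops, composites and rasterizes markers", {
  img <- makeImage(64, 48, "blobs", seed = 2)
  cap <- captureViewport(list(img), list(displayParams()), c(0, 0, 64, 48))
  expect_identical(cap[, , 1], img)
  ## two-layer composite delegates to compositeLayers on the same crop
  g <- makeImage(64, 48, "gradient")
  prm <- list(displayParams(color = "red"), displayParams(color = "green"))
  cap2 <- captureViewport(list(img, g), prm, c(8, 4, 32, 16))
  ref <- compositeLayers(list(img[5:20, 9:40], g[5:20, 9:40]), prm)
  expect_identical(cap2, ref)
  expect_error(captureViewport(list(img), list(displayParams()),
                               c(0, 0, 0, 10)), "empty viewport")
  ## marker discs appear in the marker color
  tab <- MarkerTable(list(x = 32, y = 24), roles = list(x = "x", y = "y"))
  capm <- captureViewport(list(img), list(displayParams()), c(0, 0, 64, 48),
                          markers = tab,
                          markerStyle = list(color = "red", size = 4))
  expect_identical(capm[25, 33, ], c(1, 0, 0))
})

test_that("the CLI mirrors the library: convert/tile agree and enrich is deterministic", {
  dir <- withr::local_tempdir()
  img <- makeImage(100, 80, "noise", seed = 3)
  src <- file.path(dir, "img.png")
  writeImageFile(img, src)

  out <- utils::capture.output(
    rc <- cliMain(c("convert", src, file.path(dir, "pyr"))))
  expect_identical(rc, 0L)
  info <- jsonlite::fromJSON(out[length(out)])
  expect_identical(info$levels, maxLevel(100, 80) + 1L)

  tileOut <- file.path(dir, "t.png")
  utils::capture.output(
    rc2 <- cliMain(c("tile", src, "7", "0", "0", "--out", tileOut)))
  expect_identical(rc2, 0L)
  spec <- PyramidSpec(100, 80)
  expect_identical(readBin(tileOut, "raw", file.size(tileOut)),
                   encodeTile(getTile(img, spec, 7, 0, 0), "png"))
  ## tile served from the pyramid directory equals the CLI tile
  expect_identical(
    readBin(file.path(dir, "pyr", "img_files", "7", "0_0.png"), "raw",
            n = 1e6),
    readBin(tileOut, "raw", n = 1e6))

  csv <- file.path(dir, "m.csv")
  sc <- simulateMarkers(150, c("A", "B"), "csr", seed = 4)
  writeCsvMarkers(sc$table, csv)
  args <- c("enrich", csv, "--cat", "gene", "--radius", "80",
            "--perms", "100", "--seed", "11")
  r1 <- utils::capture.output(cliMain(args))
  r2 <- utils::capture.output(cliMain(args))
  expect_identical(r1, r2)
  expect_match(r1[1], "^category,")

  expect_identical(cliMain(c("frobnicate")), 2L)
})
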