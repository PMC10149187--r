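#' @include AllClasses.R
NULL

#' Deterministic synthetic test image
#'
#' Patterns: `"checkerboard"` (cells of side `cellSize`; the cell at the
#' origin is 1), `"gradient"` (strictly increasing left to right),
#' `"blobs"` (seeded Gaussian bumps, quantised to 8 bits) and `"noise"`
#' (seeded uniform 8-bit noise).  Identical arguments always produce
#' identical pixels.
#'
#' @param width,height image size in pixels (>= 1).
#' @param pattern pattern name.
#' @param seed integer seed (used by the random patterns).
#' @param cellSize checkerboard cell side.
#' @return a height x width matrix in `[0, 1]`.
#' @export
makeImage <- function(width, height,
                      pattern = c("checkerboard", "gradient", "blobs",
                                  "noise"),
                      seed = 1L, cellSize = 8L) {
  if (width < 1L || height < 1L) stop("dims must be >= 1")
  pattern <- match.arg(pattern)
  x <- matrix(rep(0:(width - 1L), each = height), nrow = height)
  y <- matrix(rep(0:(height - 1L), times = width), nrow = height)
  switch(pattern,
    checkerboard = (((x %/% cellSize) + (y %/% cellSize)) %% 2L == 0L) * 1,
    gradient = if (width == 1L) matrix(0, height, 1L)
               else x / (width - 1L),
    blobs = with_seed(seed, {
      img <- matrix(0, height, width)
      for (b in seq_len(6L)) {
        cx <- runif(1L, 0, width); cy <- runif(1L, 0, height)
        s <- runif(1L, min(width, height) / 12, min(width, height) / 5)
        img <- img + exp(-((x - cx)^2 + (y - cy)^2) / (2 * s^2))
      }
      round(pmin(img, 1) * 255) / 255
    }),
    noise = with_seed(seed, {
      matrix(floor(runif(width * height, 0, 256)) / 255, height, width)
    }))
}

#' Simulate a marked spatial point process
#'
#' Generates the study conditions for the analytics:
#' \describe{
#'   \item{`"csr"`}{complete spatial randomness -- uniform positions,
#'     labels drawn independently and uniformly; the calibration null
#'     for the enrichment test.}
#'   \item{`"domains"`}{axis-aligned vertical domains with distinct
#'     category compositions (category d is emitted in domain d with
#'     probability `purity`, default 1); the ground-truth partition for
#'     region clustering.}
#'   \item{`"attract"`}{the first two categories share `nBlobs`
#'     Gaussian blob centers (sd `blobSd`); remaining categories are
#'     uniform -- a positive control for enrichment.}
#' }
#'
#' @param n number of markers (>= 1).
#' @param categories character vector of category labels.
#' @param process `"csr"`, `"domains"` or `"attract"`.
#' @param params optional list: `width`, `height` (default 1000 px),
#'   `purity`, `nDomains`, `nBlobs`, `blobSd`.
#' @param seed integer seed; the scene is fully determined by the
#'   arguments.
#' @return a list with `table` (a [MarkerTable-class] with x/y/group
#'   roles), `groundTruth` (per-marker domain id for `"domains"`, the
#'   attracted category pair for `"attract"`, NULL for `"csr"`) and
#'   `params` (all generation parameters, logged).
#' @export
simulateMarkers <- function(n, categories,
                            process = c("csr", "domains", "attract"),
                            params = list(), seed = 1L) {
  if (n < 1L) stop("n must be >= 1")
  process <- match.arg(process)
  p <- modifyList(list(width = 1000, height = 1000, purity = 1,
                       nDomains = min(2L, length(categories)),
                       nBlobs = 10L, blobSd = 10), params)
  gt <- NULL
  with_seed(seed, {
    if (process == "csr") {
      x <- runif(n, 0, p$width); y <- runif(n, 0, p$height)
      gene <- sample(categories, n, replace = TRUE)
    } else if (process == "domains") {
      D <- p$nDomains
      if (D < 1L || D > length(categories))
        stop("nDomains must be in [1, length(categories)]")
      x <- runif(n, 0, p$width); y <- runif(n, 0, p$height)
      dom <- pmin(D, 1L + floor(x / (p$width / D)))
      pure <- runif(n) < p$purity
      gene <- ifelse(pure, categories[dom],
                     sample(categories, n, replace = TRUE))
      gt <- dom
    } else {
      if (length(categories) < 2L) stop("attract needs >= 2 categories")
      gene <- sample(categories, n, replace = TRUE)
      x <- runif(n, 0, p$width); y <- runif(n, 0, p$height)
      centers <- cbind(runif(p$nBlobs, 0, p$width),
                       runif(p$nBlobs, 0, p$height))
      ab <- gene %in% categories[1:2]
      nab <- sum(ab)
      ci <- sample.int(p$nBlobs, nab, replace = TRUE)
      x[ab] <- pmin(p$width, pmax(0, centers[ci, 1L] + rnorm(nab, 0, p$blobSd)))
      y[ab] <- pmin(p$height, pmax(0, centers[ci, 2L] + rnorm(nab, 0, p$blobSd)))
      gt <- categories[1:2]
    }
    tab <- MarkerTable(list(x = x, y = y, gene = gene),
                       roles = list(x = "x", y = "y", group = "gene"),
                       provenance = list(process = process, seed = seed,
                                         params = p))
    list(table = tab, groundTruth = gt,
         params = c(p, list(n = n, process = process, seed = seed,
                            categories = categories)))
  })
}
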