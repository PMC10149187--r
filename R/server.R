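#' @include AllClasses.R project.R
NULL

http_response <- function(status, body, contentType = "text/plain") {
  if (is.character(body)) body <- charToRaw(paste(body, collapse = "\n"))
  head <- sprintf(paste0("HTTP/1.1 %s\r\nContent-Type: %s\r\n",
                         "Content-Length: %d\r\nConnection: close\r\n\r\n"),
                  status, contentType, length(body))
  c(charToRaw(head), body)
}

## in-memory layer state: level images precomputed once so tiles are a
## pure function of (layer, level, col, row)
prepare_layers <- function(proj, dir) {
  resolve <- function(p) if (file.exists(p)) p else file.path(dir, p)
  out <- list()
  for (ly in proj$layers) {
    img <- readImageFile(resolve(ly$source))
    spec <- PyramidSpec(dim(img)[2L], dim(img)[1L],
                        tileSize = proj$tileSize %||% 254L,
                        overlap = proj$overlap %||% 1L,
                        format = proj$format %||% "png")
    levels <- vector("list", maxLevel(spec) + 1L)
    cur <- img
    for (lv in maxLevel(spec):0) {
      levels[[lv + 1L]] <- cur
      if (lv > 0L) cur <- downsample2x(cur)
    }
    out[[ly$name]] <- list(spec = spec, levels = levels)
  }
  out
}

serve_request <- function(path, layers, proj, tabs, cache) {
  ## /{layer}.dzi
  m <- regmatches(path, regexec("^/([^/]+)\\.dzi$", path))[[1L]]
  if (length(m)) {
    ly <- layers[[m[2L]]]
    if (is.null(ly)) return(http_response("404 Not Found", "no such layer"))
    return(http_response("200 OK", dziDescriptor(ly$spec),
                         "application/xml"))
  }
  ## /{layer}_files/{level}/{col}_{row}.{fmt}
  m <- regmatches(path, regexec(
    "^/(.+)_files/([0-9]+)/([0-9]+)_([0-9]+)\\.(png|jpeg)$", path))[[1L]]
  if (length(m)) {
    ly <- layers[[m[2L]]]
    if (is.null(ly)) return(http_response("404 Not Found", "no such layer"))
    level <- as.integer(m[3L]); col <- as.integer(m[4L])
    row <- as.integer(m[5L])
    if (level > maxLevel(ly$spec))
      return(http_response("404 Not Found", "level out of range"))
    key <- sprintf("%s/%d/%d_%d", m[2L], level, col, row)
    hit <- cache$get(key)
    if (!is.null(hit))
      return(http_response("200 OK", hit, paste0("image/", m[6L])))
    bytes <- tryCatch({
      tile <- getTile(ly$levels[[level + 1L]], ly$spec, level, col, row)
      encodeTile(tile, ly$spec@format)
    }, error = function(e) NULL)
    if (is.null(bytes))
      return(http_response("404 Not Found", "tile outside grid"))
    cache$set(key, bytes)
    return(http_response("200 OK", bytes, paste0("image/", m[6L])))
  }
  ## /markers/{tab}?columns=a,b
  m <- regmatches(path, regexec("^/markers/([^?]+)(\\?columns=(.*))?$",
                                path))[[1L]]
  if (length(m)) {
    tab <- tabs[[m[2L]]]
    if (is.null(tab)) return(http_response("404 Not Found", "no such tab"))
    cols <- if (nchar(m[4L]))
      strsplit(utils::URLdecode(m[4L]), ",", fixed = TRUE)[[1L]]
    else columnNames(tab)
    if (!all(cols %in% columnNames(tab)))
      return(http_response("404 Not Found", "no such column"))
    body <- jsonlite::toJSON(tab@columns[cols], digits = NA)
    return(http_response("200 OK", charToRaw(as.character(body)),
                         "application/json"))
  }
  if (path == "/project")
    return(http_response("200 OK",
      charToRaw(as.character(jsonlite::toJSON(proj, auto_unbox = TRUE,
                                              digits = NA, null = "null"))),
      "application/json"))
  http_response("404 Not Found", "not found")
}

lru_cache <- function(capacity = 256L) {
  store <- new.env(parent = emptyenv())
  order <- character()
  list(
    get = function(key) {
      if (!exists(key, envir = store)) return(NULL)
      order <<- c(setdiff(order, key), key)
      get(key, envir = store)
    },
    set = function(key, value) {
      if (!exists(key, envir = store) && length(order) >= capacity) {
        rm(list = order[1L], envir = store)
        order <<- order[-1L]
      }
      assign(key, value, envir = store)
      order <<- c(setdiff(order, key), key)
    })
}

#' Serve a project over HTTP
#'
#' A small blocking HTTP service exposing, for each layer, the DZI
#' descriptor at `GET /{layer}.dzi` and on-demand tiles at
#' `GET /{layer}_files/{level}/{col}_{row}.{fmt}` -- byte-identical to
#' the offline [buildPyramid()] output for the same address -- plus
#' column-selective marker data at `GET /markers/{tab}?columns=a,b` and
#' the configuration at `GET /project`.  Unknown tiles and layers give
#' 404.  Responses are pure functions of (project, request); an LRU
#' tile cache only short-circuits re-encoding.
#'
#' @param proj a project list ([makeProject()] / [readProject()]).
#' @param port TCP port; an occupied port raises an error.
#' @param host bind address.
#' @param maxRequests stop after this many requests (default `Inf`;
#'   handy for tests and scripted use).
#' @param readyFile optional path touched once the socket is
#'   listening.
#' @param projectDir directory against which relative project paths
#'   resolve.
#' @return invisibly, the number of requests served.
#' @export
serveProject <- function(proj, port, host = "127.0.0.1", maxRequests = Inf,
                         readyFile = NULL, projectDir = ".") {
  layers <- prepare_layers(proj, projectDir)
  resolve <- function(p) if (file.exists(p)) p else file.path(projectDir, p)
  tabs <- list()
  for (tb in proj$markerTabs)
    tabs[[tb$name]] <- streamLoadCsv(resolve(tb$path))
  cache <- lru_cache()
  sock <- tryCatch(serverSocket(port),
                   error = function(e)
                     stop(sprintf("cannot bind port %d: %s", port,
                                  conditionMessage(e))))
  on.exit(close(sock), add = TRUE)
  if (!is.null(readyFile)) writeLines(as.character(port), readyFile)
  served <- 0L
  while (served < maxRequests) {
    con <- socketAccept(sock, blocking = TRUE, open = "a+b", timeout = 60)
    req <- tryCatch({
      line <- sub("\r$", "", readLines(con, n = 1L))
      while (length(l2 <- readLines(con, n = 1L)) &&
             nzchar(sub("\r$", "", l2))) NULL
      line
    }, error = function(e) character())
    if (length(req) && nzchar(req)) {
      parts <- strsplit(req, " ", fixed = TRUE)[[1L]]
      path <- if (length(parts) >= 2L) parts[2L] else "/"
      resp <- tryCatch(serve_request(path, layers, proj, tabs, cache),
                       error = function(e)
                         http_response("500 Internal Server Error",
                                       conditionMessage(e)))
      writeBin(resp, con)
      flush(con)
      served <- served + 1L
    }
    close(con)
  }
  invisible(served)
}

#' Fetch one URL over HTTP as raw bytes
#'
#' Minimal client used by the tests and CLI to talk to
#' [serveProject()].
#'
#' @param url an `http://host:port/path` URL.
#' @return raw response body; the HTTP status is attached as attribute
#'   `status`.
#' @export
httpFetch <- function(url) {
  m <- regmatches(url, regexec("^http://([^:/]+):([0-9]+)(/.*)$",
                               url))[[1L]]
  if (!length(m)) stop("expected http://host:port/path")
  con <- socketConnection(m[2L], as.integer(m[3L]), open = "r+b",
                          blocking = TRUE, timeout = 30)
  on.exit(close(con))
  writeChar(sprintf("GET %s HTTP/1.1\r\nHost: %s\r\nConnection: close\r\n\r\n",
                    m[4L], m[2L]), con, eos = NULL)
  flush(con)
  head <- character()
  repeat {
    l <- readLines(con, n = 1L)
    if (!length(l)) break
    l <- sub("\r$", "", l)
    if (!nzchar(l)) break
    head <- c(head, l)
  }
  status <- as.integer(strsplit(head[1L], " ")[[1L]][2L])
  clen <- sub("(?i)^content-length: *", "",
              grep("(?i)^content-length:", head, value = TRUE, perl = TRUE),
              perl = TRUE)
  body <- readBin(con, "raw", n = as.integer(clen))
  attr(body, "status") <- status
  body
}
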