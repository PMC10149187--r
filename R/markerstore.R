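#' @include AllClasses.R
NULL

num_re <- "^[+-]?(([0-9]+\\.?[0-9]*)|(\\.[0-9]+))([eE][+-]?[0-9]+)?$"

#' Detect a numeric column
#'
#' A column of string cells is numeric when it has at least one
#' non-empty cell and every non-empty cell parses as a finite decimal or
#' scientific-notation number.  In numeric columns, empty cells become
#' `NaN`.
#'
#' @param values character vector of cell values.
#' @return TRUE/FALSE.
#' @examples
#' detectNumeric(c("1", "2.5", "3e2"))  # TRUE
#' detectNumeric(c("", "5"))            # TRUE (missing -> NaN)
#' detectNumeric(c("1", "x", "3"))      # FALSE
#' @export
detectNumeric <- function(values) {
  nonEmpty <- values[!is.na(values) & values != ""]
  length(nonEmpty) >= 1L && all(grepl(num_re, nonEmpty))
}

convert_column <- function(values) {
  if (detectNumeric(values)) {
    out <- suppressWarnings(as.numeric(values))
    out[is.na(values) | values == ""] <- NaN
    out
  } else {
    values[is.na(values)] <- ""
    values
  }
}

## Split one logical CSV row into fields.  Fast path: no quote character
## anywhere; slow path handles RFC-4180 quoting ("" escapes, embedded
## delimiters and newlines).
split_rows <- function(rows, delimiter) {
  if (!any(grepl('"', rows, fixed = TRUE))) {
    fields <- strsplit(rows, delimiter, fixed = TRUE)
    ## strsplit drops trailing empty fields; pad to separator count + 1
    want <- nchar(rows) - nchar(gsub(delimiter, "", rows, fixed = TRUE)) + 1L
    return(mapply(function(f, w)
      if (length(f) < w) c(f, rep("", w - length(f))) else f,
      fields, want, SIMPLIFY = FALSE, USE.NAMES = FALSE))
  }
  lapply(rows, function(r) {
    f <- scan(text = r, what = character(), sep = delimiter, quote = '"',
              quiet = TRUE, blank.lines.skip = FALSE, strip.white = FALSE)
    bare <- gsub('"[^"]*"', "", r)   # separators outside quoted fields
    w <- nchar(bare) - nchar(gsub(delimiter, "", bare, fixed = TRUE)) + 1L
    if (length(f) < w) c(f, rep("", w - length(f))) else f
  })
}

#' Stream-load a delimited marker file into a columnar table
#'
#' Reads a CSV in chunks of `chunkRows` text rows, so that the peak
#' amount of raw text held at any time is proportional to the chunk
#' size, not the file size.  The result is identical -- names, order,
#' values and types -- to a whole-file parse regardless of `chunkRows`.
#' Columns in which every non-empty cell parses as a number become
#' 64-bit numeric columns (missing values `NaN`); all others stay
#' categorical strings.
#'
#' @param source file path, connection, or character vector of lines.
#' @param chunkRows parsing granularity in rows (>= 1).
#' @param delimiter single field-separator character (default comma; no
#'   dialect sniffing).
#' @param hasHeader whether the first row carries column names; without
#'   one, columns are named `col_0`, `col_1`, ...
#' @param roles optional [MarkerTable-class] column roles.
#' @return a [MarkerTable-class].
#' @export
streamLoadCsv <- function(source, chunkRows = 10000L, delimiter = ",",
                          hasHeader = TRUE, roles = list()) {
  if (chunkRows < 1L) stop("chunkRows must be >= 1")
  if (is.character(source) && length(source) == 1L && file.exists(source)) {
    con <- file(source, open = "r")
    on.exit(close(con))
    src <- source
  } else if (inherits(source, "connection")) {
    con <- source
    if (!isOpen(con)) { open(con, "r"); on.exit(close(con)) }
    src <- "<connection>"
  } else {
    con <- textConnection(as.character(source))
    on.exit(close(con))
    src <- "<text>"
  }

  header <- NULL
  nf <- NULL
  pieces <- list()
  np <- 0L
  pending <- character()   # carry for quoted fields spanning lines
  rowNumber <- 0L

  take_rows <- function(lines) {
    ## join physical lines into logical rows (odd quote count = open field)
    out <- character(length(lines))
    k <- 0L
    for (ln in lines) {
      if (length(pending)) {
        pending <<- c(pending, ln)
        joined <- paste(pending, collapse = "\n")
        if (nchar(gsub('[^"]', "", joined)) %% 2L == 0L) {
          k <- k + 1L; out[k] <- joined; pending <<- character()
        }
      } else if (nchar(gsub('[^"]', "", ln)) %% 2L == 1L) {
        pending <<- ln
      } else {
        k <- k + 1L; out[k] <- ln
      }
    }
    out[seq_len(k)]
  }

  repeat {
    lines <- readLines(con, n = chunkRows)
    if (!length(lines)) break
    rows <- take_rows(lines)
    if (!length(rows)) next
    if (is.null(header) && hasHeader) {
      header <- split_rows(rows[1L], delimiter)[[1L]]
      nf <- length(header)
      rows <- rows[-1L]
      if (!length(rows)) next
    }
    fields <- split_rows(rows, delimiter)
    lens <- lengths(fields)
    if (is.null(nf)) {
      nf <- lens[1L]
      header <- sprintf("col_%d", seq_len(nf) - 1L)
    }
    if (any(lens != nf)) {
      bad <- which(lens != nf)[1L]
      stop(sprintf("ragged row %d: %d field(s), expected %d",
                   rowNumber + bad, lens[bad], nf))
    }
    rowNumber <- rowNumber + length(rows)
    np <- np + 1L
    pieces[[np]] <- unlist(fields, use.names = FALSE)
  }
  if (length(pending)) stop("unterminated quoted field at end of input")
  if (is.null(header)) stop("empty file")

  cells <- unlist(pieces, use.names = FALSE)
  n <- length(cells) / nf
  cols <- lapply(seq_len(nf), function(j)
    convert_column(if (n) cells[seq(j, length(cells), by = nf)]
                   else character()))
  names(cols) <- header
  new("MarkerTable", columns = cols, nRows = as.integer(n), roles = roles,
      provenance = list(source = src, chunkRows = chunkRows,
                        delimiter = delimiter, hasHeader = hasHeader))
}

format_numeric_cells <- function(x) {
  s <- formatC(x, digits = 15L, format = "g", width = 1L)
  rt <- suppressWarnings(as.numeric(s))
  bad <- which(is.finite(x) & (is.na(rt) | rt != x))
  s[bad] <- sprintf("%.17g", x[bad])
  s[is.nan(x)] <- ""
  s
}

#' Write a MarkerTable to CSV
#'
#' Numeric cells use round-trip decimal formatting (re-loading
#' reproduces the doubles exactly); `NaN` becomes an empty cell.
#' Fields containing the delimiter, quotes or newlines are RFC-4180
#' quoted.
#'
#' @param table a [MarkerTable-class].
#' @param path output file path.
#' @param delimiter field separator.
#' @return invisibly, `path`.
#' @export
writeCsvMarkers <- function(table, path, delimiter = ",") {
  cols <- lapply(table@columns, function(col)
    if (is.double(col)) format_numeric_cells(col) else col)
  quote_cells <- function(s) {
    need <- grepl(delimiter, s, fixed = TRUE) | grepl('"', s, fixed = TRUE) |
      grepl("\n", s, fixed = TRUE)
    s[need] <- paste0('"', gsub('"', '""', s[need], fixed = TRUE), '"')
    s
  }
  cols <- lapply(cols, quote_cells)
  hdr <- paste(quote_cells(names(cols)), collapse = delimiter)
  body <- if (table@nRows)
    do.call(paste, c(cols, sep = delimiter))
  else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

h5_is_categorical <- function(path, sel) {
  at <- tryCatch(rhdf5::h5readAttributes(path, sel), error = function(e) NULL)
  identical(at[["encoding-type"]], "categorical")
}

#' Selectively load columns from an HDF5 / AnnData file
#'
#' Reads only the selected datasets from disk; values equal a full-file
#' read of the same fields, at the precision stored on disk.  Selector
#' syntax (one per output column):
#' \describe{
#'   \item{`"obs/cell_type"`}{a 1D dataset, or an AnnData categorical
#'     group (`categories` + `codes`), decoded to strings.}
#'   \item{`"obsm/spatial:0"`}{0-based column `0` of a 2D dataset stored
#'     row-major (C order), as AnnData/h5py write it; only that column
#'     is read.}
#'   \item{`"X:3"`}{a dense X column, same convention.}
#' }
#'
#' @param path HDF5 (.h5 / .h5ad) file path.
#' @param selectors named character vector: output column name ->
#'   selector.
#' @param roles optional [MarkerTable-class] column roles.
#' @return a [MarkerTable-class] with one column per selector.
#' @export
loadH5Columns <- function(path, selectors, roles = list()) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  selectors <- unlist(selectors)
  if (is.null(names(selectors)) || any(names(selectors) == ""))
    stop("selectors must be named (output column names)")
  ls <- rhdf5::h5ls(path, recursive = TRUE)
  avail <- file.path(ls$group, ls$name)
  avail <- sub("^/+", "", avail)
  cols <- list()
  for (nm in names(selectors)) {
    sel <- selectors[[nm]]
    colIdx <- NA_integer_
    ds <- sel
    if (grepl(":", sel, fixed = TRUE)) {
      parts <- strsplit(sel, ":", fixed = TRUE)[[1L]]
      ds <- parts[1L]
      colIdx <- as.integer(parts[2L])
    }
    ds <- sub("^/+", "", ds)
    if (!ds %in% avail)
      stop(sprintf("selector '%s' not found; available: %s", sel,
                   paste(avail, collapse = ", ")))
    if (h5_is_categorical(path, ds)) {
      categories <- as.character(rhdf5::h5read(path, file.path(ds, "categories")))
      codes <- as.integer(rhdf5::h5read(path, file.path(ds, "codes")))
      v <- rep("", length(codes))
      v[codes >= 0L] <- categories[codes[codes >= 0L] + 1L]
      cols[[nm]] <- v
    } else if (!is.na(colIdx)) {
      ## C-order (n, k) dataset appears in R as (k, n): row colIdx+1 is
      ## the requested logical column; only that hyperslab is read.
      v <- rhdf5::h5read(path, ds, index = list(colIdx + 1L, NULL))
      cols[[nm]] <- as.double(v)
    } else {
      v <- rhdf5::h5read(path, ds)
      if (length(dim(v)) > 1L)
        stop(sprintf("selector '%s' is %dD; use '%s:<col>' to pick a column",
                     sel, length(dim(v)), sel))
      cols[[nm]] <- if (is.numeric(v) || is.logical(v)) as.double(v)
                    else as.character(v)
    }
  }
  lens <- lengths(cols)
  if (length(unique(lens)) > 1L)
    stop(sprintf("selected columns have mismatched lengths: %s",
                 paste(sprintf("%s=%d", names(lens), lens), collapse = ", ")))
  rhdf5::h5closeAll()
  new("MarkerTable", columns = cols,
      nRows = as.integer(if (length(lens)) lens[1L] else 0L),
      roles = roles,
      provenance = list(source = path, selectors = selectors))
}

#' Estimated in-memory footprint of a MarkerTable
#'
#' Numeric columns cost 8 bytes per row (64-bit doubles); categorical
#' columns are costed as dictionary-encoded: 4-byte codes per row plus
#' the bytes of the unique strings.
#'
#' @param x a [MarkerTable-class].
#' @return estimated bytes (a number).
#' @export
setMethod("memoryFootprint", "MarkerTable", function(x) {
  tot <- 0
  for (col in x@columns) {
    if (is.double(col)) tot <- tot + 8 * length(col)
    else tot <- tot + 4 * length(col) +
        sum(nchar(unique(col), type = "bytes"))
  }
  tot
})

#' Row subset of a MarkerTable
#'
#' @param x a [MarkerTable-class].
#' @param i 1-based row indices (integer vector) or a logical mask; all
#'   columns are filtered consistently, preserving order.
#' @return a [MarkerTable-class] with the same schema.
#' @export
setMethod("selectRows", "MarkerTable", function(x, i) {
  if (is.logical(i)) {
    if (length(i) != x@nRows) stop("logical mask length must equal nRows")
    i <- which(i)
  }
  i <- as.integer(i)
  if (length(i) && (min(i) < 1L || max(i) > x@nRows))
    stop(sprintf("row index out of range [1, %d]", x@nRows))
  new("MarkerTable", columns = lapply(x@columns, `[`, i),
      nRows = length(i), roles = x@roles, provenance = x@provenance)
})
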