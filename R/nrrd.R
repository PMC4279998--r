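# Minimal NRRD (raw encoding) reader/writer.
#
# Covers the subset this package needs: detached-free single files,
# dimension 2-4, types double/float/int/short/uchar, raw encoding,
# little-endian. NRRD stores the fastest axis first, which matches R's
# array memory layout, so no permutation is required.

nrrd_types <- list(
  double = list(what = "double", size = 8L),
  float  = list(what = "double", size = 4L),
  int    = list(what = "integer", size = 4L),
  short  = list(what = "integer", size = 2L),
  uchar  = list(what = "integer", size = 1L)
)

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000[0-9]$", magic)) stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("unexpected end of NRRD header")
    if (line == "") break
    if (startsWith(line, "#")) next
    kv <- regmatches(line, regexpr(": ", line), invert = TRUE)[[1]]
    if (length(kv) != 2L) next
    fields[[tolower(kv[1])]] <- kv[2]
  }
  type <- fields[["type"]]
  if (is.null(type) || is.null(nrrd_types[[type]]))
    stop("unsupported NRRD type: ", type %||% "<missing>")
  if (!identical(fields[["encoding"]], "raw"))
    stop("only raw NRRD encoding is supported")
  sizes <- as.integer(strsplit(trimws(fields[["sizes"]]), "\\s+")[[1]])
  endian <- fields[["endian"]] %||% "little"
  tinfo <- nrrd_types[[type]]
  n <- prod(sizes)
  vals <- readBin(con, what = tinfo$what, n = n, size = tinfo$size,
                  endian = endian, signed = tinfo$size > 1L)
  if (length(vals) != n) stop("NRRD payload truncated")
  spacings <- fields[["spacings"]]
  if (!is.null(spacings))
    spacings <- as.numeric(strsplit(trimws(spacings), "\\s+")[[1]])
  list(data = array(vals, dim = sizes), spacings = spacings, type = type)
}

write_nrrd <- function(data, path, spacings = NULL, type = NULL) {
  if (is.null(type)) type <- if (is.integer(data)) "int" else "double"
  tinfo <- nrrd_types[[type]]
  if (is.null(tinfo)) stop("unsupported NRRD type: ", type)
  d <- dim(data)
  if (is.null(d)) d <- length(data)
  hdr <- c(
    "NRRD0004",
    paste0("type: ", type),
    paste0("dimension: ", length(d)),
    paste0("sizes: ", paste(d, collapse = " ")),
    if (!is.null(spacings)) paste0("spacings: ", paste(format(spacings, digits = 17), collapse = " ")),
    "encoding: raw",
    "endian: little",
    ""
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  writeBin(as.vector(data), con, size = tinfo$size, endian = "little")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
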