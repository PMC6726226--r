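#' Write an array as a NRRD file
#'
#' Minimal NRRD writer covering the needs of this package: dense numeric or
#' integer arrays, raw little-endian or whitespace-separated text encoding.
#' Axis order follows R's column-major layout, so the first array dimension is
#' the fastest axis in the file (NRRD convention).
#'
#' @param x A numeric or integer array (any dimension >= 1).
#' @param path Output file path.
#' @param encoding `"raw"` (binary, little endian) or `"text"`.
#' @return `path`, invisibly.
#' @export
write_nrrd <- function(x, path, encoding = c("raw", "text")) {
  encoding <- match.arg(encoding)
  if (is.null(dim(x))) dim(x) <- length(x)
  type <- if (is.integer(x)) "int" else "double"
  header <- c(
    "NRRD0004",
    paste0("type: ", type),
    paste0("dimension: ", length(dim(x))),
    paste0("sizes: ", paste(dim(x), collapse = " ")),
    paste0("encoding: ", encoding)
  )
  if (encoding == "raw") header <- c(header, "endian: little")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(header, ""), con, sep = "\n")
  if (encoding == "raw") {
    writeBin(as.vector(x), con,
             size = if (type == "int") 4L else 8L, endian = "little")
  } else {
    writeLines(paste(format(as.vector(x), digits = 17, trim = TRUE,
                            scientific = TRUE),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read a NRRD file written by [write_nrrd()] (or a compatible subset)
#'
#' Supports `double`, `float`, `int`, `short` and `uchar` sample types with
#' `raw` or `text`/`ascii` encodings.
#'
#' @param path File path.
#' @return An array with the dimensions recorded in the header.
#' @export
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!startsWith(magic, "NRRD")) stop("not a NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L || !nzchar(line)) break
    if (startsWith(line, "#")) next
    kv <- regmatches(line, regexpr(": ", line), invert = TRUE)[[1]]
    if (length(kv) == 2L) fields[[tolower(kv[1])]] <- kv[2]
  }
  sizes <- as.integer(strsplit(trimws(fields$sizes), "\\s+")[[1]])
  n <- prod(sizes)
  type <- fields$type
  encoding <- fields$encoding
  if (encoding %in% c("text", "txt", "ascii")) {
    vals <- scan(con, what = double(), n = n, quiet = TRUE)
    if (type %in% c("int", "short", "uchar", "signed char", "uint"))
      vals <- as.integer(vals)
  } else if (encoding == "raw") {
    endian <- if (identical(fields$endian, "big")) "big" else "little"
    vals <- switch(type,
      double = readBin(con, double(), n = n, size = 8L, endian = endian),
      float  = readBin(con, double(), n = n, size = 4L, endian = endian),
      int    = readBin(con, integer(), n = n, size = 4L, endian = endian),
      short  = readBin(con, integer(), n = n, size = 2L, endian = endian),
      uchar  = readBin(con, integer(), n = n, size = 1L, signed = FALSE,
                       endian = endian),
      stop("unsupported NRRD type: ", type))
  } else {
    stop("unsupported NRRD encoding: ", encoding)
  }
  array(vals, dim = sizes)
}
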