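# Minimal MAT-file (Level 5) container support.
#
# Topographers commonly export elevation data as MATLAB binary containers
# holding a handful of named double arrays. Only that subset is supported
# here: uncompressed miMATRIX elements of class mxDOUBLE_CLASS. Compressed
# (v7) or cell/struct content raises an error naming the offending element.

MAT_MI_INT8 <- 1L
MAT_MI_UINT8 <- 2L
MAT_MI_INT32 <- 5L
MAT_MI_UINT32 <- 6L
MAT_MI_DOUBLE <- 9L
MAT_MI_COMPRESSED <- 15L
MAT_MI_MATRIX <- 14L
MAT_MX_DOUBLE_CLASS <- 6L

#' Read named double arrays from a MAT v5 container
#'
#' Parses the subset of the MAT Level-5 binary format used for point-cloud
#' exports: uncompressed data elements, each a double-precision numeric
#' array. Little- and big-endian files are both accepted.
#'
#' @param path Path to a `*.mat` file.
#' @return Named list of numeric arrays (dimensions preserved via `dim`).
#' @seealso [write_mat()] for the matching writer.
#' @export
read_mat <- function(path) {
  stopifnot(file.exists(path))
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 128L) stop("not a MAT v5 file (truncated header): ", path)
  endian_tag <- rawToChar(raw[127:128])
  endian <- if (endian_tag == "IM") "little" else if (endian_tag == "MI") "big" else
    stop("not a MAT v5 file (bad endian indicator): ", path)
  out <- list()
  pos <- 129L
  n <- length(raw)
  while (pos + 8L <= n + 1L) {
    hdr <- mat_read_tag(raw, pos, endian)
    if (hdr$type == MAT_MI_COMPRESSED) {
      stop("compressed MAT element found; only uncompressed v5/v6 containers are supported")
    }
    if (hdr$type != MAT_MI_MATRIX) {
      pos <- hdr$next_pos
      next
    }
    el <- mat_parse_matrix(raw[hdr$data_start:(hdr$data_start + hdr$nbytes - 1L)], endian)
    out[[el$name]] <- el$value
    pos <- hdr$next_pos
  }
  out
}

# Tag = 8-byte (type, nbytes) pair, or the packed "small data element" form
# where the high 16 bits of the type word carry the byte count.
mat_read_tag <- function(raw, pos, endian) {
  type_word <- readBin(raw[pos:(pos + 3L)], "integer", size = 4L, endian = endian)
  small_nbytes <- bitwAnd(bitwShiftR(type_word, 16L), 0xFFFFL)
  if (small_nbytes > 0L) {
    list(type = bitwAnd(type_word, 0xFFFFL), nbytes = small_nbytes,
         data_start = pos + 4L, next_pos = pos + 8L)
  } else {
    nbytes <- readBin(raw[(pos + 4L):(pos + 7L)], "integer", size = 4L, endian = endian)
    padded <- 8L * ((nbytes + 7L) %/% 8L)
    list(type = type_word, nbytes = nbytes,
         data_start = pos + 8L, next_pos = pos + 8L + padded)
  }
}

mat_parse_matrix <- function(buf, endian) {
  pos <- 1L
  flags <- mat_read_tag(buf, pos, endian)
  flag_words <- readBin(buf[flags$data_start:(flags$data_start + 7L)], "integer",
                        n = 2L, size = 4L, endian = endian)
  klass <- bitwAnd(flag_words[1L], 0xFFL)
  pos <- flags$next_pos
  dims_tag <- mat_read_tag(buf, pos, endian)
  dims <- readBin(buf[dims_tag$data_start:(dims_tag$data_start + dims_tag$nbytes - 1L)],
                  "integer", n = dims_tag$nbytes %/% 4L, size = 4L, endian = endian)
  pos <- dims_tag$next_pos
  name_tag <- mat_read_tag(buf, pos, endian)
  name <- if (name_tag$nbytes > 0L)
    rawToChar(buf[name_tag$data_start:(name_tag$data_start + name_tag$nbytes - 1L)])
  else ""
  pos <- name_tag$next_pos
  if (klass != MAT_MX_DOUBLE_CLASS) {
    stop("MAT variable '", name, "' is not a double array (class code ", klass,
         "); only numeric arrays are supported")
  }
  data_tag <- mat_read_tag(buf, pos, endian)
  if (data_tag$type != MAT_MI_DOUBLE) {
    stop("MAT variable '", name, "' stores non-double data (type code ",
         data_tag$type, ")")
  }
  vals <- readBin(buf[data_tag$data_start:(data_tag$data_start + data_tag$nbytes - 1L)],
                  "double", n = data_tag$nbytes %/% 8L, size = 8L, endian = endian)
  if (length(dims) > 1L && prod(dims) == length(vals)) dim(vals) <- dims
  list(name = name, value = vals)
}

#' Write named double arrays to a MAT v5 container
#'
#' @param vars Named list of numeric vectors/matrices.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mat <- function(vars, path) {
  stopifnot(is.list(vars), length(names(vars)) == length(vars), all(nzchar(names(vars))))
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("MATLAB 5.0 MAT-file, created by scleratopo %s",
                              format(Sys.Date())))
  header <- c(header, rep(as.raw(0x20), 116L - length(header)))
  writeBin(header, con)
  writeBin(rep(as.raw(0L), 8L), con)                       # subsys offset
  writeBin(as.raw(c(0x00, 0x01)), con)                     # version 0x0100
  writeBin(charToRaw("IM"), con)                           # little-endian tag
  for (nm in names(vars)) mat_write_matrix(con, nm, vars[[nm]])
  invisible(path)
}

mat_write_matrix <- function(con, name, value) {
  v <- as.double(value)
  dims <- if (is.null(dim(value))) c(length(v), 1L) else as.integer(dim(value))
  name_raw <- charToRaw(name)
  pad8 <- function(k) (8L - k %% 8L) %% 8L
  name_pad <- pad8(length(name_raw))
  body_bytes <- 16L +                                      # array flags
    8L + 4L * length(dims) + pad8(4L * length(dims)) +     # dimensions
    8L + length(name_raw) + name_pad +                     # name
    8L + 8L * length(v)                                    # data (already 8-aligned)
  writeBin(c(MAT_MI_MATRIX, body_bytes), con, size = 4L, endian = "little")
  writeBin(c(MAT_MI_UINT32, 8L), con, size = 4L, endian = "little")
  writeBin(c(MAT_MX_DOUBLE_CLASS, 0L), con, size = 4L, endian = "little")
  writeBin(c(MAT_MI_INT32, 4L * length(dims)), con, size = 4L, endian = "little")
  writeBin(as.integer(dims), con, size = 4L, endian = "little")
  writeBin(rep(as.raw(0L), pad8(4L * length(dims))), con)
  writeBin(c(MAT_MI_INT8, length(name_raw)), con, size = 4L, endian = "little")
  writeBin(name_raw, con)
  writeBin(rep(as.raw(0L), name_pad), con)
  writeBin(c(MAT_MI_DOUBLE, 8L * length(v)), con, size = 4L, endian = "little")
  writeBin(v, con, size = 8L, endian = "little")
}
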