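# Minimal MAT-file (level 5) support, limited to real numeric 2-D matrices.
# This is all the SPC-2015 record layout needs; there is no MAT reader in the
# package's dependency set, so the subset is implemented here. Little-endian
# files only (the format written by scipy.io and virtually every modern tool).

MI_INT8 <- 1L; MI_UINT8 <- 2L; MI_INT16 <- 3L; MI_UINT16 <- 4L
MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_SINGLE <- 7L; MI_DOUBLE <- 9L
MI_INT64 <- 12L; MI_UINT64 <- 13L; MI_MATRIX <- 14L; MI_COMPRESSED <- 15L
MX_DOUBLE_CLASS <- 6L

mat5_numeric_types <- c(MI_INT8, MI_UINT8, MI_INT16, MI_UINT16, MI_INT32,
                        MI_UINT32, MI_SINGLE, MI_DOUBLE, MI_INT64, MI_UINT64)

# read `n` values of mat data type `type` from a raw vector
mat5_read_numeric <- function(raw, type) {
  switch(as.character(type),
    "1" = as.numeric(readBin(raw, "integer", length(raw), size = 1L,
                             signed = TRUE, endian = "little")),
    "2" = as.numeric(readBin(raw, "integer", length(raw), size = 1L,
                             signed = FALSE, endian = "little")),
    "3" = as.numeric(readBin(raw, "integer", length(raw) / 2L, size = 2L,
                             signed = TRUE, endian = "little")),
    "4" = as.numeric(readBin(raw, "integer", length(raw) / 2L, size = 2L,
                             signed = FALSE, endian = "little")),
    "5" = as.numeric(readBin(raw, "integer", length(raw) / 4L, size = 4L,
                             endian = "little")),
    "6" = {
      v <- readBin(raw, "integer", length(raw) / 4L, size = 4L, endian = "little")
      ifelse(v < 0, v + 2^32, as.numeric(v))
    },
    "7" = readBin(raw, "double", length(raw) / 4L, size = 4L, endian = "little"),
    "9" = readBin(raw, "double", length(raw) / 8L, size = 8L, endian = "little"),
    stop("unsupported MAT data type: ", type)
  )
}

# parse one data element starting at offset `pos` (1-based) in raw vector;
# returns list(type, data_raw, next_pos)
mat5_read_element <- function(bytes, pos) {
  word <- readBin(bytes[pos:(pos + 3L)], "integer", 1L, size = 4L, endian = "little")
  small_size <- bitwAnd(bitwShiftR(word, 16L), 0xFFFFL)
  if (small_size != 0L) {            # small data element: type+size packed in 4 bytes
    type <- bitwAnd(word, 0xFFFFL)
    data <- bytes[(pos + 4L):(pos + 3L + small_size)]
    return(list(type = type, data = data, next_pos = pos + 8L))
  }
  type <- word
  size <- readBin(bytes[(pos + 4L):(pos + 7L)], "integer", 1L, size = 4L,
                  endian = "little")
  data <- if (size > 0L) bytes[(pos + 8L):(pos + 7L + size)] else raw(0)
  pad <- if (type == MI_COMPRESSED) 0L else (8L - size %% 8L) %% 8L
  list(type = type, data = data, next_pos = pos + 8L + size + pad)
}

# parse a miMATRIX payload into a named numeric matrix (or NULL if not numeric)
mat5_parse_matrix <- function(payload) {
  pos <- 1L
  flags <- mat5_read_element(payload, pos)
  cls <- as.integer(flags$data[1L])
  cplx <- bitwAnd(as.integer(flags$data[2L]), 8L) != 0L
  pos <- flags$next_pos
  dims_el <- mat5_read_element(payload, pos)
  dims <- readBin(dims_el$data, "integer", length(dims_el$data) / 4L,
                  size = 4L, endian = "little")
  pos <- dims_el$next_pos
  name_el <- mat5_read_element(payload, pos)
  name <- rawToChar(name_el$data[name_el$data != as.raw(0)])
  pos <- name_el$next_pos
  if (cls > 15L || cls < 6L || length(dims) != 2L) {
    return(list(name = name, value = NULL))   # cell/struct/char etc: skipped
  }
  pr <- mat5_read_element(payload, pos)
  if (!(pr$type %in% mat5_numeric_types)) return(list(name = name, value = NULL))
  vals <- mat5_read_numeric(pr$data, pr$type)
  if (cplx) warning("imaginary part of variable '", name, "' discarded")
  list(name = name, value = matrix(vals, nrow = dims[1L], ncol = dims[2L]))
}

#' Read a MAT v5 file of numeric matrices
#'
#' Reads MATLAB level-5 `.mat` files containing real numeric 2-D matrices
#' (the layout used by SPC-2015-style records). Compressed elements are
#' supported; character, cell and struct variables are skipped; big-endian
#' files are rejected.
#'
#' @param path path to the `.mat` file.
#' @return Named list of numeric matrices.
#' @seealso [write_mat5()], [read_spc2015_record()]
#' @export
read_mat5 <- function(path) {
  if (!file.exists(path)) stop("cannot read MAT file: ", path)
  bytes <- readBin(path, "raw", file.info(path)$size)
  if (length(bytes) < 128L) stop("not a MAT v5 file (truncated header): ", path)
  endian <- rawToChar(bytes[127:128])
  if (endian == "MI") stop("big-endian MAT files are not supported")
  if (endian != "IM") stop("not a MAT v5 file (bad endian indicator): ", path)
  out <- list()
  pos <- 129L
  n <- length(bytes)
  while (pos + 7L <= n) {
    el <- mat5_read_element(bytes, pos)
    if (el$type == MI_COMPRESSED) {
      inner <- memDecompress(el$data, type = "gzip")
      sub <- mat5_read_element(inner, 1L)
      if (sub$type == MI_MATRIX) {
        m <- mat5_parse_matrix(sub$data)
        if (!is.null(m$value)) out[[m$name]] <- m$value
      }
    } else if (el$type == MI_MATRIX) {
      m <- mat5_parse_matrix(el$data)
      if (!is.null(m$value)) out[[m$name]] <- m$value
    }
    pos <- el$next_pos
  }
  out
}

mat5_write_element <- function(con, type, data_raw) {
  writeBin(as.integer(type), con, size = 4L, endian = "little")
  writeBin(length(data_raw), con, size = 4L, endian = "little")
  writeBin(data_raw, con)
  pad <- (8L - length(data_raw) %% 8L) %% 8L
  if (pad > 0L) writeBin(raw(pad), con)
}

#' Write a MAT v5 file of numeric matrices
#'
#' Writes real numeric vectors/matrices as double-precision variables in an
#' uncompressed little-endian MATLAB level-5 file, readable by MATLAB, Octave
#' and scipy.io.
#'
#' @param vars named list of numeric vectors (stored as 1-row matrices) or
#'   matrices.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mat5 <- function(vars, path) {
  stopifnot(is.list(vars), length(names(vars)) == length(vars),
            all(nzchar(names(vars))))
  con <- file(path, "wb")
  on.exit(close(con))
  desc <- sprintf("MATLAB 5.0 MAT-file, written by hankelppg on %s",
                  format(Sys.time(), "%Y-%m-%d"))
  hdr <- charToRaw(desc)
  length(hdr) <- 116L
  hdr[is.na(hdr)] <- as.raw(32L)
  writeBin(hdr, con)
  writeBin(raw(8L), con)                                  # subsystem offset
  writeBin(as.raw(c(0x00, 0x01)), con)                    # version 0x0100
  writeBin(charToRaw("IM"), con)                          # endian indicator
  for (nm in names(vars)) {
    v <- vars[[nm]]
    if (!is.matrix(v)) v <- matrix(as.numeric(v), nrow = 1L)
    storage.mode(v) <- "double"
    body <- local({
      bc <- rawConnection(raw(0), "wb")
      on.exit(close(bc))
      mat5_write_element(bc, MI_UINT32,
                         writeBin(c(MX_DOUBLE_CLASS, 0L), raw(), size = 4L,
                                  endian = "little"))
      mat5_write_element(bc, MI_INT32,
                         writeBin(dim(v), raw(), size = 4L, endian = "little"))
      mat5_write_element(bc, MI_INT8, charToRaw(nm))
      mat5_write_element(bc, MI_DOUBLE,
                         writeBin(as.vector(v), raw(), size = 8L,
                                  endian = "little"))
      rawConnectionValue(bc)
    })
    writeBin(MI_MATRIX, con, size = 4L, endian = "little")
    writeBin(length(body), con, size = 4L, endian = "little")
    writeBin(body, con)
  }
  invisible(path)
}
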