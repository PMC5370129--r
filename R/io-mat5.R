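# Minimal MAT v5 container codec (little-endian), sufficient for EEGLAB-style
# .set files: numeric arrays (double/single), character vectors and (arrays
# of) structs. Writing is always uncompressed; reading also accepts
# zlib-compressed (miCOMPRESSED) top-level elements.

MI_INT8 <- 1L; MI_UINT8 <- 2L; MI_INT16 <- 3L; MI_UINT16 <- 4L
MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_SINGLE <- 7L; MI_DOUBLE <- 9L
MI_MATRIX <- 14L; MI_COMPRESSED <- 15L; MI_UTF8 <- 16L
MX_STRUCT <- 2L; MX_CHAR <- 4L; MX_DOUBLE <- 6L; MX_SINGLE <- 7L

# ---- writing ---------------------------------------------------------------

mat5_pad <- function(raw_vec) {
  rem <- length(raw_vec) %% 8L
  if (rem) c(raw_vec, raw(8L - rem)) else raw_vec
}

mat5_tag <- function(type, nbytes) {
  writeBin(as.integer(c(type, nbytes)), raw(), size = 4, endian = "little")
}

mat5_element <- function(type, data_raw) {
  c(mat5_tag(type, length(data_raw)), mat5_pad(data_raw))
}

mat5_numeric_subelement <- function(x, single = FALSE) {
  if (single) {
    mat5_element(MI_SINGLE, writeBin(as.numeric(x), raw(), size = 4,
                                     endian = "little"))
  } else {
    mat5_element(MI_DOUBLE, writeBin(as.numeric(x), raw(), size = 8,
                                     endian = "little"))
  }
}

# serialize one R object as a named miMATRIX element (name "" for struct
# fields); matrices column-major, vectors as 1 x n row vectors
mat5_matrix <- function(x, name = "", single = FALSE,
                        single_fields = character(0)) {
  if (is.character(x)) {
    stopifnot(length(x) <= 1)
    chars <- if (length(x) == 0 || !nzchar(x)) integer(0) else
      utf8ToInt(enc2utf8(x))
    dims <- c(if (length(chars)) 1L else 0L, length(chars))
    cls <- MX_CHAR
    payload <- mat5_element(MI_UINT16,
                            writeBin(as.integer(chars), raw(), size = 2,
                                     endian = "little"))
  } else if (is.list(x)) { # struct (fields = names) or struct array
    return(mat5_struct(x, name, single_fields))
  } else {
    if (is.matrix(x)) {
      dims <- dim(x)
    } else {
      dims <- c(if (length(x)) 1L else 0L, length(x))
    }
    cls <- if (single) MX_SINGLE else MX_DOUBLE
    payload <- mat5_numeric_subelement(x, single)
  }
  body <- c(
    mat5_element(MI_UINT32, writeBin(as.integer(c(cls, 0L)), raw(), size = 4,
                                     endian = "little")),
    mat5_element(MI_INT32, writeBin(as.integer(dims), raw(), size = 4,
                                    endian = "little")),
    mat5_element(MI_INT8, if (nzchar(name)) charToRaw(name) else raw(0)),
    payload
  )
  c(mat5_tag(MI_MATRIX, length(body)), body)
}

# struct: a named list (1 x 1 struct) or an unnamed list of identically
# named lists (1 x n struct array)
mat5_struct <- function(x, name = "", single_fields = character(0)) {
  if (!is.null(names(x)) && all(nzchar(names(x)))) {
    elems <- list(x)
  } else {
    elems <- x
  }
  fields <- names(elems[[1]])
  maxlen <- 32L
  fn_raw <- do.call(c, lapply(fields, function(f) {
    b <- charToRaw(f)
    if (length(b) >= maxlen) stop_assrmix("Struct field name too long.")
    c(b, raw(maxlen - length(b)))
  }))
  body <- c(
    mat5_element(MI_UINT32, writeBin(as.integer(c(MX_STRUCT, 0L)), raw(),
                                     size = 4, endian = "little")),
    mat5_element(MI_INT32, writeBin(c(1L, length(elems)), raw(), size = 4,
                                    endian = "little")),
    mat5_element(MI_INT8, if (nzchar(name)) charToRaw(name) else raw(0)),
    mat5_element(MI_INT32, writeBin(maxlen, raw(), size = 4,
                                    endian = "little")),
    mat5_element(MI_INT8, fn_raw)
  )
  for (el in elems) {
    stopifnot(identical(names(el), fields))
    for (f in fields) {
      body <- c(body, mat5_matrix(el[[f]], name = "",
                                  single = f %in% single_fields,
                                  single_fields = single_fields))
    }
  }
  c(mat5_tag(MI_MATRIX, length(body)), body)
}

# write named top-level variables (a named list) to a MAT5 file
mat5_write <- function(vars, path, single_fields = character(0)) {
  header <- charToRaw(sprintf(
    "MATLAB 5.0 MAT-file, Platform: %s, Created by: assrmix", R.version$os))
  header <- c(header[seq_len(min(116, length(header)))],
              raw(max(0, 116 - length(header))))
  header <- c(header, raw(8)) # subsystem offset
  header <- c(header, writeBin(c(0x00L, 0x01L), raw(), size = 1)) # 0x0100 LE
  header <- c(header, charToRaw("IM"))
  body <- raw(0)
  for (nm in names(vars)) {
    body <- c(body, mat5_matrix(vars[[nm]], name = nm,
                                single = nm %in% single_fields,
                                single_fields = single_fields))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(header, body), con)
  invisible(path)
}

# ---- reading ---------------------------------------------------------------

mat5_reader <- function(raw_vec) {
  env <- new.env(parent = emptyenv())
  env$buf <- raw_vec
  env$pos <- 1L
  env
}

mat5_take <- function(rd, n) {
  if (n == 0) return(raw(0))
  out <- rd$buf[rd$pos:(rd$pos + n - 1L)]
  rd$pos <- rd$pos + n
  out
}

mat5_read_tag <- function(rd) {
  w <- readBin(mat5_take(rd, 4L), "integer", size = 4, endian = "little")
  small <- bitwAnd(w, -65536L) # upper 16 bits
  if (small != 0L) {
    list(type = bitwAnd(w, 65535L), nbytes = bitwShiftR(small, 16),
         small = TRUE)
  } else {
    n <- readBin(mat5_take(rd, 4L), "integer", size = 4, endian = "little")
    list(type = w, nbytes = n, small = FALSE)
  }
}

mat5_read_data <- function(rd, tag) {
  data <- mat5_take(rd, tag$nbytes)
  if (tag$small) {
    mat5_take(rd, 4L - tag$nbytes)
  } else {
    rem <- tag$nbytes %% 8L
    if (rem) mat5_take(rd, 8L - rem)
  }
  data
}

mat5_decode_numeric <- function(data, type) {
  switch(as.character(type),
    "1" = readBin(data, "integer", n = length(data), size = 1, signed = TRUE),
    "2" = readBin(data, "integer", n = length(data), size = 1, signed = FALSE),
    "3" = readBin(data, "integer", n = length(data) / 2, size = 2,
                  signed = TRUE, endian = "little"),
    "4" = readBin(data, "integer", n = length(data) / 2, size = 2,
                  signed = FALSE, endian = "little"),
    "5" = readBin(data, "integer", n = length(data) / 4, size = 4,
                  endian = "little"),
    "6" = readBin(data, "integer", n = length(data) / 4, size = 4,
                  endian = "little"), # uint32 read as int32 (values < 2^31)
    "7" = readBin(data, "numeric", n = length(data) / 4, size = 4,
                  endian = "little"),
    "9" = readBin(data, "numeric", n = length(data) / 8, size = 8,
                  endian = "little"),
    "16" = utf8ToInt(rawToChar(data)),
    stop_assrmix(sprintf("Unsupported MAT data type %d.", type))
  )
}

# read one miMATRIX body; returns list(name=, value=)
mat5_read_matrix <- function(rd) {
  flags_tag <- mat5_read_tag(rd)
  flags <- readBin(mat5_read_data(rd, flags_tag), "integer", n = 2, size = 4,
                   endian = "little")
  cls <- bitwAnd(flags[1], 255L)
  dims_tag <- mat5_read_tag(rd)
  dims <- readBin(mat5_read_data(rd, dims_tag), "integer",
                  n = dims_tag$nbytes / 4, size = 4, endian = "little")
  name_tag <- mat5_read_tag(rd)
  name <- rawToChar(mat5_read_data(rd, name_tag))
  if (cls == MX_STRUCT) {
    len_tag <- mat5_read_tag(rd)
    mat5_read_data(rd, len_tag) # field name length (fixed stride, unused)
    fn_tag <- mat5_read_tag(rd)
    fn_raw <- mat5_read_data(rd, fn_tag)
    stride <- 32L
    nfield <- length(fn_raw) / stride
    fields <- vapply(seq_len(nfield), function(i) {
      b <- fn_raw[((i - 1) * stride + 1):(i * stride)]
      rawToChar(b[b != as.raw(0)])
    }, character(1))
    n_elem <- prod(dims)
    elems <- vector("list", n_elem)
    for (e in seq_len(n_elem)) {
      el <- stats::setNames(vector("list", nfield), fields)
      for (f in fields) {
        sub_tag <- mat5_read_tag(rd)
        if (sub_tag$type != MI_MATRIX) {
          stop_assrmix("Malformed struct field (expected miMATRIX).")
        }
        end <- rd$pos + sub_tag$nbytes
        el[[f]] <- if (sub_tag$nbytes == 0) numeric(0) else
          mat5_read_matrix(rd)$value
        rd$pos <- end
      }
      elems[[e]] <- el
    }
    value <- if (n_elem == 1) elems[[1]] else elems
    return(list(name = name, value = value))
  }
  data_tag <- mat5_read_tag(rd)
  vals <- mat5_decode_numeric(mat5_read_data(rd, data_tag), data_tag$type)
  if (cls == MX_CHAR) {
    value <- intToUtf8(vals[vals > 0])
  } else {
    value <- as.numeric(vals)
    if (length(dims) == 2 && all(dims > 1)) {
      value <- matrix(value, dims[1], dims[2])
    }
  }
  list(name = name, value = value)
}

# read all top-level variables of a MAT5 file into a named list
mat5_read <- function(path) {
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw_all) < 128) stop_assrmix("File too short to be a MAT5 file.")
  magic <- readBin(raw_all[125:126], "integer", size = 2, endian = "little")
  if (magic != 256L) {
    stop_assrmix("Not a little-endian MAT 5.0 file (version field mismatch).")
  }
  rd <- mat5_reader(raw_all)
  rd$pos <- 129L
  out <- list()
  while (rd$pos <= length(raw_all) - 8L) {
    tag <- mat5_read_tag(rd)
    if (tag$type == MI_COMPRESSED) {
      sub <- memDecompress(mat5_read_data(rd, tag), type = "gzip")
      sub_rd <- mat5_reader(sub)
      stag <- mat5_read_tag(sub_rd)
      if (stag$type != MI_MATRIX) next
      m <- mat5_read_matrix(sub_rd)
    } else if (tag$type == MI_MATRIX) {
      end <- rd$pos + tag$nbytes + (8L - tag$nbytes %% 8L) %% 8L
      m <- mat5_read_matrix(rd)
      rd$pos <- end
    } else {
      mat5_read_data(rd, tag)
      next
    }
    out[[m$name]] <- m$value
  }
  out
}
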