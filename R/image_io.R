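# Minimal grey-image codecs (baseline TIFF, PGM).
#
# The package must run in offline environments where no image-I/O package is
# guaranteed, so it carries its own reader/writer for the two plain formats
# it needs: uncompressed single-channel baseline TIFF (8/16-bit, either byte
# order on read, little-endian on write) and PGM (P2/P5). Compressed,
# tiled, multi-channel or planar TIFFs are rejected with clear errors.

u16le <- function(x) as.raw(c(x %% 256L, x %/% 256L))
u32le <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
}

rd_uint <- function(raw, offset, size, big_endian) {
  # offset is 0-based; returns numeric scalar
  b <- as.integer(raw[(offset + 1L):(offset + size)])
  if (big_endian) b <- rev(b)
  sum(b * 256^(seq_along(b) - 1L))
}

pix_to_raw <- function(pixels, bit_depth, big_endian = FALSE) {
  v <- as.integer(t(pixels))  # row-major
  if (bit_depth == 8L) return(as.raw(v))
  lo <- as.raw(v %% 256L)
  hi <- as.raw(v %/% 256L)
  out <- raw(2L * length(v))
  if (big_endian) {
    out[c(TRUE, FALSE)] <- hi
    out[c(FALSE, TRUE)] <- lo
  } else {
    out[c(TRUE, FALSE)] <- lo
    out[c(FALSE, TRUE)] <- hi
  }
  out
}

raw_to_pix <- function(bytes, nr, nc, bit_depth, big_endian = FALSE) {
  if (bit_depth == 8L) {
    v <- as.integer(bytes)
  } else {
    a <- as.integer(bytes[c(TRUE, FALSE)])
    b <- as.integer(bytes[c(FALSE, TRUE)])
    v <- if (big_endian) a * 256L + b else b * 256L + a
  }
  matrix(v, nrow = nr, ncol = nc, byrow = TRUE)
}

write_tiff_grey <- function(pixels, path, bit_depth = 8L) {
  stopifnot(is.matrix(pixels), bit_depth %in% c(8L, 16L))
  nr <- nrow(pixels); nc <- ncol(pixels)
  data <- pix_to_raw(pixels, bit_depth)
  nbytes <- length(data)
  if (nbytes %% 2L == 1L) data <- c(data, as.raw(0L))  # word-align the IFD
  ifd_off <- 8L + length(data)
  entry <- function(tag, type, value) {
    val <- if (type == 3L) c(u16le(value), as.raw(c(0L, 0L))) else u32le(value)
    c(u16le(tag), u16le(type), u32le(1L), val)
  }
  entries <- c(
    entry(256L, 4L, nc),          # ImageWidth
    entry(257L, 4L, nr),          # ImageLength
    entry(258L, 3L, bit_depth),   # BitsPerSample
    entry(259L, 3L, 1L),          # Compression: none
    entry(262L, 3L, 1L),          # Photometric: BlackIsZero
    entry(273L, 4L, 8L),          # StripOffsets
    entry(277L, 3L, 1L),          # SamplesPerPixel
    entry(278L, 4L, nr),          # RowsPerStrip
    entry(279L, 4L, nbytes)       # StripByteCounts
  )
  out <- c(as.raw(c(0x49L, 0x49L)), u16le(42L), u32le(ifd_off),
           data, u16le(9L), entries, u32le(0L))
  writeBin(out, path)
  invisible(path)
}

tiff_type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L)

read_tiff_grey <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8L) stop("not a TIFF file: ", path)
  order_tag <- rawToChar(raw[1:2])
  big <- order_tag == "MM"
  if (!big && order_tag != "II") stop("not a TIFF file: ", path)
  if (rd_uint(raw, 2L, 2L, big) != 42) stop("not a TIFF file: ", path)
  ifd <- rd_uint(raw, 4L, 4L, big)
  n_entries <- rd_uint(raw, ifd, 2L, big)
  tags <- list()
  for (e in seq_len(n_entries)) {
    off <- ifd + 2L + (e - 1L) * 12L
    tag <- rd_uint(raw, off, 2L, big)
    type <- rd_uint(raw, off + 2L, 2L, big)
    count <- rd_uint(raw, off + 4L, 4L, big)
    size <- tiff_type_size[as.character(type)]
    if (is.na(size)) next
    total <- size * count
    voff <- if (total <= 4) off + 8L else rd_uint(raw, off + 8L, 4L, big)
    if (type %in% c(1L, 3L, 4L)) {
      vals <- vapply(seq_len(count) - 1L,
                     function(i) rd_uint(raw, voff + i * size, size, big),
                     numeric(1))
      tags[[as.character(tag)]] <- vals
    }
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) stop("TIFF tag ", tag, " missing in ", path)
      default
    } else v
  }
  nc <- need(256L); nr <- need(257L)
  bits <- need(258L, 8)
  if (need(259L, 1) != 1) stop("compressed TIFF not supported: ", path)
  photo <- need(262L, 1)
  if (!photo %in% c(0, 1)) stop("only single-channel grey TIFF supported: ", path)
  if (any(need(277L, 1) != 1) || length(bits) != 1L)
    stop("only single-channel grey TIFF supported: ", path)
  if (!bits %in% c(8, 16)) stop("unsupported bit depth ", bits, " in ", path)
  offsets <- need(273L)
  counts <- need(279L)
  bytes <- raw(0L)
  for (s in seq_along(offsets)) {
    bytes <- c(bytes, raw[(offsets[s] + 1L):(offsets[s] + counts[s])])
  }
  want <- nr * nc * (bits / 8)
  if (length(bytes) < want) stop("truncated TIFF pixel data in ", path)
  pix <- raw_to_pix(bytes[seq_len(want)], nr, nc, as.integer(bits), big)
  if (photo == 0) pix <- (2^bits - 1) - pix  # WhiteIsZero
  list(pixels = pix, bit_depth = as.integer(bits))
}

write_pgm <- function(pixels, path, bit_depth = 8L) {
  stopifnot(is.matrix(pixels), bit_depth %in% c(8L, 16L))
  maxval <- as.integer(2^bit_depth - 1)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(sprintf("P5\n%d %d\n%d\n", ncol(pixels), nrow(pixels), maxval)), con)
  writeBin(pix_to_raw(pixels, bit_depth, big_endian = TRUE), con)  # PGM >8 bit is big-endian
  invisible(path)
}

read_pgm <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  magic <- rawToChar(raw[1:2])
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path)
  # header: magic, width, height, maxval; '#' comments allowed. Parsed over
  # raw bytes (the binary payload may contain nul bytes).
  ints <- as.integer(raw)
  is_digit <- ints >= 48L & ints <= 57L
  pos <- 3L
  toks <- integer(0)
  n <- length(raw)
  while (length(toks) < 3L && pos <= n) {
    if (ints[pos] == 35L) {  # '#'
      while (pos <= n && ints[pos] != 10L) pos <- pos + 1L
    } else if (is_digit[pos]) {
      start <- pos
      while (pos <= n && is_digit[pos]) pos <- pos + 1L
      toks <- c(toks, as.integer(rawToChar(raw[start:(pos - 1L)])))
      next
    }
    pos <- pos + 1L
  }
  nc <- toks[1]; nr <- toks[2]; maxval <- toks[3]
  bit_depth <- if (maxval > 255) 16L else 8L
  if (magic == "P2") {
    vals <- as.integer(strsplit(trimws(rawToChar(raw[pos:n])), "\\s+")[[1]])
    pix <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  } else {
    bytes <- raw[(pos + 1L):length(raw)]  # skip the single whitespace after maxval
    want <- nr * nc * (bit_depth / 8)
    pix <- raw_to_pix(bytes[seq_len(want)], nr, nc, bit_depth, big_endian = TRUE)
  }
  list(pixels = pix, bit_depth = bit_depth)
}

#' Read a single grey slice image
#'
#' Supports uncompressed single-channel baseline TIFF (8/16-bit) and PGM
#' (P2/P5). Other formats are rejected: decoding JPEG/PNG/BMP would need an
#' external codec that cannot be assumed present.
#'
#' @param path path to the image file.
#' @return list with `pixels` (integer matrix, rows = image rows) and
#'   `bit_depth` (8 or 16).
#' @export
read_slice_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  out <- switch(ext,
    tif = , tiff = read_tiff_grey(path),
    pgm = read_pgm(path),
    stop("unsupported image format '.", ext, "' for ", path,
         " (supported: TIFF, PGM)")
  )
  out
}

#' Write a single grey slice image
#'
#' @param pixels integer matrix of grey values.
#' @param path output path; format chosen from extension (.tif/.tiff/.pgm).
#' @param bit_depth 8 or 16.
#' @return the path, invisibly.
#' @export
write_slice_image <- function(pixels, path, bit_depth = 8L) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = write_tiff_grey(pixels, path, bit_depth),
    pgm = write_pgm(pixels, path, bit_depth),
    stop("unsupported image format '.", ext, "'")
  )
  invisible(path)
}
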