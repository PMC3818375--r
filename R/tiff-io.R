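# Minimal baseline TIFF codec: little-endian, uncompressed, single-channel
# grayscale, 8 or 16 bits per sample, multi-page. This covers the microCT
# stack interchange contract (no compression, no tiling, no predictors); it is
# not a general-purpose TIFF implementation.

TIFF_TAG <- list(width = 256L, height = 257L, bits = 258L, compression = 259L,
                 photometric = 262L, strip_offsets = 273L, samples = 277L,
                 rows_per_strip = 278L, strip_bytes = 279L)

# pages: list of integer matrices (first index = image column x, second = row y;
# pixel (x, y) is sample x of row y, matching R's column-major layout).
write_tiff_pages <- function(pages, path, bits = 8L) {
  stopifnot(bits %in% c(8L, 16L))
  maxval <- 2^bits - 1
  for (p in pages) {
    if (!is.matrix(p)) stop("each page must be a matrix")
    if (any(p < 0 | p > maxval)) stop(sprintf("pixel values out of %d-bit range", bits))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")

  writeBin(charToRaw("II"), con); w2(42L); # header; IFD0 offset patched below
  ifd0_pos <- 4L
  w4(0L)

  offset <- 8L
  n_entries <- 9L
  ifd_size <- 2L + n_entries * 12L + 4L

  for (k in seq_along(pages)) {
    page <- pages[[k]]
    nxp <- nrow(page); nyp <- ncol(page)
    nbytes <- nxp * nyp * (bits %/% 8L)
    data_off <- offset
    # pixel data
    vals <- as.integer(page) # x fastest, then y == row-major rows of y
    if (bits == 8L) {
      writeBin(as.raw(vals), con)
    } else {
      lo <- vals %% 256L; hi <- vals %/% 256L
      writeBin(as.raw(as.vector(rbind(lo, hi))), con)
    }
    ifd_off <- data_off + nbytes
    # patch previous IFD-chain pointer
    cur <- seek(con, NA, "start")
    seek(con, ifd0_pos, "start"); w4(ifd_off); seek(con, cur, "start")

    entry <- function(tag, type, count, value) {
      w2(tag); w2(type); w4(count); w4(value)
    }
    w2(n_entries)
    entry(TIFF_TAG$width, 3L, 1L, nxp)
    entry(TIFF_TAG$height, 3L, 1L, nyp)
    entry(TIFF_TAG$bits, 3L, 1L, bits)
    entry(TIFF_TAG$compression, 3L, 1L, 1L)
    entry(TIFF_TAG$photometric, 3L, 1L, 1L)
    entry(TIFF_TAG$strip_offsets, 4L, 1L, data_off)
    entry(TIFF_TAG$samples, 3L, 1L, 1L)
    entry(TIFF_TAG$rows_per_strip, 3L, 1L, nyp)
    entry(TIFF_TAG$strip_bytes, 4L, 1L, nbytes)
    ifd0_pos <- seek(con, NA, "start") # position of the next-IFD pointer
    w4(0L)
    offset <- ifd_off + ifd_size
  }
  invisible(path)
}

read_tiff_pages <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 8L) stop("not a TIFF file: ", path)
  order <- rawToChar(raw[1:2])
  endian <- if (order == "II") "little" else if (order == "MM") "big" else
    stop("not a TIFF file: ", path)
  rd <- function(at, size, n = 1L, signed = TRUE) {
    readBin(raw[(at + 1):(at + size * n)], "integer", n = n, size = size,
            endian = endian, signed = if (size > 2L) TRUE else signed)
  }
  magic <- rd(2, 2, signed = FALSE)
  if (magic != 42L) stop("not a TIFF file: ", path)
  ifd_off <- rd(4, 4)
  pages <- list()
  while (ifd_off != 0L) {
    n_entries <- rd(ifd_off, 2, signed = FALSE)
    tags <- list()
    for (e in seq_len(n_entries)) {
      base <- ifd_off + 2L + (e - 1L) * 12L
      tag <- rd(base, 2, signed = FALSE)
      type <- rd(base + 2L, 2, signed = FALSE)
      count <- rd(base + 4L, 4)
      val <- if (type == 3L && count == 1L) rd(base + 8L, 2, signed = FALSE)
             else rd(base + 8L, 4)
      tags[[as.character(tag)]] <- list(type = type, count = count, value = val,
                                        at = base + 8L)
    }
    need <- function(tag, default = NULL) {
      t <- tags[[as.character(tag)]]
      if (is.null(t)) {
        if (is.null(default)) stop("missing required TIFF tag ", tag)
        return(default)
      }
      t$value
    }
    width <- need(TIFF_TAG$width); height <- need(TIFF_TAG$height)
    bits <- need(TIFF_TAG$bits, 8L)
    if (need(TIFF_TAG$compression, 1L) != 1L)
      stop("only uncompressed TIFF is supported")
    if (!bits %in% c(8L, 16L)) stop("only 8/16-bit grayscale TIFF is supported")
    # strip offsets/byte counts may be arrays stored out of line
    get_vec <- function(tag) {
      t <- tags[[as.character(tag)]]
      if (is.null(t)) stop("missing required TIFF tag ", tag)
      size <- if (t$type == 3L) 2L else 4L
      if (t$count * size <= 4L) {
        rd(t$at, size, t$count, signed = FALSE)[seq_len(t$count)]
      } else {
        rd(t$value, size, t$count, signed = FALSE)
      }
    }
    offs <- get_vec(TIFF_TAG$strip_offsets)
    cnts <- get_vec(TIFF_TAG$strip_bytes)
    bytes <- unlist(lapply(seq_along(offs), function(i)
      raw[(offs[i] + 1):(offs[i] + cnts[i])]))
    vals <- if (bits == 8L) {
      as.integer(bytes)
    } else {
      m <- matrix(as.integer(bytes), nrow = 2L)
      if (endian == "little") m[1, ] + 256L * m[2, ] else m[2, ] + 256L * m[1, ]
    }
    if (length(vals) != width * height) stop("corrupt TIFF strip data")
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = width, ncol = height)
    ifd_off <- rd(ifd_off + 2L + n_entries * 12L, 4)
  }
  pages
}
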