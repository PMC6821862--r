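# Minimal baseline TIFF codec: little-endian, uncompressed, single-channel
# grayscale, multi-page. Written because no TIFF package is available in the
# target environment. Supports 8/16-bit unsigned integer and 32-bit float
# pages; readers tolerate multiple strips; writers emit one strip per page.

TIFF_TAGS <- c(ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
               Compression = 259L, Photometric = 262L, StripOffsets = 273L,
               SamplesPerPixel = 277L, RowsPerStrip = 278L,
               StripByteCounts = 279L, SampleFormat = 339L)

#' Write a multi-page grayscale TIFF
#'
#' Pages are uncompressed, little-endian, one sample per pixel. `float32`
#' stores values bit-exactly; `uint16` requires values in [0, 65535] and
#' rounds; `uint8` likewise in [0, 255].
#'
#' @param pages a list of numeric matrices (equal shapes not required by the
#'   format, but required by [write_stack()]), or a 3-d array `(page, row,
#'   col)`.
#' @param path output file path.
#' @param dtype `"float32"`, `"uint16"` or `"uint8"`.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(path, pages, dtype = c("float32", "uint16", "uint8")) {
  dtype <- match.arg(dtype)
  if (is.array(pages) && length(dim(pages)) == 3) {
    d <- dim(pages)
    pages <- lapply(seq_len(d[1]), function(i) matrix(pages[i, , ], d[2], d[3]))
  }
  if (!is.list(pages) || !length(pages))
    stop_value("write_tiff needs a non-empty list of matrices")
  con <- file(path, "wb")
  on.exit(close(con))
  wb <- function(x, size) writeBin(x, con, size = size, endian = "little")
  # header: "II", magic 42, offset of first IFD (patched after data layout)
  writeChar("II", con, nchars = 2, eos = NULL)
  wb(42L, 2)
  n <- length(pages)
  bps <- switch(dtype, float32 = 32L, uint16 = 16L, uint8 = 8L)
  fmt <- if (dtype == "float32") 3L else 1L
  bytes_px <- bps %/% 8L
  sizes <- vapply(pages, function(p) length(p) * bytes_px, numeric(1))
  data_off <- 8
  offs <- data_off + cumsum(c(0, sizes[-n]))
  ifd_start <- data_off + sum(sizes)
  wb(as.integer(ifd_start), 4)
  for (p in pages) {
    v <- t(p)  # TIFF stores row-major
    if (dtype == "float32") {
      wb(as.numeric(v), 4)
    } else {
      iv <- as.integer(round(v))
      top <- 2^bps - 1
      if (any(iv < 0 | iv > top) || anyNA(iv))
        stop_value("values outside [0, %d] cannot be written as %s", top, dtype)
      if (dtype == "uint16") iv[iv > 32767L] <- iv[iv > 32767L] - 65536L
      wb(iv, bytes_px)
    }
  }
  n_entries <- 10L
  ifd_size <- 2 + 12 * n_entries + 4
  entry <- function(tag, type, count, value) {
    wb(as.integer(tag), 2); wb(as.integer(type), 2); wb(as.integer(count), 4)
    if (type == 3L) { wb(as.integer(value), 2); wb(0L, 2) } else wb(as.integer(value), 4)
  }
  for (i in seq_len(n)) {
    d <- dim(pages[[i]])
    wb(n_entries, 2)
    entry(TIFF_TAGS["ImageWidth"], 4L, 1L, d[2])
    entry(TIFF_TAGS["ImageLength"], 4L, 1L, d[1])
    entry(TIFF_TAGS["BitsPerSample"], 3L, 1L, bps)
    entry(TIFF_TAGS["Compression"], 3L, 1L, 1L)
    entry(TIFF_TAGS["Photometric"], 3L, 1L, 1L)
    entry(TIFF_TAGS["StripOffsets"], 4L, 1L, offs[i])
    entry(TIFF_TAGS["SamplesPerPixel"], 3L, 1L, 1L)
    entry(TIFF_TAGS["RowsPerStrip"], 4L, 1L, d[1])
    entry(TIFF_TAGS["StripByteCounts"], 4L, 1L, sizes[i])
    entry(TIFF_TAGS["SampleFormat"], 3L, 1L, fmt)
    next_off <- if (i < n) ifd_start + i * ifd_size else 0
    wb(as.integer(next_off), 4)
  }
  invisible(path)
}

#' Read a multi-page grayscale TIFF
#'
#' Supports the baseline subset this package writes (uncompressed grayscale,
#' 8/16-bit unsigned or 32-bit float, little- or big-endian, strips).
#'
#' @param path TIFF file path.
#' @return a list of numeric matrices, one per page.
#' @export
read_tiff <- function(path) {
  if (!file.exists(path)) stop_io("cannot read '%s': no such file", path)
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8) stop_format("'%s' is not a TIFF (too short)", path)
  endian <- if (rawToChar(raw[1:2]) == "II") "little"
            else if (rawToChar(raw[1:2]) == "MM") "big"
            else stop_format("'%s' is not a TIFF (bad byte-order mark)", path)
  rd <- function(off, what, size, n = 1, signed = TRUE)
    readBin(raw[(off + 1):(off + n * size)], what, n = n, size = size,
            endian = endian, signed = signed)
  if (rd(2, "integer", 2) != 42L) stop_format("'%s' is not a TIFF (bad magic)", path)
  ifd_off <- rd(4, "integer", 4)
  pages <- list()
  while (ifd_off != 0) {
    n_entries <- rd(ifd_off, "integer", 2)
    tags <- list()
    for (k in seq_len(n_entries)) {
      e <- ifd_off + 2 + (k - 1) * 12
      tag <- rd(e, "integer", 2, signed = FALSE)
      type <- rd(e + 2, "integer", 2)
      count <- rd(e + 4, "integer", 4)
      val_off <- e + 8
      sz <- switch(as.character(type), `1` = 1L, `3` = 2L, `4` = 4L, NA_integer_)
      if (is.na(sz)) next  # ignore exotic tag types
      if (count * sz > 4) val_off <- rd(e + 8, "integer", 4)
      vals <- rd(val_off, "integer", sz, n = count, signed = sz == 4L)
      tags[[as.character(tag)]] <- vals
    }
    g <- function(tag, default = NULL) {
      v <- tags[[as.character(TIFF_TAGS[tag])]]
      if (is.null(v)) default else v
    }
    w <- g("ImageWidth"); h <- g("ImageLength")
    if (is.null(w) || is.null(h)) stop_format("TIFF page lacks dimensions")
    if (g("Compression", 1L)[1] != 1L)
      stop_format("compressed TIFF not supported (compression=%d)",
                  g("Compression")[1])
    bps <- g("BitsPerSample", 8L)[1]
    fmt <- g("SampleFormat", 1L)[1]
    offs <- g("StripOffsets"); cnts <- g("StripByteCounts")
    if (is.null(offs)) stop_format("TIFF page lacks strip offsets")
    if (is.null(cnts)) cnts <- rep(w * h * bps / 8 / length(offs), length(offs))
    buf <- raw(0)
    for (s in seq_along(offs))
      buf <- c(buf, raw[(offs[s] + 1):(offs[s] + cnts[s])])
    npx <- as.integer(w) * as.integer(h)
    v <- if (fmt == 3L && bps == 32L) {
      readBin(buf, "numeric", n = npx, size = 4, endian = endian)
    } else if (fmt == 1L && bps == 16L) {
      readBin(buf, "integer", n = npx, size = 2, endian = endian, signed = FALSE)
    } else if (fmt == 1L && bps == 8L) {
      as.integer(readBin(buf, "integer", n = npx, size = 1, signed = FALSE))
    } else {
      stop_format("unsupported TIFF sample layout (bits=%d, format=%d)", bps, fmt)
    }
    pages[[length(pages) + 1L]] <- matrix(as.numeric(v), nrow = h, byrow = TRUE)
    ifd_off <- rd(ifd_off + 2 + n_entries * 12, "integer", 4)
  }
  pages
}
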