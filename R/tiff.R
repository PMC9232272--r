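## Minimal multi-page TIFF codec (baseline: uncompressed, grayscale,
## single sample per pixel, 8/16-bit unsigned integer or 32-bit float).
##
## No TIFF library is part of the package's dependency footprint, so a
## small self-contained reader/writer is provided.  It covers exactly
## the container this package emits: little-endian classic TIFF, one
## strip per page, depth-major pages (rows = z).  The reader also
## accepts big-endian files and multi-strip pages produced by common
## writers (e.g. tifffile), as long as they are uncompressed grayscale.

tiff_dtypes <- c(uint8 = 1L, uint16 = 2L, float32 = 4L)

#' Write a stack of matrices as a multi-page TIFF
#'
#' @param pages list of numeric matrices (rows = depth).
#' @param path output file.
#' @param dtype `"uint8"`, `"uint16"` or `"float32"`.  Integer types
#'   require values already integral and in range (no silent clamping).
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(pages, path, dtype = c("float32", "uint8", "uint16")) {
  dtype <- match.arg(dtype)
  if (!is.list(pages) || length(pages) == 0L)
    abort_oct("`pages` must be a non-empty list of matrices", "octmoco_shape")
  bpp <- tiff_dtypes[[dtype]]
  if (dtype != "float32") {
    top <- if (dtype == "uint8") 255 else 65535
    for (p in pages) {
      if (any(p < 0 | p > top) || any(p != round(p)))
        abort_oct(sprintf("values out of range for %s", dtype), "octmoco_value")
    }
  }
  sizes <- vapply(pages, function(p) nrow(p) * ncol(p) * bpp, numeric(1))
  padded <- sizes + sizes %% 2          # word-align page data
  offs <- 8 + cumsum(c(0, padded[-length(padded)]))
  ifd0 <- 8 + sum(padded)
  n_ifd_entries <- 10L
  ifd_size <- 2L + n_ifd_entries * 12L + 4L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, nchars = 2, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(as.integer(ifd0), con, size = 4, endian = "little")
  for (i in seq_along(pages)) {
    v <- as.vector(t(pages[[i]]))       # TIFF is row-major
    if (dtype == "float32") writeBin(as.double(v), con, size = 4, endian = "little")
    else writeBin(as.integer(v), con, size = bpp, endian = "little")
    if (padded[i] != sizes[i]) writeBin(raw(1), con)
  }
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L) {                   # SHORT, left-justified in 4 bytes
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  sample_format <- if (dtype == "float32") 3L else 1L
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    writeBin(n_ifd_entries, con, size = 2, endian = "little")
    entry(256, 4, 1, ncol(p))                       # ImageWidth
    entry(257, 4, 1, nrow(p))                       # ImageLength
    entry(258, 3, 1, bpp * 8L)                      # BitsPerSample
    entry(259, 3, 1, 1)                             # Compression: none
    entry(262, 3, 1, 1)                             # Photometric: BlackIsZero
    entry(273, 4, 1, offs[i])                       # StripOffsets
    entry(277, 3, 1, 1)                             # SamplesPerPixel
    entry(278, 4, 1, nrow(p))                       # RowsPerStrip
    entry(279, 4, 1, sizes[i])                      # StripByteCounts
    entry(339, 3, 1, sample_format)                 # SampleFormat
    nxt <- if (i < length(pages)) ifd0 + i * ifd_size else 0L
    writeBin(as.integer(nxt), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a multi-page grayscale TIFF
#'
#' @param path TIFF file.
#' @return list with `pages` (list of numeric matrices) and `dtype`.
#' @export
read_tiff_stack <- function(path) {
  if (!file.exists(path)) abort_oct(paste("no such file:", path), "octmoco_io")
  raw_all <- readBin(path, "raw", file.info(path)$size)
  if (length(raw_all) < 8L) abort_oct("not a TIFF file (truncated)", "octmoco_format")
  head2 <- rawToChar(raw_all[1:2])
  endian <- if (head2 == "II") "little" else if (head2 == "MM") "big"
            else abort_oct("not a TIFF file (bad byte-order mark)", "octmoco_format")
  rint <- function(at, size) {
    # sizes 1-2 read unsigned; size 4 must read signed (R limitation),
    # fine for the < 2 GiB offsets this codec produces
    readBin(raw_all[at:(at + size - 1L)], "integer", n = 1L, size = size,
            signed = size >= 4L, endian = endian)
  }
  rints <- function(at, size, n) {
    readBin(raw_all[at:(at + size * n - 1L)], "integer", n = n, size = size,
            signed = size >= 4L, endian = endian)
  }
  if (rint(3L, 2L) != 42L) abort_oct("not a classic TIFF (bad magic)", "octmoco_format")
  ifd_off <- rint(5L, 4L)
  pages <- list()
  dtype <- NULL
  while (ifd_off != 0L) {
    n <- rint(ifd_off + 1L, 2L)
    tags <- list()
    for (k in seq_len(n)) {
      at <- ifd_off + 3L + (k - 1L) * 12L
      tag <- rint(at, 2L)
      type <- rint(at + 2L, 2L)
      cnt <- rint(at + 4L, 4L)
      tsize <- c(1L, 1L, 2L, 4L, 8L, 1L, 1L, 2L, 4L, 8L, 4L, 8L)[type]
      vat <- if (tsize * cnt <= 4L) at + 8L else rint(at + 8L, 4L) + 1L
      val <- if (type %in% c(3L, 4L)) rints(vat, tsize, cnt) else NA
      tags[[as.character(tag)]] <- val
    }
    g <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) default else v
    }
    wd <- g(256); ht <- g(257)
    if (is.null(wd) || is.null(ht)) abort_oct("TIFF page missing dimensions", "octmoco_format")
    if (g(259, 1L)[1] != 1L) abort_oct("compressed TIFF not supported", "octmoco_format")
    if (g(277, 1L)[1] != 1L) abort_oct("multi-sample TIFF not supported", "octmoco_format")
    bits <- g(258, 1L)[1]
    sfmt <- g(339, 1L)[1]
    this_dtype <- if (sfmt == 3L && bits == 32L) "float32"
                  else if (sfmt == 1L && bits == 8L) "uint8"
                  else if (sfmt == 1L && bits == 16L) "uint16"
                  else abort_oct(sprintf("unsupported TIFF sample type (%d bits, format %d)",
                                         bits, sfmt), "octmoco_format")
    dtype <- dtype %||% this_dtype
    strip_off <- g(273)
    strip_cnt <- g(279, wd * ht * bits %/% 8L)
    buf <- raw(0)
    for (s in seq_along(strip_off))
      buf <- c(buf, raw_all[(strip_off[s] + 1L):(strip_off[s] + strip_cnt[s])])
    npx <- wd * ht
    v <- if (this_dtype == "float32") {
      readBin(buf, "double", n = npx, size = 4L, endian = endian)
    } else {
      readBin(buf, "integer", n = npx, size = bits %/% 8L, signed = FALSE,
              endian = endian)
    }
    pages[[length(pages) + 1L]] <- matrix(v, nrow = ht, ncol = wd, byrow = TRUE)
    ifd_off <- rint(ifd_off + 3L + n * 12L, 4L)
  }
  list(pages = pages, dtype = dtype)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
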