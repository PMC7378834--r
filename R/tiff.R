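## Minimal multi-page grayscale TIFF support (little-endian, uncompressed).
## Written by hand because no TIFF package is available in the target library;
## the dialect is deliberately small: one strip per page, 32-bit float samples
## on write, 8/16/32-bit unsigned or 32-bit float on read.

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, samples = 277L,
               rows_per_strip = 278L, strip_bytes = 279L, sample_format = 339L)

#' Write a stack of matrices as a multi-page TIFF
#'
#' Pages are written uncompressed as 32-bit little-endian IEEE floats,
#' one strip per page. All pages must share one size.
#'
#' @param pages list of numeric matrices (image rows in matrix rows)
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_tiff <- function(pages, path) {
  if (is.matrix(pages)) pages <- list(pages)
  stopifnot(length(pages) >= 1L, all(vapply(pages, is.matrix, logical(1))))
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stopf("all TIFF pages must have identical dimensions")
  }
  h <- dims[1, 1]; w <- dims[2, 1]
  n <- length(pages)
  page_bytes <- h * w * 4L
  ifd_size <- 2L + 10L * 12L + 4L
  data_off <- 8L
  ifd0 <- data_off + n * page_bytes

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, nchars = 2, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd0, con, size = 4, endian = "little")
  for (p in pages) {
    writeBin(as.numeric(t(p)), con, size = 4, endian = "little")
  }
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L) { # SHORT packed into 4-byte value field
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  for (i in seq_len(n)) {
    entry_vals <- list(
      c(TIFF_TAGS[["width"]], 4L, 1L, w),
      c(TIFF_TAGS[["length"]], 4L, 1L, h),
      c(TIFF_TAGS[["bits"]], 3L, 1L, 32L),
      c(TIFF_TAGS[["compression"]], 3L, 1L, 1L),
      c(TIFF_TAGS[["photometric"]], 3L, 1L, 1L),
      c(TIFF_TAGS[["strip_offsets"]], 4L, 1L, data_off + (i - 1L) * page_bytes),
      c(TIFF_TAGS[["samples"]], 3L, 1L, 1L),
      c(TIFF_TAGS[["rows_per_strip"]], 4L, 1L, h),
      c(TIFF_TAGS[["strip_bytes"]], 4L, 1L, page_bytes),
      c(TIFF_TAGS[["sample_format"]], 3L, 1L, 3L))
    writeBin(10L, con, size = 2, endian = "little")
    for (e in entry_vals) entry(e[1], e[2], e[3], e[4])
    next_ifd <- if (i < n) ifd0 + i * ifd_size else 0L
    writeBin(as.integer(next_ifd), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a multi-page grayscale TIFF
#'
#' Supports uncompressed single-sample little- or big-endian files with
#' 8/16/32-bit unsigned integer or 32-bit float samples (the dialect written
#' by [write_tiff()] and by common scientific writers with compression off).
#'
#' @param path TIFF file path
#' @return list of numeric matrices, one per page
#' @export
read_tiff <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw_all) < 8L) stopf("not a TIFF file: %s", path)
  order_tag <- rawToChar(raw_all[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stopf("not a TIFF file: %s", path))
  rd_int <- function(off, size, n = 1L) {
    readBin(raw_all[(off + 1L):(off + size * n)], "integer",
            n = n, size = size, endian = endian, signed = size == 4L)
  }
  magic <- rd_int(2L, 2L)
  if (magic != 42L) stopf("not a TIFF file: %s", path)
  ifd_off <- rd_int(4L, 4L)
  pages <- list()
  while (ifd_off != 0L) {
    n_entries <- rd_int(ifd_off, 2L)
    tags <- list()
    for (k in seq_len(n_entries)) {
      e_off <- ifd_off + 2L + (k - 1L) * 12L
      tag <- rd_int(e_off, 2L)
      type <- rd_int(e_off + 2L, 2L)
      count <- rd_int(e_off + 4L, 4L)
      val <- if (type == 3L && count == 1L) rd_int(e_off + 8L, 2L)
             else if (count == 1L) rd_int(e_off + 8L, 4L)
             else { # value stored elsewhere
        v_off <- rd_int(e_off + 8L, 4L)
        size <- if (type == 3L) 2L else 4L
        rd_int(v_off, size, count)
      }
      tags[[as.character(tag)]] <- val
    }
    g <- function(tag, default = NULL) tags[[as.character(tag)]] %||% default
    comp <- g(TIFF_TAGS[["compression"]], 1L)
    if (comp != 1L) stopf("unsupported TIFF compression: %d", comp)
    spp <- g(TIFF_TAGS[["samples"]], 1L)
    if (spp != 1L) stopf("only single-sample (grayscale) TIFFs are supported")
    w <- g(TIFF_TAGS[["width"]]); h <- g(TIFF_TAGS[["length"]])
    bits <- g(TIFF_TAGS[["bits"]], 1L)
    fmt <- g(TIFF_TAGS[["sample_format"]], 1L)
    offs <- g(TIFF_TAGS[["strip_offsets"]])
    bytec <- g(TIFF_TAGS[["strip_bytes"]])
    if (is.null(w) || is.null(h) || is.null(offs) || is.null(bytec)) {
      stopf("malformed TIFF IFD in %s", path)
    }
    vals <- numeric(0)
    for (s in seq_along(offs)) {
      seg <- raw_all[(offs[s] + 1L):(offs[s] + bytec[s])]
      v <- if (fmt == 3L && bits == 32L) {
        readBin(seg, "numeric", n = bytec[s] / 4L, size = 4L, endian = endian)
      } else if (fmt %in% c(1L, 4L) && bits == 8L) {
        as.numeric(readBin(seg, "integer", n = bytec[s], size = 1L,
                           endian = endian, signed = FALSE))
      } else if (fmt %in% c(1L, 4L) && bits == 16L) {
        as.numeric(readBin(seg, "integer", n = bytec[s] / 2L, size = 2L,
                           endian = endian, signed = FALSE))
      } else if (fmt %in% c(1L, 4L) && bits == 32L) {
        x <- readBin(seg, "integer", n = bytec[s] / 4L, size = 4L,
                     endian = endian)
        ifelse(x < 0, x + 2^32, as.numeric(x))
      } else {
        stopf("unsupported TIFF sample layout (bits=%d, format=%d)", bits, fmt)
      }
      vals <- c(vals, v)
    }
    if (length(vals) != h * w) stopf("TIFF pixel count mismatch in %s", path)
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
    ifd_off <- rd_int(ifd_off + 2L + n_entries * 12L, 4L)
  }
  pages
}
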