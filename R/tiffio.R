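# Minimal baseline TIFF codec: uncompressed, grayscale, little-endian,
# 8- or 16-bit, multi-page.  The pre-installed R stack has no TIFF package,
# so the external-interface contract (multi-page 16-bit image stacks) is met
# with this small, fully tested implementation.  One strip per page.

#' Write matrices as a multi-page grayscale TIFF
#'
#' @param pages a numeric matrix or a list of numeric matrices (one per page).
#'   Values must already be integers in the range of the chosen bit depth.
#' @param path output file path
#' @param bits bits per sample: 8 or 16
#' @return `path`, invisibly
#' @export
write_tiff <- function(pages, path, bits = 16L) {
  if (is.matrix(pages)) pages <- list(pages)
  stopifnot(length(pages) >= 1, bits %in% c(8L, 16L))
  for (p in pages) {
    stopifnot(is.matrix(p), all(is.finite(p)), all(p >= 0),
              all(p <= 2^bits - 1))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(charToRaw("II"), con)
  w2(42L)
  n_tags <- 9L
  ifd_size <- 2L + n_tags * 12L + 4L
  offset <- 8L
  # layout per page: [pixel strip][IFD]
  strip_off <- integer(length(pages))
  ifd_off <- integer(length(pages))
  for (i in seq_along(pages)) {
    nbytes <- length(pages[[i]]) * (bits / 8L)
    strip_off[i] <- offset
    ifd_off[i] <- offset + nbytes
    offset <- offset + nbytes + ifd_size
  }
  w4(ifd_off[1])
  tag <- function(id, type, count, value) {
    w2(id); w2(type); w4(count); w4(value)
  }
  for (i in seq_along(pages)) {
    m <- pages[[i]]
    # pixel data, row-major
    v <- as.integer(t(m))
    writeBin(v, con, size = bits / 8L, endian = "little")
    w2(n_tags)
    tag(256L, 3L, 1L, ncol(m))            # ImageWidth
    tag(257L, 3L, 1L, nrow(m))            # ImageLength
    tag(258L, 3L, 1L, bits)               # BitsPerSample
    tag(259L, 3L, 1L, 1L)                 # Compression: none
    tag(262L, 3L, 1L, 1L)                 # Photometric: BlackIsZero
    tag(273L, 4L, 1L, strip_off[i])       # StripOffsets
    tag(277L, 3L, 1L, 1L)                 # SamplesPerPixel
    tag(278L, 3L, 1L, nrow(m))            # RowsPerStrip
    tag(279L, 4L, 1L, length(m) * (bits / 8L))  # StripByteCounts
    w4(if (i < length(pages)) ifd_off[i + 1] else 0L)
  }
  invisible(path)
}

#' Read a multi-page grayscale TIFF written by [write_tiff()]
#'
#' Supports uncompressed little-endian grayscale pages with a single strip
#' (or contiguous strips), 8 or 16 bits per sample.
#'
#' @param path file path
#' @return list of numeric matrices, one per page
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  u16 <- function(off) {
    sum(as.integer(raw[off + 1:2]) * c(1, 256))
  }
  u32 <- function(off) {
    sum(as.numeric(raw[off + 1:4]) * c(1, 256, 65536, 16777216))
  }
  if (rawToChar(raw[1:2]) != "II" || u16(2) != 42) {
    stop("not a little-endian TIFF file")
  }
  ifd <- u32(4)
  pages <- list()
  while (ifd != 0) {
    n <- u16(ifd)
    tags <- list()
    for (i in seq_len(n)) {
      off <- ifd + 2 + (i - 1) * 12
      id <- u16(off); type <- u16(off + 2); count <- u32(off + 4)
      val <- if (type == 3L && count == 1L) u16(off + 8) else u32(off + 8)
      tags[[as.character(id)]] <- list(type = type, count = count, val = val,
                                       off = off + 8)
    }
    W <- tags[["256"]]$val; H <- tags[["257"]]$val
    bits <- if (!is.null(tags[["258"]])) tags[["258"]]$val else 1L
    comp <- if (!is.null(tags[["259"]])) tags[["259"]]$val else 1L
    if (comp != 1L) stop("compressed TIFF not supported")
    if (!bits %in% c(8L, 16L)) stop("only 8/16-bit grayscale supported")
    so <- tags[["273"]]
    strip_offs <- if (so$count == 1L) so$val else {
      vapply(seq_len(so$count) - 1L, function(k) u32(so$val + 4 * k), 0)
    }
    npix <- H * W
    bytes <- raw(0)
    sbc <- tags[["279"]]
    sbc_vals <- if (sbc$count == 1L) sbc$val else {
      vapply(seq_len(sbc$count) - 1L, function(k) u32(sbc$val + 4 * k), 0)
    }
    for (k in seq_along(strip_offs)) {
      bytes <- c(bytes, raw[(strip_offs[k] + 1):(strip_offs[k] + sbc_vals[k])])
    }
    v <- readBin(bytes, "integer", n = npix, size = bits / 8L,
                 signed = FALSE, endian = "little")
    pages[[length(pages) + 1]] <- matrix(v, H, W, byrow = TRUE)
    ifd <- u32(ifd + 2 + n * 12)
  }
  pages
}
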