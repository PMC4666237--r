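# Minimal baseline TIFF codec: uncompressed 8-bit grayscale (write) and
# uncompressed 8-bit grayscale or RGB in either byte order (read).

tiff_write <- function(pixels, path) {
  h <- nrow(pixels); w <- ncol(pixels)
  data <- as.raw(as.integer(t(pixels)))  # row-major strip
  # layout: header(8) | IFD | pixel data
  n_tags <- 9L
  ifd_len <- 2L + n_tags * 12L + 4L
  data_off <- 8L + ifd_len
  u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")
  tag <- function(id, type, count, value) {
    val <- if (type == 3L) c(u16(value), u16(0L)) else u32(value)
    c(u16(id), u16(type), u32(count), val)
  }
  ifd <- c(u16(n_tags),
           tag(256L, 4L, 1L, w),        # ImageWidth
           tag(257L, 4L, 1L, h),        # ImageLength
           tag(258L, 3L, 1L, 8L),       # BitsPerSample
           tag(259L, 3L, 1L, 1L),       # Compression: none
           tag(262L, 3L, 1L, 1L),       # Photometric: BlackIsZero
           tag(273L, 4L, 1L, data_off), # StripOffsets
           tag(277L, 3L, 1L, 1L),       # SamplesPerPixel
           tag(278L, 4L, 1L, h),        # RowsPerStrip
           tag(279L, 4L, 1L, length(data)),  # StripByteCounts
           u32(0L))                     # next IFD: none
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), u16(42L), u32(8L), ifd, data), con)
  invisible(path)
}

tiff_read <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz)) stop(sprintf("cannot read '%s'", path), call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  raw_all <- readBin(con, "raw", n = sz)
  order_tag <- rawToChar(raw_all[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stop(sprintf("'%s' is not a TIFF file", path), call. = FALSE))
  rd_int <- function(off, size, n = 1L) {
    readBin(raw_all[(off + 1L):(off + size * n)], "integer", n = n,
            size = size, endian = endian, signed = size == 4L)
  }
  if (rd_int(2L, 2L) != 42L)
    stop(sprintf("'%s' is not a TIFF file", path), call. = FALSE)
  ifd_off <- readBin(raw_all[5:8], "integer", size = 4L, endian = endian)
  n_tags <- rd_int(ifd_off, 2L)
  tags <- list()
  type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L)
  for (i in seq_len(n_tags)) {
    off <- ifd_off + 2L + (i - 1L) * 12L
    id <- rd_int(off, 2L); type <- rd_int(off + 2L, 2L)
    count <- rd_int(off + 4L, 4L)
    tsz <- type_size[as.character(type)]
    vals <- if (!is.na(tsz) && tsz * count <= 4L) {
      rd_int(off + 8L, tsz, count)
    } else if (!is.na(tsz)) {
      voff <- rd_int(off + 8L, 4L)
      rd_int(voff, tsz, count)
    } else NULL
    tags[[as.character(id)]] <- vals
  }
  need <- function(id, default = NULL) {
    v <- tags[[as.character(id)]]
    if (is.null(v)) {
      if (!is.null(default)) return(default)
      stop(sprintf("TIFF tag %d missing in '%s'", id, path), call. = FALSE)
    }
    v
  }
  w <- need(256L); h <- need(257L)
  bits <- need(258L, 8L); comp <- need(259L, 1L)
  spp <- need(277L, 1L)
  if (comp != 1L) stop("only uncompressed TIFF is supported", call. = FALSE)
  if (any(bits != 8L)) stop("only 8-bit TIFF is supported", call. = FALSE)
  offsets <- need(273L); counts <- need(279L)
  bytes <- unlist(lapply(seq_along(offsets), function(k) {
    as.integer(raw_all[(offsets[k] + 1L):(offsets[k] + counts[k])])
  }))
  if (spp == 1L) {
    return(list(pixels = t(matrix(bytes, w, h)), channels = 1L))
  }
  arr <- array(0L, dim = c(h, w, spp))
  for (ch in seq_len(spp)) {
    arr[, , ch] <- t(matrix(bytes[seq(ch, length(bytes), by = spp)], w, h))
  }
  list(pixels = arr, channels = spp)
}
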