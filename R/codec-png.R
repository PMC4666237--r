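# Minimal pure-R PNG codec.
#
# No binary image-I/O package is assumed to be available, so the subset of
# PNG needed here is implemented directly: reading of non-interlaced 8-bit
# images (gray, gray+alpha, RGB, RGBA) and 16-bit grayscale, and writing of
# 8-bit and 16-bit grayscale. base::memCompress(type = "gzip") emits a
# zlib-format stream (0x78 header) and memDecompress accepts one, which is
# exactly the IDAT payload format.

PNG_SIGNATURE <- as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))

crc32_env <- new.env(parent = emptyenv())

crc32_table <- function() {
  if (!is.null(crc32_env$table)) return(crc32_env$table)
  tab <- integer(256)
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L)
        bitwXor(-306674912L, bitwShiftR(c, 1))  # 0xEDB88320 as signed int
      else bitwShiftR(c, 1)
    }
    tab[n + 1L] <- c
  }
  crc32_env$table <- tab
  tab
}

crc32 <- function(bytes) {
  tab <- crc32_table()
  crc <- -1L  # 0xFFFFFFFF
  b <- as.integer(bytes)
  for (i in seq_along(b)) {
    crc <- bitwXor(tab[bitwAnd(bitwXor(crc, b[i]), 255L) + 1L],
                   bitwShiftR(crc, 8))
  }
  bitwNot(crc)
}

u32_be <- function(x) {
  # encode a (possibly negative, i.e. high-bit) 32-bit integer big-endian
  writeBin(as.integer(x), raw(), size = 4L, endian = "big")
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32_be(length(data)), body, u32_be(crc32(body)))
}

# pixels: integer matrix (rows x cols); bit_depth 8 or 16 (grayscale only)
png_write <- function(pixels, path, bit_depth = 8L) {
  stopifnot(bit_depth %in% c(8L, 16L))
  h <- nrow(pixels); w <- ncol(pixels)
  ihdr <- c(u32_be(w), u32_be(h),
            as.raw(c(bit_depth, 0L, 0L, 0L, 0L)))
  rowmajor <- as.integer(t(pixels))
  if (bit_depth == 8L) {
    scan <- matrix(as.raw(rowmajor), nrow = w, ncol = h)
  } else {
    hi <- rowmajor %/% 256L; lo <- rowmajor %% 256L
    inter <- as.raw(rbind(hi, lo))  # big-endian sample order
    scan <- matrix(inter, nrow = 2L * w, ncol = h)
  }
  filtered <- rbind(matrix(as.raw(0L), 1L, h), scan)  # filter byte 0 per row
  idat <- memCompress(as.raw(filtered), type = "gzip")
  out <- c(PNG_SIGNATURE,
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", idat),
           png_chunk("IEND", raw(0)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(out, con)
  invisible(path)
}

png_defilter <- function(bytes, h, w, bpp) {
  stride <- w * bpp
  out <- matrix(0L, nrow = stride, ncol = h)
  prev <- rep(0L, stride)
  pos <- 1L
  for (r in seq_len(h)) {
    f <- as.integer(bytes[pos])
    cur <- as.integer(bytes[pos + seq_len(stride)])
    pos <- pos + stride + 1L
    recon <- switch(as.character(f),
      "0" = cur,
      "1" = {
        m <- matrix(cur, nrow = bpp)
        as.integer(matrixStats_cumsum_mod(m))
      },
      "2" = (cur + prev) %% 256L,
      "3" = {
        recon <- integer(stride)
        for (i in seq_len(stride)) {
          a <- if (i > bpp) recon[i - bpp] else 0L
          recon[i] <- (cur[i] + (a + prev[i]) %/% 2L) %% 256L
        }
        recon
      },
      "4" = {
        recon <- integer(stride)
        for (i in seq_len(stride)) {
          a <- if (i > bpp) recon[i - bpp] else 0L
          b <- prev[i]
          cc <- if (i > bpp) prev[i - bpp] else 0L
          p <- a + b - cc
          pa <- abs(p - a); pb <- abs(p - b); pc <- abs(p - cc)
          pr <- if (pa <= pb && pa <= pc) a else if (pb <= pc) b else cc
          recon[i] <- (cur[i] + pr) %% 256L
        }
        recon
      },
      stop(sprintf("unsupported PNG filter type %d", f), call. = FALSE)
    )
    out[, r] <- recon
    prev <- recon
  }
  out
}

# column-wise cumulative sum mod 256 of a bpp x n matrix, flattened back in
# byte order (channel-interleaved)
matrixStats_cumsum_mod <- function(m) {
  for (i in seq_len(nrow(m))) m[i, ] <- cumsum(m[i, ]) %% 256L
  as.integer(m)
}

# returns list(pixels, bit_depth, channels); pixels is an integer matrix for
# grayscale or a [h, w, channels] array for colour
png_read <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz)) stop(sprintf("cannot read '%s'", path), call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  raw_all <- readBin(con, "raw", n = sz)
  if (length(raw_all) < 8L || !identical(raw_all[1:8], PNG_SIGNATURE))
    stop(sprintf("'%s' is not a PNG file", path), call. = FALSE)
  pos <- 9L
  idat <- list()
  ihdr <- NULL
  while (pos + 7L <= length(raw_all)) {
    len <- sum(as.integer(raw_all[pos:(pos + 3L)]) * c(16777216, 65536, 256, 1))
    type <- rawToChar(raw_all[(pos + 4L):(pos + 7L)])
    data <- if (len > 0L) raw_all[(pos + 8L):(pos + 7L + len)] else raw(0)
    pos <- pos + 12L + len  # skip CRC, not verified
    if (type == "IHDR") ihdr <- data
    else if (type == "IDAT") idat[[length(idat) + 1L]] <- data
    else if (type == "IEND") break
  }
  if (is.null(ihdr)) stop(sprintf("'%s': missing IHDR", path), call. = FALSE)
  w <- sum(as.integer(ihdr[1:4]) * c(16777216, 65536, 256, 1))
  h <- sum(as.integer(ihdr[5:8]) * c(16777216, 65536, 256, 1))
  depth <- as.integer(ihdr[9]); ctype <- as.integer(ihdr[10])
  interlace <- as.integer(ihdr[13])
  if (interlace != 0L)
    stop("interlaced PNG is not supported", call. = FALSE)
  channels <- switch(as.character(ctype), "0" = 1L, "2" = 3L, "4" = 2L,
                     "6" = 4L, stop("unsupported PNG colour type", call. = FALSE))
  if (!(depth == 8L || (depth == 16L && ctype == 0L)))
    stop("only 8-bit PNG (any colour type) or 16-bit grayscale supported",
         call. = FALSE)
  samp_bytes <- depth %/% 8L
  bpp <- channels * samp_bytes
  bytes <- memDecompress(do.call(c, idat), type = "gzip")
  mat <- png_defilter(bytes, h, w, bpp)  # (w*bpp) x h, column = image row
  if (depth == 16L) {
    v <- as.integer(mat)
    hi <- v[seq(1L, length(v), by = 2L)]; lo <- v[seq(2L, length(v), by = 2L)]
    px <- matrix(hi * 256L + lo, nrow = w, ncol = h)
    return(list(pixels = t(px), bit_depth = 16L, channels = 1L))
  }
  if (channels == 1L) {
    return(list(pixels = t(matrix(as.integer(mat), w, h)), bit_depth = 8L,
                channels = 1L))
  }
  arr <- array(0L, dim = c(h, w, channels))
  for (ch in seq_len(channels)) {
    idx <- seq(ch, w * bpp, by = bpp)
    arr[, , ch] <- t(matrix(as.integer(mat[idx, , drop = FALSE]), w, h))
  }
  list(pixels = arr, bit_depth = 8L, channels = channels)
}
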