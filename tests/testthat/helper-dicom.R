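# Minimal DICOM writer used only to build test fixtures (synthetic files,
# explicit or implicit VR little endian, single frame).

write_test_dicom <- function(path, pixels, bits = 16L,
                             photometric = "MONOCHROME2",
                             implicit = FALSE) {
  u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")
  pad_even <- function(s) {
    r <- charToRaw(s)
    if (length(r) %% 2L == 1L) r <- c(r, as.raw(0L))
    r
  }
  explicit_elem <- function(group, elem, vr, body) {
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      c(u16(group), u16(elem), charToRaw(vr), as.raw(c(0L, 0L)),
        u32(length(body)), body)
    } else {
      c(u16(group), u16(elem), charToRaw(vr), u16(length(body)), body)
    }
  }
  implicit_elem <- function(group, elem, vr, body) {
    c(u16(group), u16(elem), u32(length(body)), body)
  }
  ts <- if (implicit) "1.2.840.10008.1.2" else "1.2.840.10008.1.2.1"
  meta <- c(
    explicit_elem(0x0002L, 0x0010L, "UI", pad_even(ts))
  )
  meta <- c(explicit_elem(0x0002L, 0x0000L, "UL", u32(length(meta))), meta)
  el <- if (implicit) implicit_elem else explicit_elem
  rows <- nrow(pixels); cols <- ncol(pixels)
  size <- bits %/% 8L
  pixel_bytes <- writeBin(as.integer(t(pixels)), raw(), size = size,
                          endian = "little")
  vr_pix <- if (size == 1L) "OB" else "OW"
  body <- c(
    el(0x0028L, 0x0002L, "US", u16(1L)),
    el(0x0028L, 0x0004L, "CS", pad_even(photometric)),
    el(0x0028L, 0x0010L, "US", u16(rows)),
    el(0x0028L, 0x0011L, "US", u16(cols)),
    el(0x0028L, 0x0100L, "US", u16(bits)),
    el(0x0028L, 0x0101L, "US", u16(bits)),
    el(0x0028L, 0x0102L, "US", u16(bits - 1L)),
    el(0x0028L, 0x0103L, "US", u16(0L)),
    el(0x7fe0L, 0x0010L, vr_pix, pixel_bytes)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128L), charToRaw("DICM"), meta, body), con)
  invisible(path)
}

write_multiframe_dicom <- function(path, pixels, n_frames = 2L) {
  u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")
  pad_even <- function(s) {
    r <- charToRaw(s)
    if (length(r) %% 2L == 1L) r <- c(r, as.raw(0L))
    r
  }
  elem <- function(group, elem, vr, body) {
    c(u16(group), u16(elem), charToRaw(vr), u16(length(body)), body)
  }
  meta <- elem(0x0002L, 0x0010L, "UI", pad_even("1.2.840.10008.1.2.1"))
  meta <- c(elem(0x0002L, 0x0000L, "UL", u32(length(meta))), meta)
  pixel_bytes <- rep(writeBin(as.integer(t(pixels)), raw(), size = 2L,
                              endian = "little"), n_frames)
  body <- c(
    elem(0x0028L, 0x0008L, "IS", pad_even(as.character(n_frames))),
    elem(0x0028L, 0x0010L, "US", u16(nrow(pixels))),
    elem(0x0028L, 0x0011L, "US", u16(ncol(pixels))),
    elem(0x0028L, 0x0100L, "US", u16(16L)),
    elem(0x0028L, 0x0103L, "US", u16(0L)),
    c(u16(0x7fe0L), u16(0x0010L), charToRaw("OW"), as.raw(c(0L, 0L)),
      u32(length(pixel_bytes)), pixel_bytes)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128L), charToRaw("DICM"), meta, body), con)
  invisible(path)
}
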