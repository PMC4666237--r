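# Read-only single-frame DICOM support (Part-10 files, explicit or implicit
# VR little endian, MONOCHROME1/2). Raw stored pixel values are returned;
# conversion to 8-bit happens in read_image().

# decode a DICOM string value: drop NUL padding bytes, trim whitespace
dicom_string <- function(body) {
  trimws(rawToChar(body[body != as.raw(0L)]))
}

dicom_read <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz)) stop(sprintf("cannot read '%s'", path), call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  raw_all <- readBin(con, "raw", n = sz)
  if (length(raw_all) < 132L ||
      rawToChar(raw_all[129:132]) != "DICM")
    stop(sprintf("'%s' is not a DICOM file", path), call. = FALSE)
  rd_u <- function(bytes, size) {
    readBin(bytes, "integer", n = length(bytes) %/% size, size = size,
            endian = "little", signed = size == 4L)
  }
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  elems <- list()
  pos <- 133L
  explicit <- TRUE           # file meta group is always explicit LE
  transfer_syntax <- "1.2.840.10008.1.2.1"
  meta_done <- FALSE
  while (pos + 7L <= length(raw_all)) {
    group <- rd_u(raw_all[pos:(pos + 1L)], 2L)
    elem <- rd_u(raw_all[(pos + 2L):(pos + 3L)], 2L)
    if (!meta_done && group != 2L) {
      meta_done <- TRUE
      explicit <- transfer_syntax != "1.2.840.10008.1.2"
      if (!(transfer_syntax %in%
            c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1")))
        stop("unsupported DICOM transfer syntax: ", transfer_syntax,
             call. = FALSE)
    }
    use_explicit <- if (group == 2L) TRUE else explicit
    if (use_explicit) {
      vr <- rawToChar(raw_all[(pos + 4L):(pos + 5L)])
      if (vr %in% long_vrs) {
        len <- rd_u(raw_all[(pos + 8L):(pos + 11L)], 4L)
        hdr <- 12L
      } else {
        len <- rd_u(raw_all[(pos + 6L):(pos + 7L)], 2L)
        hdr <- 8L
      }
    } else {
      vr <- NA_character_
      len <- rd_u(raw_all[(pos + 4L):(pos + 7L)], 4L)
      hdr <- 8L
    }
    if (is.na(len) || len < 0L)
      stop("DICOM elements with undefined length are not supported",
           call. = FALSE)
    body <- if (len > 0L) raw_all[(pos + hdr):(pos + hdr + len - 1L)] else raw(0)
    key <- sprintf("%04x%04x", group, elem)
    elems[[key]] <- list(vr = vr, body = body)
    if (key == "00020010")
      transfer_syntax <- dicom_string(body)
    pos <- pos + hdr + len
    if (key == "7fe00010") break
  }
  get_str <- function(key) {
    e <- elems[[key]]
    if (is.null(e)) return(NULL)
    dicom_string(e$body)
  }
  get_u16 <- function(key) {
    e <- elems[[key]]
    if (is.null(e)) return(NULL)
    rd_u(e$body[1:2], 2L)
  }
  n_frames <- get_str("00280008")
  if (!is.null(n_frames) && as.integer(n_frames) > 1L)
    stop("multi-frame DICOM is not supported", call. = FALSE)
  photometric <- get_str("00280004")
  if (!is.null(photometric) && !startsWith(photometric, "MONOCHROME"))
    stop("only MONOCHROME DICOM photometric interpretations are supported",
         call. = FALSE)
  rows <- get_u16("00280010"); cols <- get_u16("00280011")
  bits_alloc <- get_u16("00280100")
  pixel_rep <- get_u16("00280103")
  if (is.null(pixel_rep)) pixel_rep <- 0L
  pd <- elems[["7fe00010"]]
  if (is.null(rows) || is.null(cols) || is.null(pd) || is.null(bits_alloc))
    stop(sprintf("'%s': incomplete DICOM pixel module", path), call. = FALSE)
  size <- bits_alloc %/% 8L
  n <- rows * cols
  v <- readBin(pd$body, "integer", n = n, size = size, endian = "little",
               signed = if (size == 1L) FALSE else pixel_rep == 1L)
  if (size == 2L && pixel_rep == 0L) v <- ifelse(v < 0L, v + 65536L, v)
  list(pixels = t(matrix(as.integer(v), cols, rows)),
       photometric = if (is.null(photometric)) "MONOCHROME2" else photometric,
       bits_allocated = bits_alloc)
}
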