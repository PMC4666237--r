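#' Read a grayscale image
#'
#' Reads PNG, TIFF or single-frame DICOM and returns an 8-bit
#' [gray_image()]. Colour inputs are converted to luminance
#' (ITU-R BT.601 weights, rounded); an alpha channel, if present, is
#' discarded. DICOM (and 16-bit grayscale PNG) pixel data are min-max
#' rescaled to `[0, 255]` and rounded to the nearest integer;
#' `MONOCHROME1` data are inverted after rescaling so that larger values
#' are brighter. DICOM windowing attributes are ignored.
#'
#' @param path path to a `.png`, `.tif`/`.tiff` or `.dcm` file. Files with
#'   other extensions are sniffed by magic number.
#' @return a [gray_image()] with `max_value = 255`.
#' @seealso [write_image()]
#' @export
read_image <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file '%s' does not exist", path), call. = FALSE)
  fmt <- detect_format(path)
  px <- switch(fmt,
    png = {
      p <- png_read(path)
      if (p$bit_depth == 16L) {
        matrix(rescale_to_8bit(p$pixels), nrow(p$pixels), ncol(p$pixels))
      } else if (p$channels == 1L) {
        p$pixels
      } else if (p$channels == 2L) {
        p$pixels[, , 1L]
      } else {
        rgb_to_luminance(p$pixels[, , 1L], p$pixels[, , 2L], p$pixels[, , 3L])
      }
    },
    tiff = {
      p <- tiff_read(path)
      if (p$channels == 1L) p$pixels
      else rgb_to_luminance(p$pixels[, , 1L], p$pixels[, , 2L], p$pixels[, , 3L])
    },
    dicom = {
      d <- dicom_read(path)
      v <- matrix(rescale_to_8bit(d$pixels), nrow(d$pixels), ncol(d$pixels))
      if (d$photometric == "MONOCHROME1") v <- 255L - v
      v
    },
    stop(sprintf("unsupported image format for '%s'", path), call. = FALSE)
  )
  gray_image(px, 255L)
}

#' Write a grayscale image
#'
#' Writes PNG or TIFF, chosen by file extension. Both encodings are
#' lossless: `read_image(write_image(img, path))` reproduces the pixel
#' matrix bit-exactly.
#'
#' @param img a [gray_image()].
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  img <- as_gray_image(img)
  if (!dir.exists(dirname(path)))
    stop(sprintf("directory '%s' does not exist", dirname(path)),
         call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png_write(img$pixels, path, 8L),
    tif = ,
    tiff = tiff_write(img$pixels, path),
    stop(sprintf("unsupported output format '.%s'", ext), call. = FALSE)
  )
  invisible(path)
}

detect_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("png", "dcm", "dicom", "tif", "tiff")) {
    return(switch(ext, png = "png", dcm = , dicom = "dicom", "tiff"))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", n = 132L)
  if (length(head) >= 8L && identical(head[1:8], PNG_SIGNATURE)) return("png")
  if (length(head) >= 4L && rawToChar(head[1:2]) %in% c("II", "MM"))
    return("tiff")
  if (length(head) >= 132L && rawToChar(head[129:132]) == "DICM")
    return("dicom")
  "unknown"
}
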