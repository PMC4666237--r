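#' Extract the central region of interest
#'
#' Cuts the fixed square window around the image centre that is assumed to
#' contain the deep-gray structures of interest (caudate nucleus, putamen,
#' thalamus). With the default `half_extent = 50` on a 256 x 256 slice this
#' is the central 100 x 100 window.
#'
#' The window spans `half_extent` pixels on each side of the centre point
#' `(floor(M/2), floor(N/2))` (0-based), i.e. rows/cols
#' `[c - half_extent, c + half_extent)`; the result is always
#' `2 * half_extent` square.
#'
#' @param img a [gray_image()].
#' @param half_extent window half-size in pixels (default 50).
#' @return an object of class `roi_window`: `pixels` (integer matrix),
#'   `origin` (1-based `(row, col)` of the top-left corner in the parent
#'   image), `rn` (pixel count).
#' @export
extract_roi <- function(img, half_extent = 50L) {
  img <- as_gray_image(img)
  half_extent <- as.integer(half_extent)
  if (half_extent < 1L) stop("half_extent must be >= 1", call. = FALSE)
  m <- nrow(img$pixels); n <- ncol(img$pixels)
  if (m < 2L * half_extent || n < 2L * half_extent)
    stop(sprintf("image %d x %d too small for half_extent %d", m, n,
                 half_extent), call. = FALSE)
  cm <- m %/% 2L; cn <- n %/% 2L
  rows <- (cm - half_extent + 1L):(cm + half_extent)
  cols <- (cn - half_extent + 1L):(cn + half_extent)
  roi_window(img$pixels[rows, cols, drop = FALSE],
             origin = c(rows[1L], cols[1L]))
}

#' Region-of-interest window
#'
#' @param pixels integer matrix of ROI intensities.
#' @param origin 1-based `(row, col)` of the window's top-left corner in its
#'   parent image.
#' @return an object of class `roi_window`.
#' @export
roi_window <- function(pixels, origin = c(1L, 1L)) {
  if (!is.matrix(pixels)) pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "integer"
  if (length(pixels) < 1L) stop("empty ROI", call. = FALSE)
  structure(list(pixels = pixels, origin = as.integer(origin),
                 rn = length(pixels)),
            class = "roi_window")
}

#' @export
print.roi_window <- function(x, ...) {
  cat(sprintf("<roi_window %d x %d at (%d, %d)>\n", nrow(x$pixels),
              ncol(x$pixels), x$origin[1], x$origin[2]))
  invisible(x)
}
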