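#' 8-bit grayscale image container
#'
#' The universal currency of the package: an integer matrix of pixel
#' intensities together with the maximum representable value. Row index is
#' the image row (top to bottom), column index the image column.
#'
#' @param pixels integer matrix of intensities in `[0, max_value]`.
#' @param max_value maximum representable intensity (255 for 8-bit data).
#' @return an object of class `gray_image` with fields `pixels` and
#'   `max_value`.
#' @examples
#' img <- gray_image(matrix(0:24, 5, 5))
#' dim(img$pixels)
#' @export
gray_image <- function(pixels, max_value = 255L) {
  if (!is.matrix(pixels)) pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "integer"
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must have at least one row and one column", call. = FALSE)
  if (anyNA(pixels))
    stop("image contains missing pixel values", call. = FALSE)
  rng <- range(pixels)
  if (rng[1] < 0L || rng[2] > max_value)
    stop(sprintf("pixel values must lie in [0, %d]", max_value), call. = FALSE)
  structure(list(pixels = pixels, max_value = as.integer(max_value)),
            class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, max %d, range [%d, %d]>\n",
              nrow(x$pixels), ncol(x$pixels), x$max_value,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

#' @method all.equal gray_image
#' @export
all.equal.gray_image <- function(target, current, ...) {
  if (!inherits(current, "gray_image")) return("current is not a gray_image")
  all.equal(target$pixels, current$pixels, ...)
}

as_gray_image <- function(x) {
  if (inherits(x, "gray_image")) return(x)
  gray_image(x)
}

# ITU-R BT.601 luminance for colour inputs, rounded half away from zero
rgb_to_luminance <- function(r, g, b) {
  round_half_away(0.299 * r + 0.587 * g + 0.114 * b)
}

# min-max rescale arbitrary integer data to [0, 255]; constant input maps to 0
rescale_to_8bit <- function(v) {
  rng <- range(v)
  if (rng[1] == rng[2]) return(rep(0L, length(v)))
  as.integer(round_half_away((v - rng[1]) * 255 / (rng[2] - rng[1])))
}
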