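#' Global histogram equalization
#'
#' Maps intensity `v` to `round(MAX * cdf(v))`, where `cdf` is the image's
#' empirical cumulative distribution including the pixel's own bin, and
#' rounding is half away from zero. Monotone: pixel ranks are preserved.
#'
#' @param img a [gray_image()].
#' @return the equalized [gray_image()].
#' @export
hist_equalize <- function(img) {
  img <- as_gray_image(img)
  lut <- he_lut(img$pixels, img$max_value)
  gray_image(matrix(lut[img$pixels + 1L], nrow(img$pixels), ncol(img$pixels)),
             img$max_value)
}

# equalization lookup table for the pixel population `px`
he_lut <- function(px, max_value) {
  h <- tabulate(as.integer(px) + 1L, nbins = max_value + 1L)
  cdf <- cumsum(h) / length(px)
  as.integer(round_half_away(max_value * cdf))
}

#' CLAHE configuration
#'
#' @param tile_grid `(rows, cols)` of contextual tiles (default `c(8, 8)`).
#' @param clip_limit histogram clip level as a fraction of the tile's pixel
#'   count per bin (default 0.01); `Inf` disables clipping.
#' @return an object of class `clahe_config`.
#' @export
clahe_config <- function(tile_grid = c(8L, 8L), clip_limit = 0.01) {
  tile_grid <- as.integer(tile_grid)
  if (length(tile_grid) != 2L || any(tile_grid < 1L))
    stop("tile_grid must be two integers >= 1", call. = FALSE)
  if (clip_limit <= 0) stop("clip_limit must be positive", call. = FALSE)
  structure(list(tile_grid = tile_grid, clip_limit = clip_limit),
            class = "clahe_config")
}

#' Contrast-limited adaptive histogram equalization
#'
#' The image is divided into a grid of contextual tiles; each tile's
#' histogram is clipped at `clip_limit * tile_pixels` counts per bin with
#' the excess redistributed uniformly over all bins, and equalization
#' mappings are computed per tile. Each pixel is then remapped by bilinear
#' interpolation between the mappings of the four nearest tile centres
#' (clamped at the borders). With a single tile and `clip_limit = Inf`
#' this reduces exactly to [hist_equalize()]. Deterministic for a fixed
#' configuration.
#'
#' @param img a [gray_image()].
#' @param cfg a [clahe_config()].
#' @return the enhanced [gray_image()].
#' @export
clahe <- function(img, cfg = clahe_config()) {
  img <- as_gray_image(img)
  px <- img$pixels
  m <- nrow(px); n <- ncol(px)
  tr <- cfg$tile_grid[1L]; tc <- cfg$tile_grid[2L]
  if (tr > m || tc > n)
    stop("tile grid larger than image", call. = FALSE)
  row_bounds <- tile_bounds(m, tr)
  col_bounds <- tile_bounds(n, tc)
  nbins <- img$max_value + 1L
  maps <- array(0L, dim = c(nbins, tr, tc))
  for (i in seq_len(tr)) {
    for (j in seq_len(tc)) {
      tile <- px[row_bounds$lo[i]:row_bounds$hi[i],
                 col_bounds$lo[j]:col_bounds$hi[j], drop = FALSE]
      h <- tabulate(as.integer(tile) + 1L, nbins = nbins)
      if (is.finite(cfg$clip_limit)) {
        cap <- cfg$clip_limit * length(tile)
        excess <- sum(pmax(h - cap, 0))
        h <- pmin(h, cap) + excess / nbins
      }
      cdf <- cumsum(h) / sum(h)
      maps[, i, j] <- as.integer(round_half_away(img$max_value * cdf))
    }
  }
  centers_r <- (row_bounds$lo + row_bounds$hi) / 2
  centers_c <- (col_bounds$lo + col_bounds$hi) / 2
  ri <- interp_coords(seq_len(m), centers_r, tr)
  ci <- interp_coords(seq_len(n), centers_c, tc)
  v <- as.integer(px) + 1L
  t0r <- rep(ri$t0, times = n); t1r <- rep(ri$t1, times = n)
  wr <- rep(ri$w, times = n)
  t0c <- rep(ci$t0, each = m); t1c <- rep(ci$t1, each = m)
  wc <- rep(ci$w, each = m)
  g <- function(tr_idx, tc_idx) maps[cbind(v, tr_idx, tc_idx)]
  out <- (1 - wr) * (1 - wc) * g(t0r, t0c) + (1 - wr) * wc * g(t0r, t1c) +
    wr * (1 - wc) * g(t1r, t0c) + wr * wc * g(t1r, t1c)
  gray_image(matrix(clip(round_half_away(out), 0, img$max_value), m, n),
             img$max_value)
}

# split `n` indices into `k` contiguous near-equal tiles
tile_bounds <- function(n, k) {
  cuts <- floor(seq(0L, n, length.out = k + 1L))
  list(lo = cuts[-(k + 1L)] + 1L, hi = cuts[-1L])
}

# for each coordinate, the two bracketing tile indices and the weight of
# the second; coordinates outside the span of centres clamp to the edge tile
interp_coords <- function(coord, centers, k) {
  idx <- findInterval(coord, centers)
  t0 <- clip(idx, 1L, k)
  t1 <- clip(idx + 1L, 1L, k)
  w <- ifelse(t1 > t0, (coord - centers[t0]) / (centers[t1] - centers[t0]), 0)
  list(t0 = t0, t1 = t1, w = clip(w, 0, 1))
}

#' Flat disk structuring element
#'
#' @param radius radius in pixels (>= 1); the element contains all integer
#'   offsets `(dr, dc)` with `dr^2 + dc^2 <= radius^2`.
#' @return an object of class `structuring_element` holding the offset
#'   matrix.
#' @export
disk_se <- function(radius = 3L) {
  radius <- as.integer(radius)
  if (radius < 1L) stop("radius must be >= 1", call. = FALSE)
  d <- -radius:radius
  g <- expand.grid(dr = d, dc = d)
  g <- g[g$dr^2 + g$dc^2 <= radius^2, , drop = FALSE]
  structure(list(shape = "disk", radius = radius,
                 offsets = as.matrix(g)),
            class = "structuring_element")
}

# grayscale erosion (op = pmin, pad = +Inf) / dilation (op = pmax, pad = -Inf)
morph_apply <- function(px, se, dilate) {
  m <- nrow(px); n <- ncol(px)
  acc <- matrix(if (dilate) -Inf else Inf, m, n)
  comb <- if (dilate) pmax else pmin
  for (k in seq_len(nrow(se$offsets))) {
    dr <- se$offsets[k, 1L]; dc <- se$offsets[k, 2L]
    ov <- shift_overlap(m, n, dr, dc)
    acc[ov$rows, ov$cols] <- comb(acc[ov$rows, ov$cols, drop = FALSE],
                                  px[ov$rows + dr, ov$cols + dc, drop = FALSE])
  }
  acc
}

morph_erode <- function(px, se) morph_apply(px, se, dilate = FALSE)
morph_dilate <- function(px, se) morph_apply(px, se, dilate = TRUE)
morph_open <- function(px, se) morph_dilate(morph_erode(px, se), se)
morph_close <- function(px, se) morph_erode(morph_dilate(px, se), se)

#' Morphological contrast enhancement (top-hat based)
#'
#' `opening` mode brightens-side enhancement via the white top-hat:
#' `clip(img + (img - opening(img)))`; `closing` mode dark-side
#' enhancement via the black top-hat: `clip(img - (closing(img) - img))`.
#' Opening and closing are standard flat grayscale morphology; outside the
#' image the erosion (dilation) treats missing pixels as +Inf (-Inf), i.e.
#' only in-image pixels participate.
#'
#' @param img a [gray_image()].
#' @param se a [disk_se()] structuring element.
#' @param mode `"opening"` or `"closing"`.
#' @return the enhanced [gray_image()].
#' @export
morpho_enhance <- function(img, se = disk_se(3L), mode = c("opening", "closing")) {
  img <- as_gray_image(img)
  mode <- match.arg(mode)
  px <- matrix(as.numeric(img$pixels), nrow(img$pixels), ncol(img$pixels))
  out <- if (mode == "opening") 2 * px - morph_open(px, se)
         else 2 * px - morph_close(px, se)
  gray_image(matrix(as.integer(clip(out, 0, img$max_value)),
                    nrow(px), ncol(px)), img$max_value)
}
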