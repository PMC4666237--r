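# 8-neighbourhood offsets (row, col)
NEIGHBOR_OFFSETS <- cbind(dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
                          dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))

# index ranges of the overlap between a matrix and its copy shifted by
# (dr, dc): centroid pixels at (rows, cols), neighbours at (rows+dr, cols+dc)
shift_overlap <- function(m, n, dr, dc) {
  rows <- max(1L, 1L - dr):min(m, m - dr)
  cols <- max(1L, 1L - dc):min(n, n - dc)
  list(rows = rows, cols = cols)
}

#' Build the gray-level correlation histogram of an ROI
#'
#' Scans the ROI with an overlapping 3 x 3 window: every pixel acts as the
#' centroid and each of its (up to eight) in-ROI neighbours contributes one
#' count at the matrix cell addressed by (centroid intensity, neighbour
#' intensity). The matrix is square with side `L = max - min + 1` over the
#' ROI's intensity range, indexed from the ROI minimum (`offset`).
#' Structurally this is a symmetric gray-level co-occurrence matrix over the
#' 8-neighbourhood; identical neighbouring pixels accumulate on the
#' diagonal.
#'
#' Border pixels use only their neighbours inside the ROI; no padding is
#' applied, which keeps the count matrix exactly symmetric.
#'
#' @param roi a [roi_window()] with at least 2 rows and 2 columns.
#' @return an object of class `correlation_histogram`: `counts` (L x L
#'   integer matrix, row = centroid intensity, column = neighbour
#'   intensity), `offset` (ROI minimum intensity mapped to index 0), `L`.
#' @export
build_correlation_histogram <- function(roi) {
  px <- roi$pixels
  m <- nrow(px); n <- ncol(px)
  if (m < 2L || n < 2L)
    stop("ROI must be at least 2 x 2 to have 8-neighbourhood pairs",
         call. = FALSE)
  offset <- min(px)
  L <- max(px) - offset + 1L
  counts <- integer(L * L)
  for (k in seq_len(nrow(NEIGHBOR_OFFSETS))) {
    dr <- NEIGHBOR_OFFSETS[k, 1L]; dc <- NEIGHBOR_OFFSETS[k, 2L]
    ov <- shift_overlap(m, n, dr, dc)
    cen <- px[ov$rows, ov$cols, drop = FALSE] - offset
    nb <- px[ov$rows + dr, ov$cols + dc, drop = FALSE] - offset
    idx <- cen + L * nb + 1L  # row = centroid, column = neighbour
    counts <- counts + tabulate(idx, nbins = L * L)
  }
  structure(list(counts = matrix(counts, L, L), offset = offset, L = L),
            class = "correlation_histogram")
}

#' @export
print.correlation_histogram <- function(x, ...) {
  cat(sprintf("<correlation_histogram L=%d, offset=%d, total=%d>\n",
              x$L, x$offset, sum(x$counts)))
  invisible(x)
}

# a block of the histogram plane; ranges are half-open 0-based intervals
# c(start, end) on the histogram indices
new_block <- function(label, x_range, y_range, layer) {
  structure(list(label = label, x_range = as.integer(x_range),
                 y_range = as.integer(y_range), layer = as.integer(layer)),
            class = "hcha_block")
}

#' @export
print.hcha_block <- function(x, ...) {
  cat(sprintf("<block %s layer %d: x [%d,%d) x y [%d,%d)>\n", x$label,
              x$layer, x$x_range[1], x$x_range[2], x$y_range[1],
              x$y_range[2]))
  invisible(x)
}

block_is_empty <- function(b) {
  b$x_range[2] <= b$x_range[1] || b$y_range[2] <= b$y_range[1]
}

#' Quadrant partition of the correlation-histogram plane (layer 1)
#'
#' Splits the L x L histogram plane at `m = floor(L/2)` into four quadrant
#' blocks. `B2` is the low-intensity diagonal quadrant and `B4` the
#' high-intensity diagonal quadrant (object information); `B1` (low
#' centroid, high neighbour) and `B3` (high centroid, low neighbour) are the
#' off-diagonal quadrants (edge information). For the degenerate `L = 1`
#' plane, `B2` spans the single cell and the other blocks are empty.
#'
#' @param hist a [build_correlation_histogram()] result.
#' @return list of four `hcha_block` objects named `B1`..`B4`.
#' @export
partition_layer1 <- function(hist) {
  L <- hist$L
  if (L == 1L) {
    return(list(B1 = new_block("B1", c(0L, 0L), c(0L, 0L), 1L),
                B2 = new_block("B2", c(0L, 1L), c(0L, 1L), 1L),
                B3 = new_block("B3", c(0L, 0L), c(0L, 0L), 1L),
                B4 = new_block("B4", c(0L, 0L), c(0L, 0L), 1L)))
  }
  m <- L %/% 2L
  low <- c(0L, m); high <- c(m, L)
  list(B1 = new_block("B1", low, high, 1L),
       B2 = new_block("B2", low, low, 1L),
       B3 = new_block("B3", high, low, 1L),
       B4 = new_block("B4", high, high, 1L))
}

#' Sub-quadrant partition of a diagonal block (layer 2)
#'
#' Splits a diagonal layer-1 block (`B2` or `B4`) into four sub-blocks with
#' the same quadrant layout as layer 1: for parent `Bm`, `Bm2` = low x low,
#' `Bm1` = low x high, `Bm3` = high x low, `Bm4` = high x high. Odd-length
#' ranges split at `floor(len/2)`, the low half getting the shorter side.
#'
#' @param parent an `hcha_block` with label `"B2"` or `"B4"`.
#' @return list of four `hcha_block` objects (e.g. `B21`..`B24`).
#' @export
partition_layer2 <- function(parent) {
  if (!inherits(parent, "hcha_block") || !parent$label %in% c("B2", "B4"))
    stop("layer-2 partition applies only to diagonal blocks B2 and B4",
         call. = FALSE)
  split_range <- function(r) {
    len <- r[2] - r[1]
    mid <- r[1] + len %/% 2L
    list(low = c(r[1], mid), high = c(mid, r[2]))
  }
  xs <- split_range(parent$x_range)
  ys <- split_range(parent$y_range)
  lab <- function(d) paste0(parent$label, d)
  out <- list(new_block(lab(1L), xs$low, ys$high, 2L),
              new_block(lab(2L), xs$low, ys$low, 2L),
              new_block(lab(3L), xs$high, ys$low, 2L),
              new_block(lab(4L), xs$high, ys$high, 2L))
  names(out) <- vapply(out, `[[`, "", "label")
  out
}

#' Back-project a histogram block to a binary pixel mask
#'
#' Marks ROI pixel `(i, j)` when it has at least one in-ROI 8-neighbour `q`
#' such that the intensity pair (pixel, neighbour) falls inside the block's
#' index ranges and the histogram holds a positive count at that cell. For
#' diagonal blocks this reduces to "the pixel and a neighbour share the
#' block's intensity range"; for off-diagonal blocks it marks the boundary
#' pixels whose neighbours lie in the other range.
#'
#' @param roi the [roi_window()] the histogram was built from.
#' @param hist the [build_correlation_histogram()] of `roi`.
#' @param block an `hcha_block`.
#' @return an object of class `pixel_mask`: `label` and `mask`, a 0/1
#'   integer matrix congruent with the ROI.
#' @export
project_mask <- function(roi, hist, block) {
  px <- roi$pixels
  m <- nrow(px); n <- ncol(px)
  mask <- matrix(FALSE, m, n)
  if (!block_is_empty(block)) {
    off <- hist$offset; L <- hist$L
    xr <- block$x_range; yr <- block$y_range
    for (k in seq_len(nrow(NEIGHBOR_OFFSETS))) {
      dr <- NEIGHBOR_OFFSETS[k, 1L]; dc <- NEIGHBOR_OFFSETS[k, 2L]
      ov <- shift_overlap(m, n, dr, dc)
      cen <- px[ov$rows, ov$cols, drop = FALSE] - off
      nb <- px[ov$rows + dr, ov$cols + dc, drop = FALSE] - off
      # as.vector: a bare 2-column index matrix would be read as (row, col)
      # coordinate pairs by `[`
      pos <- hist$counts[as.vector(cen + L * nb + 1L)] > 0L
      hit <- cen >= xr[1] & cen < xr[2] & nb >= yr[1] & nb < yr[2] & pos
      mask[ov$rows, ov$cols] <- mask[ov$rows, ov$cols] | hit
    }
  }
  structure(list(label = block$label,
                 mask = matrix(as.integer(mask), m, n)),
            class = "pixel_mask")
}
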