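# signed multiples of gamma applied to each offset-bearing sub-block;
# B23/B43 and the off-diagonal layer-1 blocks are left unchanged
OFFSET_MULTIPLES <- c(B22 = -1, B21 = -2, B24 = 1, B23 = 0,
                      B42 = 1, B44 = 1, B41 = 2, B43 = 0)

#' Contrast-enhancement parameters of an ROI
#'
#' Computes the ROI mean `mu`, the population standard deviation `sigma`
#' (divisor `RN`, not `RN - 1`), and the enhancement amplitude
#' `gamma = sigma / 4`. A quarter of the standard deviation is the unit
#' step of all per-block offsets: the full standard deviation over-brightens
#' the window while much smaller steps produce no visible change.
#'
#' @param roi a [roi_window()].
#' @return an object of class `enhancement_params`: `mu`, `sigma`, `gamma`
#'   and `offset_table`, the named vector of signed per-sub-block offsets in
#'   intensity units.
#' @export
compute_params <- function(roi) {
  pv <- as.numeric(roi$pixels)
  if (length(pv) < 1L) stop("empty ROI", call. = FALSE)
  mu <- sum(pv) / length(pv)
  sigma <- sqrt(sum((pv - mu)^2) / length(pv))
  gamma <- sigma / 4
  structure(list(mu = mu, sigma = sigma, gamma = gamma,
                 offset_table = OFFSET_MULTIPLES * gamma),
            class = "enhancement_params")
}

#' @export
print.enhancement_params <- function(x, ...) {
  cat(sprintf("<enhancement_params mu=%.3f sigma=%.3f gamma=%.3f>\n",
              x$mu, x$sigma, x$gamma))
  invisible(x)
}

#' Apply per-block intensity offsets to an ROI
#'
#' Each pixel receives the sum of the offsets of every mask that contains
#' it (masks may overlap; summation is order-independent), computed in real
#' arithmetic, rounded half away from zero once, then clipped to
#' `[0, max_value]`. Pixels contained in no mask are unchanged.
#'
#' @param roi a [roi_window()].
#' @param masks list of [project_mask()] results whose labels appear in the
#'   offset table.
#' @param params a [compute_params()] result.
#' @param max_value intensity ceiling for clipping (default 255).
#' @return a new `roi_window` with adjusted pixels and the same origin.
#' @export
apply_offsets <- function(roi, masks, params, max_value = 255L) {
  delta <- matrix(0, nrow(roi$pixels), ncol(roi$pixels))
  for (pm in masks) {
    if (!identical(dim(pm$mask), dim(roi$pixels)))
      stop(sprintf("mask %s does not match ROI dimensions", pm$label),
           call. = FALSE)
    mult <- OFFSET_MULTIPLES[[pm$label]]
    if (is.null(mult))
      stop(sprintf("no offset defined for block %s", pm$label), call. = FALSE)
    delta <- delta + pm$mask * mult * params$gamma
  }
  out <- clip(round_half_away(roi$pixels + delta), 0, max_value)
  roi_window(out, origin = roi$origin)
}

#' Run the full HCHA pipeline, returning intermediates
#'
#' Extracts the central ROI, builds its correlation histogram, partitions
#' layer 1 and the diagonal blocks into layer-2 sub-blocks, back-projects
#' the eight sub-blocks to pixel masks, computes the enhancement
#' parameters and applies the offsets.
#'
#' @param img a [gray_image()].
#' @param half_extent ROI half-size (default 50).
#' @return list with `image` (enhanced [gray_image()]), `roi`,
#'   `enhanced_roi`, `hist`, `layer1`, `layer2` (named list of eight
#'   sub-blocks), `masks` (named list of eight `pixel_mask`), `params`.
#' @export
enhance_pipeline <- function(img, half_extent = 50L) {
  img <- as_gray_image(img)
  roi <- extract_roi(img, half_extent)
  hist <- build_correlation_histogram(roi)
  layer1 <- partition_layer1(hist)
  layer2 <- c(partition_layer2(layer1$B2), partition_layer2(layer1$B4))
  masks <- lapply(layer2, function(b) project_mask(roi, hist, b))
  params <- compute_params(roi)
  offset_blocks <- masks[names(OFFSET_MULTIPLES)[OFFSET_MULTIPLES != 0]]
  new_roi <- apply_offsets(roi, offset_blocks, params, img$max_value)
  out <- img$pixels
  rows <- roi$origin[1L] + seq_len(nrow(roi$pixels)) - 1L
  cols <- roi$origin[2L] + seq_len(ncol(roi$pixels)) - 1L
  out[rows, cols] <- new_roi$pixels
  list(image = gray_image(out, img$max_value), roi = roi,
       enhanced_roi = new_roi, hist = hist, layer1 = layer1,
       layer2 = layer2, masks = masks, params = params)
}

#' Object-adaptive contrast enhancement (HCHA)
#'
#' Enhances the contrast of the structures inside the central region of
#' interest by hierarchical correlation-histogram analysis; pixels outside
#' the ROI are returned bit-identical. A zero-variance ROI (`sigma = 0`)
#' makes this the identity.
#'
#' @inheritParams enhance_pipeline
#' @return the enhanced [gray_image()].
#' @examples
#' ph <- generate_phantom(phantom_spec(seed = 42))
#' out <- enhance(ph$image)
#' @export
enhance <- function(img, half_extent = 50L) {
  enhance_pipeline(img, half_extent)$image
}
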