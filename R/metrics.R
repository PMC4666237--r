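check_same_dim <- function(a, b) {
  if (!identical(dim(a$pixels), dim(b$pixels)))
    stop("images have different dimensions", call. = FALSE)
}

#' Mean squared error between two images
#'
#' Differences are taken in signed arithmetic before squaring.
#'
#' @param c,s two [gray_image()]s of identical dimensions.
#' @return non-negative scalar.
#' @export
mse <- function(c, s) {
  c <- as_gray_image(c); s <- as_gray_image(s)
  check_same_dim(c, s)
  d <- as.numeric(c$pixels) - as.numeric(s$pixels)
  mean(d^2)
}

#' Peak signal-to-noise ratio (dB)
#'
#' `10 * log10(MAX^2 / MSE)` with `MAX` the maximum representable value of
#' the original image `c`. Identical images yield `Inf` (a total order for
#' method ranking is more useful than an error). In the benchmark harness
#' this is computed between the original and the enhanced image — no clean
#' reference exists — so it measures how conservative a method is, not
#' fidelity to ground truth.
#'
#' @inheritParams mse
#' @return PSNR in decibels, possibly `Inf`.
#' @export
psnr <- function(c, s) {
  c <- as_gray_image(c)
  e <- mse(c, s)
  if (e == 0) return(Inf)
  10 * log10(as.numeric(c$max_value)^2 / e)
}

#' Average gradient of an image
#'
#' Mean over the `(M-1) x (N-1)` grid of
#' `sqrt(((S[i+1,j]-S[i,j])^2 + (S[i,j+1]-S[i,j])^2) / 2)` — the RMS of the
#' forward differences in the row and column directions. Larger values
#' indicate a sharper image.
#'
#' @param s a [gray_image()] with at least 2 rows and 2 columns.
#' @return non-negative scalar.
#' @export
average_gradient <- function(s) {
  s <- as_gray_image(s)
  p <- s$pixels
  m <- nrow(p); n <- ncol(p)
  if (m < 2L || n < 2L)
    stop("average gradient requires at least a 2 x 2 image", call. = FALSE)
  a <- matrix(as.numeric(p), m, n)
  dr <- a[2:m, 1:(n - 1), drop = FALSE] - a[1:(m - 1), 1:(n - 1), drop = FALSE]
  dc <- a[1:(m - 1), 2:n, drop = FALSE] - a[1:(m - 1), 1:(n - 1), drop = FALSE]
  mean(sqrt((dr^2 + dc^2) / 2))
}

#' Grand average of per-group means
#'
#' The unweighted arithmetic mean of per-patient (per-group) mean values —
#' the aggregation that produces the bottom row of a per-patient benchmark
#' table. Rounding to 2 decimals is left to the caller/display.
#'
#' @param per_group_means non-empty numeric vector.
#' @return scalar mean.
#' @export
grand_average <- function(per_group_means) {
  if (length(per_group_means) == 0L)
    stop("grand_average of an empty vector", call. = FALSE)
  mean(as.numeric(per_group_means))
}

#' Quality metrics of an enhancement result
#'
#' @inheritParams mse
#' @return list with `mse`, `psnr` (dB) and `avg_gradient` of `s`.
#' @export
metric_report <- function(c, s) {
  list(mse = mse(c, s), psnr = psnr(c, s), avg_gradient = average_gradient(s))
}
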