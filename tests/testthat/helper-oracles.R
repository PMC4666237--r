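# Independent brute-force oracles. Deliberately naive: explicit double loops
# over pixels and neighbours, no shared code with the implementation.

brute_correlation_histogram <- function(px) {
  off <- min(px)
  L <- max(px) - off + 1L
  counts <- matrix(0L, L, L)
  m <- nrow(px); n <- ncol(px)
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      for (di in -1:1) {
        for (dj in -1:1) {
          if (di == 0 && dj == 0) next
          qi <- i + di; qj <- j + dj
          if (qi < 1 || qi > m || qj < 1 || qj > n) next
          a <- px[i, j] - off + 1L
          b <- px[qi, qj] - off + 1L
          counts[a, b] <- counts[a, b] + 1L
        }
      }
    }
  }
  list(counts = counts, offset = off, L = L)
}

brute_project_mask <- function(px, block, off) {
  m <- nrow(px); n <- ncol(px)
  mask <- matrix(0L, m, n)
  xr <- block$x_range; yr <- block$y_range
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      for (di in -1:1) {
        for (dj in -1:1) {
          if (di == 0 && dj == 0) next
          qi <- i + di; qj <- j + dj
          if (qi < 1 || qi > m || qj < 1 || qj > n) next
          a <- px[i, j] - off; b <- px[qi, qj] - off
          if (a >= xr[1] && a < xr[2] && b >= yr[1] && b < yr[2])
            mask[i, j] <- 1L
        }
      }
    }
  }
  mask
}

brute_mse <- function(a, b) {
  s <- 0
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(ncol(a))) s <- s + (a[i, j] - b[i, j])^2
  }
  s / (nrow(a) * ncol(a))
}

brute_avg_gradient <- function(a) {
  m <- nrow(a); n <- ncol(a)
  s <- 0
  for (i in seq_len(m - 1)) {
    for (j in seq_len(n - 1)) {
      s <- s + sqrt(((a[i + 1, j] - a[i, j])^2 + (a[i, j + 1] - a[i, j])^2) / 2)
    }
  }
  s / ((m - 1) * (n - 1))
}

brute_hist_equalize <- function(px, max_value = 255L) {
  n <- length(px)
  out <- px
  for (i in seq_along(px)) {
    v <- px[i]
    cdf <- sum(px <= v) / n
    x <- max_value * cdf
    out[i] <- sign(x) * floor(abs(x) + 0.5)
  }
  out
}

# two-pass population standard deviation
brute_sd_pop <- function(v) {
  mu <- sum(v) / length(v)
  sqrt(sum((v - mu)^2) / length(v))
}

random_gray_image <- function(m, n, max_value = 255L) {
  gray_image(matrix(sample(0:max_value, m * n, replace = TRUE), m, n),
             max_value)
}

random_roi <- function(m, n, lo = 0L, hi = 255L) {
  roi_window(matrix(sample(lo:hi, m * n, replace = TRUE), m, n))
}
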