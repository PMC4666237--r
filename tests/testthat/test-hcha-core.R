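test_that("extract_roi cuts the stated central window", {
  img <- gray_image(matrix(sample(0:255, 256 * 256, TRUE), 256, 256))
  roi <- extract_roi(img, 50L)
  expect_identical(dim(roi$pixels), c(100L, 100L))
  expect_identical(roi$origin, c(79L, 79L))  # 0-based (78, 78)
  expect_identical(roi$pixels, img$pixels[79:178, 79:178])
  expect_identical(roi$rn, 10000L)

  whole <- extract_roi(gray_image(matrix(7L, 100, 100)), 50L)
  expect_identical(dim(whole$pixels), c(100L, 100L))
  expect_identical(whole$origin, c(1L, 1L))

  tiny <- gray_image(matrix(1:25, 5, 5))
  r <- extract_roi(tiny, 1L)
  expect_identical(r$pixels, tiny$pixels[2:3, 2:3])

  expect_error(extract_roi(tiny, 50L), "too small")
})

test_that("constant 3x3 ROI gives a single diagonal cell of count 40", {
  h <- build_correlation_histogram(roi_window(matrix(9L, 3, 3)))
  expect_identical(h$L, 1L)
  expect_identical(h$offset, 9L)
  expect_identical(h$counts, matrix(40L, 1, 1))
})

test_that("histogram total matches the closed form 8MN - 6(M+N) + 4", {
  set.seed(1)
  for (m in c(2L, 3L, 5L, 9L, 20L)) {
    for (n in c(2L, 4L, 7L, 20L)) {
      h <- build_correlation_histogram(random_roi(m, n, 0L, 30L))
      expect_identical(sum(h$counts), 8L * m * n - 6L * (m + n) + 4L)
    }
  }
})

test_that("histogram is symmetric and matches the brute-force oracle", {
  set.seed(2)
  for (k in 1:50) {
    m <- sample(2:6, 1); n <- sample(2:6, 1)
    roi <- random_roi(m, n, 0L, 4L)
    h <- build_correlation_histogram(roi)
    expect_identical(h$counts, t(h$counts))
    b <- brute_correlation_histogram(roi$pixels)
    expect_identical(h$counts, b$counts)
    expect_identical(h$offset, b$offset)
    expect_identical(h$L, max(roi$pixels) - min(roi$pixels) + 1L)
  }
})

test_that("degenerate ROIs are rejected", {
  expect_error(build_correlation_histogram(roi_window(matrix(1:5, 1, 5))),
               "at least 2 x 2")
  expect_error(build_correlation_histogram(roi_window(matrix(1:5, 5, 1))),
               "at least 2 x 2")
})

test_that("layer-1 partition follows the floor(L/2) split", {
  mk <- function(L) structure(list(counts = matrix(0L, L, L), offset = 0L,
                                   L = L), class = "correlation_histogram")
  b8 <- partition_layer1(mk(8L))
  expect_identical(b8$B2$x_range, c(0L, 4L))
  expect_identical(b8$B2$y_range, c(0L, 4L))
  expect_identical(b8$B1$x_range, c(0L, 4L))
  expect_identical(b8$B1$y_range, c(4L, 8L))
  expect_identical(b8$B3$x_range, c(4L, 8L))
  expect_identical(b8$B3$y_range, c(0L, 4L))
  expect_identical(b8$B4$x_range, c(4L, 8L))
  expect_identical(b8$B4$y_range, c(4L, 8L))

  b5 <- partition_layer1(mk(5L))
  expect_identical(b5$B2$x_range, c(0L, 2L))
  expect_identical(b5$B4$x_range, c(2L, 5L))

  b1 <- partition_layer1(mk(1L))
  expect_identical(b1$B2$x_range, c(0L, 1L))
  for (lab in c("B1", "B3", "B4")) {
    expect_true(hcha:::block_is_empty(b1[[lab]]))
  }
})

test_that("layer-1 blocks tile the plane; layer-2 sub-blocks tile the parent", {
  mk <- function(L) structure(list(counts = matrix(0L, L, L), offset = 0L,
                                   L = L), class = "correlation_histogram")
  cover <- function(blocks, L) {
    plane <- matrix(0L, L, L)
    for (b in blocks) {
      if (hcha:::block_is_empty(b)) next
      xs <- (b$x_range[1] + 1):b$x_range[2]
      ys <- (b$y_range[1] + 1):b$y_range[2]
      plane[xs, ys] <- plane[xs, ys] + 1L
    }
    plane
  }
  for (L in c(1L, 2L, 3L, 5L, 8L, 13L)) {
    l1 <- partition_layer1(mk(L))
    expect_true(all(cover(l1, L) == 1L), label = sprintf("layer1 L=%d", L))
    for (lab in c("B2", "B4")) {
      parent <- l1[[lab]]
      if (hcha:::block_is_empty(parent)) next
      subs <- partition_layer2(parent)
      plane <- cover(subs, L)
      xs <- (parent$x_range[1] + 1):parent$x_range[2]
      ys <- (parent$y_range[1] + 1):parent$y_range[2]
      inside <- plane[xs, ys]
      plane[xs, ys] <- 0L
      expect_true(all(inside == 1L) && all(plane == 0L),
                  label = sprintf("layer2 %s L=%d", lab, L))
    }
  }
})

test_that("layer-2 partition arithmetic and error contract", {
  b4 <- hcha:::new_block("B4", c(4L, 9L), c(4L, 9L), 1L)
  subs <- partition_layer2(b4)
  expect_identical(names(subs), c("B41", "B42", "B43", "B44"))
  expect_identical(subs$B42$x_range, c(4L, 6L))
  expect_identical(subs$B42$y_range, c(4L, 6L))
  expect_identical(subs$B41$x_range, c(4L, 6L))
  expect_identical(subs$B41$y_range, c(6L, 9L))
  expect_identical(subs$B44$x_range, c(6L, 9L))

  empty <- hcha:::new_block("B2", c(3L, 3L), c(3L, 3L), 1L)
  for (s in partition_layer2(empty)) expect_true(hcha:::block_is_empty(s))

  expect_error(partition_layer2(hcha:::new_block("B1", c(0L, 2L), c(2L, 4L), 1L)),
               "diagonal")
})

test_that("constant ROI projects to an all-ones B2 mask and empty others", {
  roi <- roi_window(matrix(5L, 4, 4))
  h <- build_correlation_histogram(roi)
  l1 <- partition_layer1(h)
  m2 <- project_mask(roi, h, l1$B2)
  expect_true(all(m2$mask == 1L))
  for (lab in c("B1", "B3", "B4")) {
    expect_true(all(project_mask(roi, h, l1[[lab]])$mask == 0L))
  }
})

test_that("two-level ROI: B1 marks boundary pixels of the low value", {
  # left half a=0 (low range), right half b=9 (high range)
  px <- cbind(matrix(0L, 4, 2), matrix(9L, 4, 2))
  roi <- roi_window(px)
  h <- build_correlation_histogram(roi)
  l1 <- partition_layer1(h)
  m1 <- project_mask(roi, h, l1$B1)
  expect_identical(m1$mask, brute_project_mask(px, l1$B1, h$offset))
  # exactly the a-valued pixels adjacent to the b column are marked
  expect_identical(m1$mask, cbind(matrix(c(0L, 1L), 4, 2, byrow = TRUE),
                                  matrix(0L, 4, 2)))
})

test_that("diagonal-membership masks of B2 and B4 are disjoint", {
  set.seed(4)
  for (k in 1:20) {
    roi <- random_roi(5, 5, 0L, 9L)
    h <- build_correlation_histogram(roi)
    l1 <- partition_layer1(h)
    v <- roi$pixels - h$offset
    in2 <- v >= l1$B2$x_range[1] & v < l1$B2$x_range[2]
    in4 <- v >= l1$B4$x_range[1] & v < l1$B4$x_range[2]
    m2 <- project_mask(roi, h, l1$B2)$mask
    m4 <- project_mask(roi, h, l1$B4)$mask
    expect_true(!any(m2 == 1L & in2 & m4 == 1L & in4))
  }
})

test_that("project_mask agrees with the brute-force oracle on all blocks", {
  set.seed(6)
  for (k in 1:30) {
    m <- sample(2:6, 1); n <- sample(2:6, 1)
    roi <- random_roi(m, n, 0L, 4L)
    h <- build_correlation_histogram(roi)
    l1 <- partition_layer1(h)
    blocks <- c(l1, if (!hcha:::block_is_empty(l1$B2)) partition_layer2(l1$B2),
                if (!hcha:::block_is_empty(l1$B4)) partition_layer2(l1$B4))
    for (b in blocks) {
      expect_identical(project_mask(roi, h, b)$mask,
                       brute_project_mask(roi$pixels, b, h$offset),
                       label = sprintf("block %s k=%d", b$label, k))
    }
  }
})

test_that("histogram symmetry holds on many random ROIs (property)", {
  set.seed(8)
  for (k in 1:500) {
    roi <- random_roi(sample(2:5, 1), sample(2:5, 1), 0L, 20L)
    h <- build_correlation_histogram(roi)
    expect_identical(h$counts, t(h$counts))
  }
})
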