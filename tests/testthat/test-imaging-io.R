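test_that("gray_image enforces its invariants", {
  expect_error(gray_image(matrix(-1L, 2, 2)), "must lie in")
  expect_error(gray_image(matrix(256L, 2, 2)), "must lie in")
  expect_error(gray_image(matrix(integer(0), 0, 0)), "at least one")
  img <- gray_image(matrix(0L, 1, 1))
  expect_identical(img$pixels, matrix(0L, 1, 1))
  expect_identical(img$max_value, 255L)
})

test_that("PNG and TIFF round-trips are bit-exact", {
  tmp <- withr::local_tempdir()
  set.seed(11)
  for (k in 1:60) {
    m <- sample(1:40, 1); n <- sample(1:40, 1)
    img <- random_gray_image(m, n)
    for (ext in c("png", "tif")) {
      p <- file.path(tmp, sprintf("rt_%d.%s", k, ext))
      write_image(img, p)
      back <- read_image(p)
      expect_identical(back$pixels, img$pixels)
      expect_identical(back$max_value, 255L)
    }
  }
})

test_that("phantom image survives a TIFF round-trip", {
  tmp <- withr::local_tempdir()
  ph <- generate_phantom(phantom_spec(seed = 42))
  p <- file.path(tmp, "ph.tiff")
  write_image(ph$image, p)
  expect_identical(read_image(p)$pixels, ph$image$pixels)
})

test_that("16-bit DICOM is min-max rescaled to [0, 255]", {
  tmp <- withr::local_tempdir()
  set.seed(5)
  px <- matrix(sample(100:1123, 120, replace = TRUE), 10, 12)
  px[1, 1] <- 100L; px[10, 12] <- 1123L  # pin the range
  for (implicit in c(FALSE, TRUE)) {
    p <- file.path(tmp, sprintf("t_%d.dcm", implicit))
    write_test_dicom(p, px, implicit = implicit)
    img <- read_image(p)
    expect_identical(dim(img$pixels), c(10L, 12L))
    expect_identical(min(img$pixels), 0L)
    expect_identical(max(img$pixels), 255L)
    # spot-check the rescale formula on every pixel
    expected <- matrix(as.integer(floor((px - 100) * 255 / 1023 + 0.5)),
                       10, 12)
    expect_identical(img$pixels, expected)
  }
})

test_that("MONOCHROME1 DICOM is inverted so larger is brighter", {
  tmp <- withr::local_tempdir()
  px <- matrix(c(0L, 100L, 200L, 300L), 2, 2)
  p2 <- file.path(tmp, "m2.dcm"); p1 <- file.path(tmp, "m1.dcm")
  write_test_dicom(p2, px)
  write_test_dicom(p1, px, photometric = "MONOCHROME1")
  expect_identical(read_image(p1)$pixels, 255L - read_image(p2)$pixels)
})

test_that("multi-frame DICOM is rejected", {
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "mf.dcm")
  write_multiframe_dicom(p, matrix(1:6, 2, 3))
  expect_error(read_image(p), "multi-frame")
})

test_that("colour PNG is converted to BT.601 luminance", {
  # build an RGB PNG by hand through the internal chunk writer: encode three
  # channels via a raw scanline stream
  tmp <- withr::local_tempdir()
  set.seed(3)
  h <- 6L; w <- 5L
  r <- matrix(sample(0:255, h * w, TRUE), h, w)
  g <- matrix(sample(0:255, h * w, TRUE), h, w)
  b <- matrix(sample(0:255, h * w, TRUE), h, w)
  p <- file.path(tmp, "rgb.png")
  ihdr <- c(hcha:::u32_be(w), hcha:::u32_be(h), as.raw(c(8, 2, 0, 0, 0)))
  inter <- integer(0)
  for (i in seq_len(h)) {
    row <- rbind(r[i, ], g[i, ], b[i, ])
    inter <- c(inter, as.integer(row))
  }
  scan <- unlist(lapply(seq_len(h), function(i) {
    c(0L, inter[((i - 1) * 3 * w + 1):(i * 3 * w)])
  }))
  idat <- memCompress(as.raw(scan), "gzip")
  out <- c(hcha:::PNG_SIGNATURE, hcha:::png_chunk("IHDR", ihdr),
           hcha:::png_chunk("IDAT", idat), hcha:::png_chunk("IEND", raw(0)))
  con <- file(p, "wb"); writeBin(out, con); close(con)
  img <- read_image(p)
  lum <- 0.299 * r + 0.587 * g + 0.114 * b
  expect_identical(img$pixels,
                   matrix(as.integer(sign(lum) * floor(abs(lum) + 0.5)), h, w))
})

test_that("all five PNG filter types defilter correctly", {
  # craft one PNG per filter type and compare against a brute reconstruction
  set.seed(21)
  h <- 4L; w <- 6L
  px <- matrix(sample(0:255, h * w, TRUE), h, w)
  rowmajor <- t(px)
  for (f in 0:4) {
    filt <- integer(0)
    prev <- rep(0L, w)
    for (i in seq_len(h)) {
      cur <- rowmajor[, i]
      enc <- switch(as.character(f),
        "0" = cur,
        "1" = (cur - c(0L, cur[-w])) %% 256L,
        "2" = (cur - prev) %% 256L,
        "3" = (cur - (c(0L, cur[-w]) + prev) %/% 2L) %% 256L,
        "4" = {
          e <- integer(w)
          for (j in seq_len(w)) {
            a <- if (j > 1) cur[j - 1] else 0L
            b <- prev[j]
            cc <- if (j > 1) prev[j - 1] else 0L
            p <- a + b - cc
            pa <- abs(p - a); pb <- abs(p - b); pc <- abs(p - cc)
            pr <- if (pa <= pb && pa <= pc) a else if (pb <= pc) b else cc
            e[j] <- (cur[j] - pr) %% 256L
          }
          e
        })
      filt <- c(filt, f, enc)
      prev <- cur
    }
    tmp <- withr::local_tempfile(fileext = ".png")
    ihdr <- c(hcha:::u32_be(w), hcha:::u32_be(h), as.raw(c(8, 0, 0, 0, 0)))
    idat <- memCompress(as.raw(filt), "gzip")
    out <- c(hcha:::PNG_SIGNATURE, hcha:::png_chunk("IHDR", ihdr),
             hcha:::png_chunk("IDAT", idat), hcha:::png_chunk("IEND", raw(0)))
    con <- file(tmp, "wb"); writeBin(out, con); close(con)
    expect_identical(read_image(tmp)$pixels, px, label = sprintf("filter %d", f))
  }
})

test_that("I/O error contracts hold", {
  expect_error(read_image(file.path(tempdir(), "nope_missing.png")),
               "does not exist")
  img <- random_gray_image(3, 3)
  expect_error(write_image(img, file.path(tempdir(), "no_such_dir_xyz",
                                          "a.png")),
               "does not exist")
  expect_error(write_image(img, withr::local_tempfile(fileext = ".bmp")),
               "unsupported")
  # a text file is not a recognized image format
  p <- withr::local_tempfile(fileext = ".img")
  writeLines("not an image and long enough to fill the sniff buffer ....", p)
  expect_error(read_image(p), "unsupported image format")
})
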