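test_that("PNG and TIFF round trips are lossless for gray and RGB", {
  g <- RasterImage(matrix(sample(0:255, 36, replace = TRUE), 6, 6))
  rgb <- RasterImage(array(sample(0:255, 48, replace = TRUE),
                           dim = c(4, 4, 3)))
  for (ext in c("png", "tiff")) {
    for (img in list(g, rgb)) {
      f <- tempfile(fileext = paste0(".", ext))
      writeRaster(img, f)
      back <- readRaster(f)
      expect_identical(pixels(back), pixels(img))
      expect_identical(colorspace(back), colorspace(img))
      unlink(f)
    }
  }
})

test_that("16-bit TIFF is down-converted by right shift, with a message", {
  v16 <- matrix(c(0L, 255L, 256L, 257L, 511L, 513L, 65535L, 32768L, 1000L),
                3, 3)
  f <- tempfile(fileext = ".tif")
  tiff::writeTIFF(v16 / 65535, f, bits.per.sample = 16L)
  expect_message(img <- readRaster(f), "16-bit")
  # independent integer-division oracle
  expect_identical(pixels(img), matrix(as.numeric(v16 %/% 256L), 3, 3))
  unlink(f)
})

test_that("JPEG round trip preserves shape and is approximately lossless", {
  px <- matrix(rep(seq(40, 200, length.out = 16), each = 16), 16, 16)
  f <- tempfile(fileext = ".jpg")
  jpeg::writeJPEG(px / 255, f, quality = 0.95)
  back <- readRaster(f)
  expect_identical(dim(back), dim(px))
  expect_lt(mean(abs(pixels(back) - px)), 10)
  unlink(f)
})

test_that("24-bit BMP files are read correctly", {
  px <- array(sample(0:255, 5 * 7 * 3, replace = TRUE), dim = c(5, 7, 3))
  f <- tempfile(fileext = ".bmp")
  writeBMP24(px, f)
  img <- readRaster(f)
  expect_identical(colorspace(img), "RGB")
  expect_identical(pixels(img), array(as.numeric(px), dim = dim(px)))
  unlink(f)
})

test_that("missing and unsupported files raise errors naming the path", {
  expect_error(readRaster("no/such/file.png"), "no/such/file.png")
  f <- tempfile(fileext = ".xyz")
  writeLines("x", f)
  expect_error(readRaster(f), "unsupported image format")
  unlink(f)
})

test_that("BT.601 luminance matches its closed forms", {
  mk <- function(r, g, b) RasterImage(array(rep(c(r, g, b), each = 4),
                                            dim = c(2, 2, 3)))
  expect_equal(pixels(toYCbCr(mk(128, 128, 128)))[1, 1, 1], 128)
  expect_equal(pixels(toYCbCr(mk(255, 255, 255)))[1, 1, 1], 255)
  expect_equal(pixels(toYCbCr(mk(255, 0, 0)))[1, 1, 1], 76)   # round(.299*255)
  expect_equal(pixels(luminance(mk(0, 255, 0)))[1, 1], 150)   # round(.587*255)
  expect_equal(pixels(luminance(mk(10, 10, 10))),
               matrix(10, 2, 2))
  expect_error(toYCbCr(RasterImage(matrix(0, 4, 4))), "RGB")
})

test_that("YCbCr conversion inverts within one intensity level", {
  set.seed(7)
  rgb <- RasterImage(array(sample(0:255, 192, replace = TRUE),
                           dim = c(8, 8, 3)))
  back <- toRGB(toYCbCr(rgb))
  expect_lte(max(abs(pixels(back) - pixels(rgb))), 1)
})

test_that("luminance of a GRAY image is the identity", {
  g <- RasterImage(matrix(3, 4, 4))
  expect_identical(pixels(luminance(g)), pixels(g))
})

test_that("paired-dataset loading matches stems, skips and errors correctly", {
  root <- tempfile()
  dir.create(file.path(root, "ref"), recursive = TRUE)
  dir.create(file.path(root, "deg"), recursive = TRUE)
  img <- RasterImage(matrix(100, 8, 8))
  for (f in c("b.png", "a.png"))
    writeRaster(img, file.path(root, "ref", f))
  for (f in c("a.png", "b.png", "c.png"))
    writeRaster(img, file.path(root, "deg", f))
  expect_warning(pairs <- loadPairedDataset(file.path(root, "ref"),
                                            file.path(root, "deg")),
                 "c")
  expect_length(pairs, 2L)
  expect_identical(vapply(pairs, pairId, character(1)), c("a", "b"))

  # shape mismatch: pair rejected by name (the unmatched 'c' also warns)
  writeRaster(RasterImage(matrix(1, 4, 4)), file.path(root, "deg", "a.png"))
  w <- capture_warnings(pairs2 <- loadPairedDataset(file.path(root, "ref"),
                                                    file.path(root, "deg")))
  expect_true(any(grepl("shape mismatch", w)))
  expect_identical(vapply(pairs2, pairId, character(1)), "b")

  # zero matched pairs
  empty <- file.path(root, "empty")
  dir.create(empty)
  expect_error(suppressWarnings(
    loadPairedDataset(file.path(root, "ref"), empty)), "no matched pairs")
  unlink(root, recursive = TRUE)
})

test_that("cached pairwise PSNR equals the package PSNR", {
  root <- tempfile()
  dir.create(file.path(root, "ref"), recursive = TRUE)
  dir.create(file.path(root, "deg"), recursive = TRUE)
  writeRaster(RasterImage(matrix(100, 8, 8)), file.path(root, "ref", "a.png"))
  writeRaster(RasterImage(matrix(104, 8, 8)), file.path(root, "deg", "a.png"))
  pairs <- loadPairedDataset(file.path(root, "ref"), file.path(root, "deg"),
                             cachePsnr = TRUE)
  expect_equal(psnrDb(pairs[[1]]),
               psnr(reference(pairs[[1]]), degraded(pairs[[1]])))
  unlink(root, recursive = TRUE)
})

test_that("RasterImage validity enforces range and channel contracts", {
  expect_error(RasterImage(matrix(-1, 2, 2)), "intensities")
  expect_error(RasterImage(matrix(256, 2, 2)), "intensities")
  expect_error(RasterImage(array(0, dim = c(2, 2, 2))), "3 channels")
  expect_error(RasterImage(matrix(0, 2, 2), colorspace = "RGB"),
               "3 channels")
})
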