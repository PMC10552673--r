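test_that("read/write round trip preserves shape, channels and intensities", {
  dir <- withr::local_tempdir()
  set.seed(11)
  # 16-bit TIFF gray round trip
  g <- matrix(runif(20 * 30), 20, 30)
  p <- file.path(dir, "g.tif")
  write_image(g, p)
  back <- read_image(p)
  expect_equal(dim(back$pixels), c(20L, 30L, 1L))
  expect_lte(max(abs(back$pixels[, , 1L] - g)), 1 / 65535)
  # RGB round trip keeps channel order and shape
  a <- array(runif(15 * 12 * 3), c(15, 12, 3))
  img <- multichannel_image(a, c("red", "green", "blue"))
  p2 <- file.path(dir, "rgb.tif")
  write_image(img, p2)
  back2 <- read_image(p2)
  expect_identical(back2$channel_names, c("red", "green", "blue"))
  expect_lte(max(abs(back2$pixels - a)), 1 / 65535)
  # binary mask re-reads with exactly two values
  mask <- matrix(rbinom(100, 1, 0.4), 10, 10)
  p3 <- file.path(dir, "mask.tif")
  write_image(mask * 1, p3)
  expect_lte(length(unique(as.vector(read_image(p3)$pixels))), 2L)
})

test_that("8-bit PNG intensities are normalized by 255 and alpha is dropped", {
  dir <- withr::local_tempdir()
  vals <- c(255, 0, 128) / 255
  a <- array(0, c(4, 4, 3))
  a[, , 1L] <- vals[1L]; a[, , 2L] <- vals[2L]; a[, , 3L] <- vals[3L]
  p <- file.path(dir, "rgb.png")
  png::writePNG(a, p)
  got <- read_image(p)
  expect_equal(got$pixels[1, 1, ], c(1, 0, 128 / 255), tolerance = 1e-12)
  # RGBA with opaque alpha reads the same as the RGB file
  a4 <- array(1, c(4, 4, 4))
  a4[, , 1:3] <- a
  p4 <- file.path(dir, "rgba.png")
  png::writePNG(a4, p4)
  got4 <- read_image(p4)
  expect_identical(got4$channel_names, c("red", "green", "blue"))
  expect_equal(got4$pixels, got$pixels)
})

test_that("read_image rejects missing files and multi-plane stacks", {
  expect_error(read_image(file.path(tempdir(), "nope.tif")), "no such file")
  dir <- withr::local_tempdir()
  p <- file.path(dir, "stack.tif")
  tiff::writeTIFF(list(matrix(0.5, 4, 4), matrix(0.2, 4, 4)), p)
  expect_error(read_image(p), "more than one plane")
})

test_that("image intensities stay in [0,1] across written bit depths", {
  dir <- withr::local_tempdir()
  set.seed(12)
  for (i in 1:5) {
    g <- matrix(runif(64), 8, 8)
    p8 <- file.path(dir, sprintf("a%d.png", i))
    p16 <- file.path(dir, sprintf("a%d.tif", i))
    write_image(g, p8)
    write_image(g, p16)
    for (p in c(p8, p16)) {
      px <- read_image(p)$pixels
      expect_gte(min(px), 0)
      expect_lte(max(px), 1)
    }
  }
})

test_that("results CSV has one header plus one row per image and round-trips numbers", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "out.csv")
  # empty list: header only
  write_results_csv(list(), p)
  expect_length(readLines(p), 1L)
  r1 <- assay_result("img1", "ebd",
                     counts = list(total_cells = 100L, not_ebd_cells = 93L,
                                   ebd_pos_cells = 7L),
                     percent = list(pct_ebd_pos = 7.0))
  r2 <- assay_result("img2", "ebd",
                     counts = list(total_cells = 50L, not_ebd_cells = 50L,
                                   ebd_pos_cells = 0L),
                     percent = list(pct_ebd_pos = 0))
  write_results_csv(list(r1, r2), p)
  lines <- readLines(p)
  expect_length(lines, 3L)
  parsed <- read.csv(p)
  expect_equal(parsed$pct_ebd_pos, c(7.0, 0.0))
  expect_equal(parsed$ebd_pos_cells, c(7L, 0L))
  # mixed assay types are rejected
  r3 <- assay_result("img3", "cd68",
                     counts = list(foreground_pixels = 10L, total_pixels = 100L),
                     percent = list(pct_area = 10))
  expect_error(write_results_csv(list(r1, r3), p), "same assay")
})

test_that("invalid multichannel images are rejected", {
  expect_error(multichannel_image(array(2, c(2, 2, 1)), "red"), "\\[0, 1\\]")
  expect_error(multichannel_image(array(0.5, c(2, 2, 2)), "red"), "length")
  expect_error(multichannel_image(array(0.5, c(2, 2, 1)), "cyan"), "red/green/blue")
})
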