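test_that("slide() validates its inputs", {
  m <- matrix(0L, 4, 4)
  expect_error(slide(list(m), 0.5), "named")
  expect_error(slide(list(DAPI = m, FITC = matrix(0L, 4, 5)), 0.5),
               "identical dimensions")
  expect_error(slide(list(DAPI = m), -1), "pixel_size")
  expect_error(slide(list(DAPI = matrix(70000L, 4, 4)), 0.5), "outside")
  x <- slide(list(DAPI = m), 0.5)
  expect_s3_class(x, "Slide")
  expect_identical(dim(x), c(4L, 4L))
  expect_identical(x$pixel_size, 0.5)
  expect_identical(x$bit_depth, 16L)
})

test_that("area_um2 is exact and validates", {
  expect_identical(area_um2(100, 1), 100)
  expect_identical(area_um2(100, 0.5), 25)
  expect_identical(area_um2(0, 2), 0)
  expect_error(area_um2(-1, 1))
  expect_error(area_um2(1, 0))
})

test_that("label_mask enforces legend coverage", {
  lab <- matrix(c(0L, 1L, 2L, 0L), 2, 2)
  expect_error(label_mask(lab, c(`1` = "a")), "legend")
  mk <- label_mask(lab, c(`1` = "a", `2` = "b"))
  cls <- slidequant:::mask_classes(mk)
  expect_identical(cls[1, 1], NA_character_)
  expect_identical(cls[2, 1], "a")
  expect_identical(cls[1, 2], "b")
})

test_that("slide TIFF round trip is exact and calibration precedence holds", {
  set.seed(7)
  ch <- list(DAPI = matrix(sample.int(65535L, 64) - 1L, 8, 8),
             FITC = matrix(sample.int(65535L, 64) - 1L, 8, 8))
  x <- slide(ch, pixel_size = 0.161028)
  p <- file.path(tempdir(), "rt.tif")
  write_slide(x, p)
  y <- load_slide(p, channel_names = c("DAPI", "FITC"))
  expect_identical(y$channels, x$channels)       # bit-exact 16-bit round trip
  expect_identical(y$pixel_size, 0.161028)       # from the sidecar
  # explicit argument overrides the sidecar
  z <- load_slide(p, channel_names = c("DAPI", "FITC"), pixel_size = 2)
  expect_identical(z$pixel_size, 2)
  # channel-count mismatch is an error
  expect_error(load_slide(p, channel_names = "DAPI"), "mismatch")
  file.remove(p, slidequant:::slide_sidecar(p))
})

test_that("mask and report round trips preserve content", {
  lab <- matrix(sample(0:3, 100, replace = TRUE), 10, 10)
  mk <- label_mask(lab, c(`1` = "mucosa", `2` = "tumor", `3` = "other"))
  p <- file.path(tempdir(), "mask.tif")
  write_mask(mk, p)
  mk2 <- read_mask(p)
  expect_identical(mk2$labels, mk$labels)
  expect_identical(unname(mk2$legend[as.character(1:3)]),
                   unname(mk$legend[as.character(1:3)]))
  file.remove(p, slidequant:::slide_sidecar(p))

  rep <- data.frame(slide = "s1", roi_class = "mucosa", area_um2 = 1234.5,
                    area_mm2 = 1234.5 / 1e6, bis_area_um2 = 0,
                    total_cells = 10L, positive_positive = 4L,
                    density_positive = 4 * 1e6 / 1234.5)
  class(rep) <- c("DensityReport", class(rep))
  pr <- file.path(tempdir(), "report.csv")
  write_report(rep, pr)
  rep2 <- read_report(pr)
  expect_s3_class(rep2, "DensityReport")
  expect_equal(as.data.frame(rep2), as.data.frame(rep))
  file.remove(pr)
})
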