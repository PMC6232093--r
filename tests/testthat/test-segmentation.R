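test_that("primitive segmentation partitions the tissue mask exactly", {
  g <- small_fixture()
  xr <- downsample_slide(g$slide, 4L)
  mk <- detect_tissue(xr, tissue_params())
  layer <- segment_primitives(xr, mk, scale = 4, base_area = 1024)
  lab <- layer$labels
  m <- mk$labels > 0L
  expect_true(all(lab[m] > 0L))                 # every tissue pixel labeled
  expect_true(all(lab[!m] == 0L))               # nothing outside the mask
  n <- n_objects(layer)
  expect_gt(n, 10L)
  expect_setequal(unique(lab[m]), seq_len(n))   # contiguous ids, all present
  # primitive sizes scatter around the scale-derived target area
  target_px <- (1024 / 4^2) / xr$pixel_size^2
  expect_lt(abs(mean(tabulate(lab[m])) / target_px - 1), 0.75)
})

test_that("compute_features reports exact per-object channel means", {
  lab <- cbind(matrix(1L, 8, 4), matrix(2L, 8, 4))
  ch <- cbind(matrix(100L, 8, 4), matrix(900L, 8, 4))
  x <- slide(list(DAPI = ch, FITC = ch + 10L), pixel_size = 1)
  layer <- slidequant:::object_layer(lab, scale = 1, x)
  layer <- compute_features(layer, x)
  f <- layer$features
  expect_identical(f$n_px, c(32L, 32L))
  expect_identical(f$area, c(32, 32))
  expect_equal(f$mean_DAPI, c(100, 900))
  expect_equal(f$mean_FITC, c(110, 910))
  expect_equal(f$sd_DAPI, c(0, 0))
  expect_true(all(c("context_DAPI", "context_FITC", "heterogeneity",
                    "local_density", "compactness") %in% names(f)))
  # contextual mean blends the two halves: strictly between the own means
  expect_true(f$context_DAPI[1] > 100 && f$context_DAPI[1] < 900)
})

test_that("boundary contacts and relative border are consistent on a toy", {
  lab <- cbind(matrix(1L, 4, 4), matrix(2L, 4, 4))
  x <- toy_slide(4, 8)
  layer <- slidequant:::object_layer(lab, scale = 1, x)
  layer <- compute_features(layer, x)
  b <- layer$boundary
  # objects 1 and 2 share a 4-px contact; the rest is image border
  expect_identical(b$n[b$a == 1L & b$b == 2L], 4L)
  expect_identical(b$n[b$a == 2L & b$b == 1L], 4L)
  expect_identical(b$n[b$a == 1L & b$b == 0L], 12L)
  rb <- relative_border(layer, c("left", "right"))
  expect_equal(unname(rb[1, "right"]), 4 / 16)
  expect_equal(unname(rb[2, "left"]), 4 / 16)
  expect_true(all(rowSums(rb) <= 1))
  expect_identical(object_neighbors(layer, 1L), 2L)
})

test_that("rowsum_by matches a tapply oracle", {
  set.seed(11)
  v <- rnorm(500)
  ids <- sample.int(20L, 500, replace = TRUE)
  got <- slidequant:::rowsum_by(v, ids, 25L)
  want <- numeric(25)
  want[sort(unique(ids))] <- tapply(v, ids, sum)
  expect_equal(got, unname(want))
})

test_that("local nuclear density is bounded and tracks coverage", {
  ch <- matrix(100L, 96, 96)
  ch <- draw_disk(ch, 48, 28, 20, 30000L)    # dense bright patch
  x <- slide(list(DAPI = ch), pixel_size = 1)
  d <- slidequant:::nuclear_blob_density(x, "DAPI", radius_um = 10)
  expect_true(all(d >= 0))
  expect_true(all(d <= 1e6 / 35 + 1e-6))     # full coverage ceiling
  expect_gt(d[48, 28], d[48, 90])            # bright center >> empty corner
})
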