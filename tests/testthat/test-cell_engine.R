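# toys use 0.5 um/px: a 35 um^2 nucleus is a disk of radius ~6.7 px

nucleus_toy <- function(centers, radius = 6.7, value = 20000L, n = 100L) {
  dapi <- matrix(0L, n, n)
  for (i in seq_len(nrow(centers)))
    dapi <- draw_disk(dapi, centers[i, 1], centers[i, 2], radius, value)
  slide(list(DAPI = dapi, FITC = matrix(0L, n, n)), pixel_size = 0.5)
}

test_that("detect_nuclei finds isolated nuclei at their true centroids", {
  ctr <- rbind(c(30, 30), c(70, 64))
  x <- nucleus_toy(ctr)
  ns <- detect_nuclei(x, params = nucleus_params(detect_threshold = 0.3))
  expect_identical(nrow(ns$table), 2L)
  got <- ns$table[order(ns$table$row), c("row", "col")]
  expect_true(all(abs(as.matrix(got) - ctr) < 1.5))
  expect_true(all(abs(ns$table$area_um2 - 35) < 8))
})

test_that("the area prior splits fused nuclei and gates reject debris", {
  # two nuclei 8 px apart fuse into one blob ~2x the prior
  x <- nucleus_toy(rbind(c(50, 46), c(50, 54)))
  ns <- detect_nuclei(x, params = nucleus_params(detect_threshold = 0.3))
  expect_identical(nrow(ns$table), 2L)
  # a 2-px-radius speck (~3 um^2) falls below the lower gate
  y <- nucleus_toy(rbind(c(30, 30)))
  y$channels$DAPI <- draw_disk(y$channels$DAPI, 70, 70, 2, 20000L)
  ns2 <- detect_nuclei(y, params = nucleus_params(detect_threshold = 0.3))
  expect_identical(nrow(ns2$table), 1L)
  expect_lt(abs(ns2$table$row - 30), 1.5)
})

test_that("detection is restricted to the requested region classes", {
  x <- nucleus_toy(rbind(c(30, 30), c(70, 70)))
  roi <- label_mask(cbind(matrix(1L, 100, 50), matrix(2L, 100, 50)),
                    c(`1` = "mucosa", `2` = "other_tissue"))
  ns <- detect_nuclei(x, roi, iroi_classes = "mucosa",
                      params = nucleus_params(detect_threshold = 0.3))
  expect_identical(nrow(ns$table), 1L)
  expect_lt(abs(ns$table$col - 30), 1.5)
  expect_error(detect_nuclei(x, roi, iroi_classes = "tumor",
                             params = nucleus_params(detect_threshold = 0.3)),
               "not all present")
})

test_that("membrane-guided growth is capped and stays contiguous", {
  x <- nucleus_toy(rbind(c(50, 50)))
  f <- x$channels$FITC
  f <- draw_disk(f, 50, 50, 11, 5000L)           # membrane annulus
  f <- draw_disk(f, 50, 50, 6, 0L)
  f <- draw_disk(f, 15, 85, 5, 5000L)            # detached membrane blob
  x$channels$FITC <- f
  ns <- detect_nuclei(x, params = nucleus_params(detect_threshold = 0.3))
  cs <- simulate_cells(ns, x, params = cell_params())
  expect_identical(nrow(cs$cells), 1L)
  expect_lte(cs$cells$cell_area_um2, 38 + 5)     # the cap is exact
  expect_gte(cs$cells$cell_area_um2, cs$cells$nucleus_area_um2)
  expect_gt(cs$cells$mean_FITC_cell, cs$cells$mean_FITC_nucleus)
  # the detached blob is never claimed
  expect_true(all(cs$cell_labels[1:25, 75:95] == 0L))
})

test_that("growth_from_nuclei dilates to the mean area, ignoring membranes", {
  x <- nucleus_toy(rbind(c(50, 50)))
  ns <- detect_nuclei(x, params = nucleus_params(detect_threshold = 0.3))
  cs <- simulate_cells(ns, x, params = cell_params(mode = "growth_from_nuclei"))
  expect_identical(cs$cells$cell_area_um2, 38)   # exactly the mean area
})

test_that("cells never cross region-class borders", {
  x <- nucleus_toy(rbind(c(50, 40)))     # nucleus inside region 1
  # membrane staining spills across the region border at column 50
  x$channels$FITC <- draw_disk(x$channels$FITC, 50, 48, 12, 5000L)
  roi <- label_mask(cbind(matrix(1L, 100, 50), matrix(2L, 100, 50)),
                    c(`1` = "mucosa", `2` = "tumor"))
  ns <- detect_nuclei(x, roi, iroi_classes = c("mucosa", "tumor"),
                      params = nucleus_params(detect_threshold = 0.3))
  cs <- simulate_cells(ns, x, roi = roi)
  id <- cs$cells$id[1]
  expect_identical(cs$cells$roi_class[1], "mucosa")
  expect_true(all(roi$labels[cs$cell_labels == id] == 1L))
})

test_that("classify_cells uses inclusive thresholds in both schemes", {
  x <- toy_slide(4, 4, channels = c("DAPI", "FITC"))
  tb <- data.frame(id = 1:4, nucleus_area_um2 = 35, cell_area_um2 = 38,
                   row = 2, col = 2,
                   mean_DAPI_nucleus = c(1000, 999, 1000, 5000),
                   mean_DAPI_cell = 1000,
                   mean_FITC_nucleus = 0,
                   mean_FITC_cell = c(1300, 5000, 1299, 1300))
  cs <- slidequant:::cell_set(tb, matrix(0L, 4, 4), matrix(0L, 4, 4), x)
  out <- classify_cells(cs, classification_thresholds(),
                        phenotype_scheme("single_CD45"))
  expect_identical(out$cells$phenotype,
                   c("positive", "negative", "negative", "positive"))

  xd <- toy_slide(4, 4, channels = c("DAPI", "CY3", "FITC"))
  tb2 <- data.frame(id = 1:4, nucleus_area_um2 = 35, cell_area_um2 = 38,
                    row = 2, col = 2,
                    mean_DAPI_nucleus = 500, mean_DAPI_cell = 500,
                    mean_CY3_nucleus = 0,
                    mean_CY3_cell = c(2500, 2500, 2499, 0),
                    mean_FITC_nucleus = 0,
                    mean_FITC_cell = c(1500, 1499, 1500, 0))
  cs2 <- slidequant:::cell_set(tb2, matrix(0L, 4, 4), matrix(0L, 4, 4), xd)
  out2 <- classify_cells(cs2,
                         classification_thresholds(
                           nuclear_min = 500,
                           marker_min = c(CY3 = 2500, FITC = 1500)),
                         phenotype_scheme("double_CD3_CD4"))
  expect_identical(out2$cells$phenotype,
                   c("CD3+CD4+", "CD3+CD4-", "CD3-CD4+", "CD3-CD4-"))
  # a scheme channel missing from the slide is an error
  expect_error(classify_cells(cs, classification_thresholds(),
                              phenotype_scheme("double_CD3_CD4")),
               "missing")
})

test_that("exclude_artifacts drops edge and undersized cells with reasons", {
  x <- toy_slide(10, 10)
  tb <- data.frame(id = 1:3, nucleus_area_um2 = 20,
                   cell_area_um2 = c(38, 38, 5),
                   row = c(2, 8, 8), col = c(2, 8, 8),
                   mean_DAPI_nucleus = 2000, mean_DAPI_cell = 2000,
                   mean_FITC_nucleus = 0, mean_FITC_cell = 0,
                   phenotype = "negative")
  nl <- matrix(0L, 10, 10); nl[2, 2] <- 1L; nl[8, 8] <- 2L
  cl <- nl
  cs <- slidequant:::cell_set(tb, nl, cl, x)
  roi <- label_mask(rbind(matrix(2L, 5, 10), matrix(1L, 5, 10)),
                    c(`1` = "mucosa", `2` = "mucosa_bis"))
  out <- exclude_artifacts(cs, roi, min_cell_area = 10)
  expect_identical(out$cells$cells$id, 2L)
  expect_identical(out$log$reason[out$log$id == 1L], "edge_exclusion")
  expect_identical(out$log$reason[out$log$id == 3L], "below_min_area")
  expect_true(all(out$cells$cell_labels != 1L))
})

test_that("upscale_mask preserves class areas exactly", {
  mk <- label_mask(matrix(c(1L, 0L, 2L, 1L), 2, 2), c(`1` = "a", `2` = "b"))
  up <- upscale_mask(mk, 4L)
  expect_identical(dim(up$labels), c(8L, 8L))
  expect_identical(sum(up$labels == 1L), 16L * sum(mk$labels == 1L))
  expect_identical(area_um2(sum(up$labels == 2L), 1 / 4),
                   area_um2(sum(mk$labels == 2L), 1))
})
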