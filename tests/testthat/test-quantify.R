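test_that("cell_density implements the exact convention", {
  expect_identical(cell_density(100, 1e6), 100)
  expect_identical(cell_density(50, 5e5), 100)
  expect_identical(cell_density(0, 0), 0)
  expect_identical(cell_density(10, 8e5, 2e5), 10)   # bis in the denominator
  expect_error(cell_density(1, 0), "zero area")
  expect_error(cell_density(-1, 10))
})

test_that("summarize_density reports exact areas, counts and densities", {
  # 10x10 px at 10 um/px: mucosa 60 px, mucosa_bis 20 px, tumor 20 px
  lab <- matrix(1L, 10, 10)
  lab[1:2, ] <- 2L
  lab[9:10, ] <- 3L
  roi <- label_mask(lab, c(`1` = "mucosa", `2` = "mucosa_bis", `3` = "tumor"))
  x <- toy_slide(10, 10, pixel_size = 10)
  tb <- data.frame(id = 1:6, nucleus_area_um2 = 35, cell_area_um2 = 38,
                   row = 5, col = 5,
                   mean_DAPI_nucleus = 2000, mean_DAPI_cell = 2000,
                   mean_FITC_nucleus = 0, mean_FITC_cell = 0,
                   roi_class = c(rep("mucosa", 5), "tumor"),
                   phenotype = c("positive", "positive", "positive",
                                 "negative", "negative", "positive"))
  cs <- slidequant:::cell_set(tb, matrix(0L, 10, 10), matrix(0L, 10, 10), x)
  rep <- summarize_density(roi, cs, phenotype_scheme("single_CD45"),
                           pixel_size = 10, slide_id = "s1")
  expect_s3_class(rep, "DensityReport")
  expect_setequal(rep$roi_class, c("mucosa", "tumor"))   # bis folded away
  mu <- rep[rep$roi_class == "mucosa", ]
  expect_identical(mu$area_um2, 6000)
  expect_identical(mu$bis_area_um2, 2000)
  expect_identical(mu$total_cells, 5L)
  expect_identical(mu$positive_positive, 3L)
  expect_identical(mu$density_positive, 3 * 1e6 / 8000)  # bis in denominator
  tu <- rep[rep$roi_class == "tumor", ]
  expect_identical(tu$density_positive, 1 * 1e6 / 2000)
  # unclassified cells are an error
  cs2 <- cs; cs2$cells$phenotype <- NULL
  expect_error(summarize_density(roi, cs2, phenotype_scheme("single_CD45"),
                                 pixel_size = 10), "classified")
})

test_that("correlate_manual agrees with cor.test and validates", {
  dens <- c(10, 22, 35.5, 41, 18, 55)
  sc <- c(0, 1, 3, 4, 1, 5)
  rep <- data.frame(slide = sprintf("s%d", 1:6), roi_class = "mucosa",
                    density_positive = dens)
  scores <- data.frame(slide_id = sprintf("s%d", 1:6), roi_class = "mucosa",
                       score = sc)
  got <- correlate_manual(rep, scores, "mucosa")
  ref <- stats::cor.test(dens, sc)
  expect_equal(got$r, unname(ref$estimate))
  expect_equal(got$p, ref$p.value)
  expect_identical(got$n, 6L)
  # fewer than 3 pairs, out-of-range scores and zero variance are errors
  expect_error(correlate_manual(rep[1:2, ], scores[1:2, ], "mucosa"),
               "at least 3")
  bad <- scores; bad$score[1] <- 6
  expect_error(correlate_manual(rep, bad, "mucosa"), "\\[0, 5\\]")
  flat <- rep; flat$density_positive <- 7
  expect_error(correlate_manual(flat, scores, "mucosa"), "zero variance")
})

test_that("compare_rois agrees with oneway.test and validates groups", {
  set.seed(3)
  d <- data.frame(slide = sprintf("s%d", 1:12),
                  roi_class = rep(c("mucosa", "tumor", "lymphoid_follicle"),
                                  each = 4),
                  density_positive = c(rnorm(4, 100, 10), rnorm(4, 120, 10),
                                       rnorm(4, 900, 50)))
  got <- compare_rois(d)
  ref <- stats::oneway.test(density_positive ~ roi_class, data = d,
                            var.equal = TRUE)
  expect_equal(got$F, unname(ref$statistic))
  expect_equal(got$p, ref$p.value)
  expect_equal(unname(got$df), unname(ref$parameter))
  expect_error(compare_rois(d[d$roi_class == "mucosa", ]), "at least 2")
  expect_error(compare_rois(d[c(1:4, 5), ]), "at least 2 observations")
})
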