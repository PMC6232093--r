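test_that("the generator is fully deterministic given a seed", {
  cfg <- synth_config(size = 320L, seed = 17L)
  a <- generate_slide(cfg)
  b <- generate_slide(cfg)
  expect_identical(a$slide$channels, b$slide$channels)
  expect_identical(a$truth$cells, b$truth$cells)
  expect_identical(a$truth$roi$labels, b$truth$roi$labels)
  c2 <- generate_slide(synth_config(size = 320L, seed = 18L))
  expect_false(identical(a$slide$channels$DAPI, c2$slide$channels$DAPI))
})

test_that("the ground-truth region mask partitions the frame", {
  g <- small_fixture()
  lab <- g$truth$roi$labels
  expect_true(all(lab >= 1L & lab <= 5L))
  expect_setequal(unname(g$truth$roi$legend),
                  c("mucosa", "lymphoid_follicle", "tumor", "other_tissue",
                    "background"))
  # all four tissue region classes are actually present
  expect_true(all(1:4 %in% lab))
})

test_that("ground-truth positive counts track the configured densities", {
  g <- default_fixture()
  cfg <- synth_config()
  lab <- g$truth$roi$labels
  ps <- cfg$pixel_size
  legend <- g$truth$roi$legend
  area_mm2 <- vapply(c("mucosa", "lymphoid_follicle", "tumor"), function(cl) {
    code <- as.integer(names(legend)[legend == cl])
    area_um2(sum(lab == code), ps) / 1e6
  }, numeric(1))
  pos <- table(factor(
    g$truth$cells$region[g$truth$cells$phenotype == "positive"],
    levels = names(area_mm2)))
  dens <- as.numeric(pos) / area_mm2
  target <- cfg$positive_density[names(area_mm2)]
  # region areas are re-carved after placement counts are drawn, so the
  # realized density deviates from the target by up to ~15%
  expect_lt(abs(dens[["mucosa"]] / target[["mucosa"]] - 1), 0.15)
  expect_lt(abs(dens[["tumor"]] / target[["tumor"]] - 1), 0.15)
  # follicles are near the packing limit; small shortfalls are tolerated
  expect_gt(dens[["lymphoid_follicle"]], 0.8 * target[["lymphoid_follicle"]])
  expect_gt(dens[["lymphoid_follicle"]], 4 * dens[["mucosa"]])
})

test_that("the hard-core separation holds within and across regions", {
  g <- small_fixture()
  cfg <- synth_config(size = 512L, seed = 5L)
  cells <- g$truth$cells
  d_um <- 2 * sqrt(cfg$nucleus_area_mean / pi)       # nucleus diameter
  pts <- as.matrix(cells[, c("row", "col")]) * cfg$pixel_size
  dm <- as.matrix(stats::dist(pts))
  diag(dm) <- Inf
  # globally, no pair is closer than the smallest separation factor
  expect_gte(min(dm), min(unlist(cfg$sep_factor)) * d_um - 1e-9)
  # within the mucosa the full-diameter separation holds
  mu <- cells$region == "mucosa"
  if (sum(mu) > 1)
    expect_gte(min(dm[mu, mu]), cfg$sep_factor[["mucosa"]] * d_um - 1e-9)
})

test_that("negative controls carry no marker signal and no positives", {
  nc <- generate_negative_control(synth_config(size = 512L, seed = 5L))
  expect_lt(max(nc$slide$channels$FITC), 1600)   # below the CD45 threshold
  expect_true(all(nc$truth$cells$phenotype == "negative"))
  expect_false(any(nc$truth$artifacts$kind == "aggregate"))
})

test_that("positive slides render rings and aggregate artifacts", {
  g <- small_fixture()
  expect_gt(max(g$slide$channels$FITC), 1600)
  expect_true(any(g$truth$artifacts$kind == "aggregate"))
  # the double scheme renders both marker channels
  gd <- generate_slide(synth_config(size = 320L, seed = 2L,
                                    scheme = "double_CD3_CD4"))
  expect_setequal(names(gd$slide$channels), c("DAPI", "CY3", "FITC"))
  expect_true(all(gd$truth$cells$phenotype %in%
                  c("CD3+CD4+", "CD3+CD4-", "CD3-CD4+", "CD3-CD4-")))
})
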