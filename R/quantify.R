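#' Cell density in cells per square millimetre
#'
#' `density = count * 1e6 / (area_um2 + bis_area_um2)`, i.e. the count over
#' the region area expressed in mm^2. The `bis` term adds edge-class area
#' to the denominator (edge-class cells never enter the numerator). A zero
#' area with a zero count returns 0 by convention.
#'
#' @param count non-negative cell count.
#' @param area_um2 region area in um^2.
#' @param bis_area_um2 edge-class area in um^2 (default 0).
#' @return density in cells/mm^2.
#' @examples
#' cell_density(100, 1e6)   # 100 cells in 1 mm^2 -> 100 cells/mm^2
#' @export
cell_density <- function(count, area_um2, bis_area_um2 = 0) {
  stopifnot(count >= 0, area_um2 >= 0, bis_area_um2 >= 0)
  denom <- area_um2 + bis_area_um2
  if (denom == 0) {
    if (count > 0) stop("positive count with zero area")
    return(0)
  }
  count * 1e6 / denom
}

#' Aggregate a slide analysis into a per-region density report
#'
#' One row per region class (background excluded). `*_bis` edge-class
#' areas are folded into their parent class's denominator only; their
#' cells were already excluded by [exclude_artifacts()]. Densities are
#' reported per phenotype of the scheme, in cells/mm^2.
#'
#' @param roi a class `LabelMask` at the resolution used for areas.
#' @param cells a classified (and artifact-filtered) `CellSet`.
#' @param scheme the [phenotype_scheme()] used for classification.
#' @param pixel_size um/pixel of `roi` (needed for areas).
#' @param slide_id identifier written into the `slide` column.
#' @return a `DensityReport` data frame.
#' @export
summarize_density <- function(roi, cells, scheme, pixel_size,
                              slide_id = "slide") {
  stopifnot(inherits(roi, "LabelMask"), inherits(cells, "CellSet"),
            inherits(scheme, "PhenotypeScheme"))
  tb <- cells$cells
  if (nrow(tb) && !"phenotype" %in% names(tb))
    stop("cells must be classified before summarizing")
  legend <- roi$legend
  counts_px <- table(factor(roi$labels[roi$labels > 0L],
                            levels = names(legend)))
  class_px <- tapply(as.numeric(counts_px), unname(legend[names(counts_px)]), sum)
  all_classes <- setdiff(unique(unname(legend)), "background")
  report_classes <- all_classes[!is_bis(all_classes)]
  if (nrow(tb)) {
    known <- tb$roi_class %in% unname(legend) | is.na(tb$roi_class)
    if (!all(known)) stop("cells reference unknown region classes")
  }
  rows <- lapply(report_classes, function(cl) {
    a <- area_um2(if (cl %in% names(class_px)) class_px[[cl]] else 0, pixel_size)
    bis_cl <- paste0(cl, "_bis")
    b <- area_um2(if (bis_cl %in% names(class_px)) class_px[[bis_cl]] else 0,
                  pixel_size)
    in_cl <- which(!is.na(tb$roi_class) & tb$roi_class == cl)
    out <- data.frame(slide = slide_id, roi_class = cl, area_um2 = a,
                      area_mm2 = a / 1e6, bis_area_um2 = b,
                      total_cells = length(in_cl))
    for (ph in scheme$classes) {
      npos <- sum(tb$phenotype[in_cl] == ph)
      out[[paste0("positive_", ph)]] <- npos
      out[[paste0("density_", ph)]] <-
        if (a + b > 0) cell_density(npos, a, b) else 0
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("DensityReport", class(out))
  out
}

#' Correlate automated densities with a manual-score table
#'
#' Pearson correlation between the automated density and the expert 0--5
#' manual score for one region class, paired by slide id; the p-value is
#' the usual two-sided t-transform with n - 2 degrees of freedom.
#'
#' @param report a `DensityReport` (rows from several slides).
#' @param scores data frame with columns `slide_id`, `roi_class`, `score`
#'   (scores in `[0, 5]`).
#' @param roi_class region class to correlate.
#' @param phenotype phenotype whose density column is used (default
#'   `"positive"`).
#' @return list with `r`, `p` and `n`.
#' @export
correlate_manual <- function(report, scores, roi_class,
                             phenotype = "positive") {
  stopifnot(all(c("slide_id", "roi_class", "score") %in% names(scores)))
  if (any(scores$score < 0 | scores$score > 5))
    stop("manual scores must lie in [0, 5]")
  dens_col <- paste0("density_", phenotype)
  rr <- report[report$roi_class == roi_class, c("slide", dens_col)]
  ss <- scores[scores$roi_class == roi_class, c("slide_id", "score")]
  m <- merge(rr, ss, by.x = "slide", by.y = "slide_id")
  if (nrow(m) < 3L) stop("need at least 3 paired observations")
  x <- m[[dens_col]]; y <- m$score
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in density or score: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(m))
}

#' Compare a phenotype's density across region classes by one-way ANOVA
#'
#' Classical fixed-effects one-way analysis of variance of density on
#' region class, across slides/sections.
#'
#' @param report a `DensityReport` with rows from several slides.
#' @param phenotype phenotype whose density is compared (default
#'   `"positive"`).
#' @param classes region classes to include (default: all present).
#' @return list with `F`, `p`, `df` (numerator, denominator) and the group
#'   means.
#' @export
compare_rois <- function(report, phenotype = "positive", classes = NULL) {
  dens_col <- paste0("density_", phenotype)
  if (!dens_col %in% names(report)) stop("phenotype density column not found")
  d <- report[, c("roi_class", dens_col)]
  if (!is.null(classes)) d <- d[d$roi_class %in% classes, ]
  d$roi_class <- factor(d$roi_class)
  sizes <- table(d$roi_class)
  if (length(sizes) < 2L) stop("need at least 2 region-class groups")
  if (any(sizes < 2L)) stop("every group needs at least 2 observations")
  ft <- stats::oneway.test(stats::reformulate("roi_class", dens_col),
                           data = d, var.equal = TRUE)
  list(F = unname(ft$statistic), p = ft$p.value,
       df = unname(ft$parameter),
       means = tapply(d[[dens_col]], d$roi_class, mean))
}
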