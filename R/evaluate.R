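#' Match detected positive cells against generator ground truth
#'
#' Greedy nearest-pair matching of detected marker-positive cells to
#' ground-truth positive cells within a radius, per region, yielding
#' precision, recall, F1 and the relative count error. Used to validate
#' the cellular pipeline against synthetic slides.
#'
#' @param cells a classified `CellSet` (after artifact exclusion).
#' @param truth the `truth` component of [generate_slide()].
#' @param positive_classes phenotype labels counting as positive (default:
#'   any label other than `negative` / `CD3-CD4-`).
#' @param regions regions to evaluate (default: regions with at least one
#'   ground-truth positive).
#' @param match_radius_um maximal centroid distance for a match (default 5).
#' @return data frame per region: ground-truth and detected positive
#'   counts, TP/FP/FN, precision, recall, F1 and `count_error` (relative).
#' @export
match_cells_to_truth <- function(cells, truth,
                                 positive_classes = NULL,
                                 regions = NULL,
                                 match_radius_um = 5) {
  tb <- cells$cells
  ps <- cells$pixel_size
  if (is.null(positive_classes))
    positive_classes <- setdiff(unique(c(tb$phenotype, truth$cells$phenotype)),
                                c("negative", "CD3-CD4-"))
  gt <- truth$cells[truth$cells$phenotype %in% positive_classes, , drop = FALSE]
  det <- tb[!is.na(tb$phenotype) & tb$phenotype %in% positive_classes, ,
            drop = FALSE]
  if (is.null(regions)) regions <- sort(unique(gt$region))
  r_px <- match_radius_um / ps
  rows <- lapply(regions, function(reg) {
    g <- gt[gt$region == reg, , drop = FALSE]
    d <- det[!is.na(det$roi_class) & det$roi_class == reg, , drop = FALSE]
    tp <- 0L
    if (nrow(g) && nrow(d)) {
      dm <- outer(d$row, g$row, `-`)^2 + outer(d$col, g$col, `-`)^2
      cand <- which(dm <= r_px^2, arr.ind = TRUE)
      if (nrow(cand)) {
        cand <- cand[order(dm[cand]), , drop = FALSE]
        used_d <- logical(nrow(d)); used_g <- logical(nrow(g))
        for (i in seq_len(nrow(cand))) {
          a <- cand[i, 1]; b <- cand[i, 2]
          if (!used_d[a] && !used_g[b]) {
            used_d[a] <- TRUE; used_g[b] <- TRUE; tp <- tp + 1L
          }
        }
      }
    }
    fp <- nrow(d) - tp; fn <- nrow(g) - tp
    prec <- if (nrow(d)) tp / nrow(d) else NA_real_
    rec <- if (nrow(g)) tp / nrow(g) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
      2 * prec * rec / (prec + rec) else NA_real_
    data.frame(region = reg, gt_positive = nrow(g), det_positive = nrow(d),
               tp = tp, fp = fp, fn = fn, precision = prec, recall = rec,
               f1 = f1,
               count_error = if (nrow(g)) abs(nrow(d) - nrow(g)) / nrow(g)
                             else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pixel-level agreement of a region labeling with ground truth
#'
#' @param layer the `ObjectLayer` the labeling lives on.
#' @param labeling an `ROILabeling`.
#' @param gt_mask ground-truth class `LabelMask` at layer resolution.
#' @param ignore classes excluded from the comparison (default
#'   `background`; `*_bis` classes are scored as their parent).
#' @return fraction of evaluated tissue pixels whose class matches.
#' @export
roi_agreement <- function(layer, labeling, gt_mask, ignore = "background") {
  lab <- layer$labels
  idx <- which(lab > 0L)
  pred <- bis_parent(labeling$primitive_class[lab[idx]])
  gt <- unname(gt_mask$legend[as.character(gt_mask$labels[idx])])
  keep <- !is.na(gt) & !(gt %in% ignore)
  mean(pred[keep] == gt[keep])
}
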