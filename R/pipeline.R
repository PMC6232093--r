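#' Downsample a slide by integer block averaging
#'
#' Region-scale steps (tissue detection, segmentation, classification) run
#' well at a coarser viewing resolution than cellular analysis; block
#' averaging by an integer factor multiplies the pixel size accordingly.
#'
#' @param x a `Slide`.
#' @param factor integer >= 1 dividing both image dimensions is not
#'   required: trailing rows/columns are cropped.
#' @return a downsampled `Slide`.
#' @export
downsample_slide <- function(x, factor) {
  stopifnot(inherits(x, "Slide"), factor >= 1, factor == round(factor))
  if (factor == 1) return(x)
  f <- as.integer(factor)
  d <- dim(x$channels[[1]])
  nr <- (d[1] %/% f) * f; nc <- (d[2] %/% f) * f
  ds <- lapply(x$channels, function(ch) {
    ch <- ch[seq_len(nr), seq_len(nc)]
    # mean over f x f blocks
    a <- array(ch, c(f, nr %/% f, nc))
    m <- colMeans(a)                       # (nr/f) x nc
    a2 <- array(t(m), c(f, nc %/% f, nr %/% f))
    matrix(as.integer(round(t(colMeans(a2)))), nr %/% f, nc %/% f)
  })
  slide(ds, pixel_size = x$pixel_size * f, bit_depth = x$bit_depth)
}

#' Nearest-neighbor downsample of a label mask (for annotations)
#' @param mask a `LabelMask`; @param factor integer factor.
#' @return the downsampled `LabelMask`.
#' @export
downsample_mask <- function(mask, factor) {
  f <- as.integer(factor)
  if (f == 1) return(mask)
  d <- dim(mask$labels)
  ri <- seq(1L, (d[1] %/% f) * f, by = f)
  ci <- seq(1L, (d[2] %/% f) * f, by = f)
  label_mask(mask$labels[ri, ci], mask$legend)
}

#' Reclassify a tissue-edge margin into `*_bis` classes
#'
#' Paraffin-section edges autofluoresce on membrane channels; the standard
#' correction is to carve an edge margin of the affected classes into
#' `<class>_bis` so the margin's cells are excluded from positive counts
#' while its area still counts toward density denominators.
#'
#' @param layer the `ObjectLayer`.
#' @param labeling an `ROILabeling`.
#' @param tissue_mask the binary tissue `LabelMask` at layer resolution.
#' @param width_um margin width in um (default 8).
#' @param parents classes to carve (default mucosa and tumor).
#' @return the updated `ROILabeling`; its class set is extended with the
#'   bis classes as needed.
#' @export
add_bis_margin <- function(layer, labeling, tissue_mask, width_um = 8,
                           parents = c("mucosa", "tumor")) {
  m <- tissue_mask$labels != 0L
  d <- EBImage::imageData(EBImage::distmap(
    EBImage::Image(matrix(as.numeric(m), nrow(m)))))
  lab <- layer$labels
  idx <- which(lab > 0L)
  dmin <- tapply(d[idx], lab[idx], min) * layer$pixel_size
  near <- as.integer(names(dmin))[dmin <= width_um]
  pc <- labeling$primitive_class
  pv <- labeling$provenance
  hit <- intersect(near, which(pc %in% parents))
  if (!length(hit)) return(labeling)
  cs <- labeling$class_set$classes
  need <- paste0(unique(pc[hit]), "_bis")
  cs2 <- roi_class_set(c(cs, setdiff(need, cs)))
  pc[hit] <- paste0(pc[hit], "_bis")
  pv[hit] <- "bis_margin"
  roi_labeling(layer, pc, pv, cs2)
}

#' Assemble a pipeline configuration
#'
#' One configuration drives the full workflow (tissue detection, region
#' classification, cellular analysis, export) and can be mapped over a
#' batch of slides, realizing the one-parameter-set-per-batch principle.
#'
#' @param tissue a [tissue_params()].
#' @param scale segmentation scale (default 4).
#' @param base_area base primitive area at scale 1, um^2 (default 1024).
#' @param downsample integer viewing-resolution factor for the region
#'   steps (default 4); cellular analysis always runs at full resolution.
#' @param rules list of [reclass_rule()]s (default [default_ruleset()]).
#' @param exemplars_per_class cap on training exemplars derived per class.
#' @param regularize_passes sweeps of [regularize_labeling()] after the
#'   rules (0 disables; default 3).
#' @param manual_edits optional data frame for [manual_correct()].
#' @param bis_margin_um numeric margin width to carve into `*_bis` edge
#'   classes, or `NULL` to skip (default `NULL`).
#' @param nucleus a [nucleus_params()].
#' @param cell a [cell_params()].
#' @param thresholds a [classification_thresholds()].
#' @param scheme a [phenotype_scheme()].
#' @param iroi_classes classes analyzed for cells (default the three
#'   immune regions).
#' @param min_cell_area artifact filter minimum cell area, um^2.
#' @param seed integer seed for every stochastic step.
#' @return a list of class `PipelineConfig`.
#' @export
pipeline_config <- function(tissue = tissue_params(),
                            scale = 4, base_area = 1024, downsample = 4L,
                            rules = default_ruleset(),
                            exemplars_per_class = 200L,
                            regularize_passes = 3L,
                            manual_edits = NULL,
                            bis_margin_um = NULL,
                            nucleus = nucleus_params(),
                            cell = cell_params(),
                            thresholds = classification_thresholds(),
                            scheme = phenotype_scheme("single_CD45"),
                            iroi_classes = c("mucosa", "lymphoid_follicle",
                                             "tumor"),
                            min_cell_area = 10,
                            seed = 1L) {
  structure(as.list(environment()), class = "PipelineConfig")
}

#' Write a pipeline configuration to YAML
#'
#' The YAML file is the single source of truth for a batch: every
#' [run_pipeline()] call with an `out_dir` writes the fully resolved
#' configuration beside its outputs, and [read_config()] restores it.
#'
#' @param config a [pipeline_config()].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "PipelineConfig"))
  cfg <- unclass(config)
  cfg$tissue <- unclass(cfg$tissue)
  cfg$nucleus <- unclass(cfg$nucleus)
  cfg$cell <- unclass(cfg$cell)
  cfg$thresholds <- list(nuclear_min = cfg$thresholds$nuclear_min,
                         marker_min = as.list(cfg$thresholds$marker_min),
                         intensity_max = cfg$thresholds$intensity_max)
  cfg$scheme <- list(name = cfg$scheme$name,
                     nuclear_channel = cfg$scheme$nuclear_channel,
                     marker_channels = as.list(cfg$scheme$marker_channels))
  cfg$rules <- lapply(cfg$rules, unclass)
  cfg$manual_edits <- if (is.null(cfg$manual_edits)) NULL
                      else as.list(cfg$manual_edits)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML path written by [write_config()] (or hand-authored
#'   with the same fields; omitted fields take [pipeline_config()]
#'   defaults).
#' @return a [pipeline_config()].
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$tissue)) args$tissue <- do.call(tissue_params, y$tissue)
  if (!is.null(y$nucleus)) {
    y$nucleus$intensity_range <- unlist(y$nucleus$intensity_range)
    y$nucleus$area_gate <- unlist(y$nucleus$area_gate)
    args$nucleus <- do.call(nucleus_params, y$nucleus)
  }
  if (!is.null(y$cell)) args$cell <- do.call(cell_params, y$cell)
  if (!is.null(y$thresholds))
    args$thresholds <- classification_thresholds(
      nuclear_min = y$thresholds$nuclear_min,
      marker_min = unlist(y$thresholds$marker_min),
      intensity_max = y$thresholds$intensity_max)
  if (!is.null(y$scheme))
    args$scheme <- phenotype_scheme(
      y$scheme$name, nuclear_channel = y$scheme$nuclear_channel,
      marker_channels = unlist(y$scheme$marker_channels))
  if (!is.null(y$rules))
    args$rules <- lapply(y$rules, function(r) do.call(reclass_rule, r))
  if (!is.null(y$manual_edits))
    args$manual_edits <- as.data.frame(y$manual_edits,
                                       stringsAsFactors = FALSE)
  for (nm in c("scale", "base_area", "downsample", "exemplars_per_class",
               "regularize_passes", "bis_margin_um", "iroi_classes",
               "min_cell_area", "seed"))
    if (!is.null(y[[nm]])) args[[nm]] <- unlist(y[[nm]])
  do.call(pipeline_config, args)
}

#' Run the full analysis pipeline on one slide
#'
#' Stages, in order: tissue detection, primitive segmentation and feature
#' computation (at the region viewing resolution), exemplar-trained region
#' classification, ordered rule reclassification, neighbor-majority
#' regularization, optional manual
#' correction and edge (`bis`) margin, nucleus detection, cell simulation,
#' phenotyping, artifact exclusion, and density aggregation. All outputs
#' and a manifest are written when `out_dir` is given.
#'
#' @param x a `Slide` (or a TIFF path readable by [load_slide()], in which
#'   case `channel_names` must be supplied via `...`).
#' @param annotations a `LabelMask` at slide resolution with region-class
#'   training annotations (ground truth or analyst exemplar regions).
#' @param config a [pipeline_config()].
#' @param slide_id identifier used in the report.
#' @param out_dir optional output directory.
#' @param ... passed to [load_slide()] when `x` is a path.
#' @return list with `report` (a `DensityReport`), `roi` (full-resolution
#'   class `LabelMask`), `labeling`, `layer`, `cells` (filtered, classified
#'   `CellSet`), `exclusions` and `manifest`.
#' @export
run_pipeline <- function(x, annotations, config = pipeline_config(),
                         slide_id = "slide", out_dir = NULL, ...) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (is.character(x)) x <- load_slide(x, ...)
  stopifnot(inherits(x, "Slide"))
  need <- unname(c(config$scheme$nuclear_channel,
                   config$scheme$marker_channels))
  missing_ch <- setdiff(need, names(x$channels))
  if (length(missing_ch))
    stop(sprintf("config references channel(s) absent from slide: %s",
                 paste(missing_ch, collapse = ", ")))
  manifest <- list(slide_id = slide_id, seed = config$seed,
                   pixel_size = x$pixel_size,
                   downsample = config$downsample, stages = list())
  stage <- function(name, val) {
    manifest$stages[[name]] <<- val
    invisible(NULL)
  }
  # --- region-scale analysis ---
  xr <- downsample_slide(x, config$downsample)
  tissue <- detect_tissue(xr, config$tissue)
  stage("tissue_detection", list(tissue_px = sum(tissue$labels > 0L)))
  layer <- segment_primitives(xr, tissue, scale = config$scale,
                              base_area = config$base_area)
  layer <- compute_features(layer, xr)
  stage("segmentation", list(n_objects = n_objects(layer)))
  ann_ds <- downsample_mask(annotations, config$downsample)
  ex <- exemplars_from_mask(layer, ann_ds,
                            per_class = config$exemplars_per_class,
                            seed = config$seed)
  cls_present <- sort(unique(ex$class))
  class_set <- roi_class_set(cls_present)
  clf <- train_classifier(layer, ex, class_set, seed = config$seed)
  labeling <- classify_objects(clf, layer)
  labeling <- apply_rules(layer, labeling, config$rules)
  if (config$regularize_passes > 0L)
    labeling <- regularize_labeling(layer, labeling,
                                    passes = config$regularize_passes)
  if (!is.null(config$manual_edits))
    labeling <- manual_correct(layer, labeling, config$manual_edits)
  if (!is.null(config$bis_margin_um))
    labeling <- add_bis_margin(layer, labeling, tissue,
                               width_um = config$bis_margin_um)
  stage("roi_classification",
        list(classes = table(labeling$roi_table$class)))
  roi_ds <- roi_mask(layer, labeling)
  roi_full <- upscale_mask(roi_ds, config$downsample)
  # pad to the full slide frame if downsampling cropped trailing pixels
  d <- dim(x$channels[[1]])
  if (!identical(dim(roi_full$labels), d)) {
    full <- matrix(0L, d[1], d[2])
    dd <- dim(roi_full$labels)
    full[seq_len(dd[1]), seq_len(dd[2])] <- roi_full$labels
    roi_full <- label_mask(full, roi_full$legend)
  }
  # --- cellular analysis at full resolution ---
  iroi <- intersect(config$iroi_classes, unname(roi_full$legend))
  nuclei <- detect_nuclei(x, roi_full, iroi_classes = iroi,
                          params = config$nucleus,
                          nuclear_channel = config$scheme$nuclear_channel)
  stage("nucleus_detection", list(n_nuclei = nrow(nuclei$table)))
  cells <- simulate_cells(nuclei, x, params = config$cell, roi = roi_full,
                          nuclear_channel = config$scheme$nuclear_channel)
  cells <- classify_cells(cells, config$thresholds, config$scheme)
  filt <- exclude_artifacts(cells, roi_full,
                            min_cell_area = config$min_cell_area)
  stage("cell_analysis",
        list(n_cells = nrow(filt$cells$cells),
             n_excluded = nrow(filt$log)))
  report <- summarize_density(roi_full, filt$cells, config$scheme,
                              pixel_size = x$pixel_size,
                              slide_id = slide_id)
  out <- list(report = report, roi = roi_full, labeling = labeling,
              layer = layer, cells = filt$cells, exclusions = filt$log,
              manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(report, file.path(out_dir, paste0(slide_id, "_report.csv")))
    write_mask(roi_full, file.path(out_dir, paste0(slide_id, "_roi.tif")))
    utils::write.csv(filt$cells$cells,
                     file.path(out_dir, paste0(slide_id, "_cells.csv")),
                     row.names = FALSE)
    jsonlite::write_json(manifest,
                         file.path(out_dir, paste0(slide_id, "_manifest.json")),
                         auto_unbox = TRUE, force = TRUE)
    write_config(config, file.path(out_dir, paste0(slide_id, "_config.yaml")))
  }
  out
}

#' Run one configuration over a batch of slides
#'
#' @param slides named list of `Slide`s (or paths).
#' @param annotations single `LabelMask` or named list matching `slides`.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @param ... passed to [run_pipeline()].
#' @return a combined `DensityReport` with one row set per slide.
#' @export
run_batch <- function(slides, annotations, config = pipeline_config(),
                      out_dir = NULL, ...) {
  ids <- names(slides)
  if (is.null(ids)) ids <- sprintf("slide_%02d", seq_along(slides))
  rep_list <- lapply(seq_along(slides), function(i) {
    ann <- if (inherits(annotations, "LabelMask")) annotations
           else annotations[[i]]
    run_pipeline(slides[[i]], ann, config, slide_id = ids[i],
                 out_dir = out_dir, ...)$report
  })
  out <- do.call(rbind, rep_list)
  class(out) <- c("DensityReport", class(out))
  out
}
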