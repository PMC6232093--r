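#' Construct a calibrated multichannel slide
#'
#' A `Slide` bundles named 2-D intensity channels with the physical pixel
#' calibration needed to express every downstream rule in micrometres.
#' Intensities are raw grey-value levels (integers); the default bit depth of
#' 16 gives a dynamic range of 0--65535.
#'
#' @param channels named list of integer matrices, all with identical
#'   dimensions, indexed `[row, col]` with origin top-left.
#' @param pixel_size pixel edge length in micrometres per pixel (> 0).
#' @param bit_depth integer bit depth; intensities must lie in
#'   `[0, 2^bit_depth)`.
#' @return an object of class `Slide`.
#' @export
slide <- function(channels, pixel_size, bit_depth = 16L) {
  if (!is.list(channels) || length(channels) == 0L || is.null(names(channels)) ||
      any(!nzchar(names(channels))))
    stop("'channels' must be a non-empty named list of matrices")
  dims <- lapply(channels, dim)
  if (any(vapply(dims, is.null, logical(1))))
    stop("every channel must be a matrix")
  d0 <- dims[[1]]
  if (!all(vapply(dims, function(d) identical(d, d0), logical(1))))
    stop("all channels must share identical dimensions")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || is.na(pixel_size) ||
      pixel_size <= 0)
    stop("'pixel_size' must be a single positive number (um/pixel)")
  bit_depth <- as.integer(bit_depth)
  hi <- 2^bit_depth
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (any(ch < 0 | ch >= hi, na.rm = TRUE))
      stop(sprintf("channel '%s' has intensities outside [0, 2^%d)", nm, bit_depth))
    storage.mode(channels[[nm]]) <- "integer"
  }
  structure(
    list(channels = channels, pixel_size = as.numeric(pixel_size),
         bit_depth = bit_depth),
    class = "Slide"
  )
}

#' @export
print.Slide <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("Slide: %d x %d px, %d channel(s) [%s], %.6f um/px, %d-bit\n",
              d[1], d[2], length(x$channels),
              paste(names(x$channels), collapse = ", "),
              x$pixel_size, x$bit_depth))
  invisible(x)
}

#' @export
dim.Slide <- function(x) dim(x$channels[[1]])

#' Construct a label mask
#'
#' A `LabelMask` is an integer label image (0 = unassigned) plus a legend
#' mapping each nonzero label to a class name. It carries region ground truth
#' and classification results.
#'
#' @param labels integer matrix; 0 means unassigned.
#' @param legend named character vector: `names(legend)` are label integers
#'   (as strings), values are class names. Every nonzero label occurring in
#'   `labels` must appear in the legend.
#' @return an object of class `LabelMask`.
#' @export
label_mask <- function(labels, legend = character()) {
  if (is.null(dim(labels))) stop("'labels' must be a matrix")
  storage.mode(labels) <- "integer"
  present <- setdiff(unique(as.vector(labels)), 0L)
  if (length(present) && !all(as.character(present) %in% names(legend)))
    stop("every nonzero label must appear in the legend")
  structure(list(labels = labels, legend = legend), class = "LabelMask")
}

#' @export
print.LabelMask <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("LabelMask: %d x %d px, %d classes [%s]\n", d[1], d[2],
              length(unique(x$legend)),
              paste(unique(x$legend), collapse = ", ")))
  invisible(x)
}

#' Look up the class name of each pixel label
#' @param mask a `LabelMask`.
#' @return character matrix of class names, `NA` where unassigned.
#' @keywords internal
mask_classes <- function(mask) {
  out <- matrix(NA_character_, nrow(mask$labels), ncol(mask$labels))
  nz <- mask$labels != 0L
  out[nz] <- unname(mask$legend[as.character(mask$labels[nz])])
  out
}

#' Convert a pixel count to an area in square micrometres
#'
#' @param pixel_count non-negative number of pixels.
#' @param pixel_size pixel edge length in um/pixel.
#' @return area in um^2: `pixel_count * pixel_size^2`.
#' @examples
#' area_um2(100, 1)          # 100 um^2
#' area_um2(386, 0.161028)   # ~10 um^2, the minimal tissue fragment size
#' @export
area_um2 <- function(pixel_count, pixel_size) {
  if (any(pixel_count < 0)) stop("'pixel_count' must be >= 0")
  if (any(pixel_size <= 0)) stop("'pixel_size' must be > 0")
  pixel_count * pixel_size^2
}

# sidecar metadata path for a written slide
slide_sidecar <- function(path) paste0(path, ".meta.json")

#' Read a multichannel slide from a (multi-page) TIFF
#'
#' Each TIFF page is one channel. Pixel calibration is taken, in order of
#' precedence, from (1) the `pixel_size` argument, (2) a JSON sidecar
#' `<path>.meta.json` written by [write_slide()], (3) the TIFF resolution tag
#' when it is expressed in pixels per centimetre or inch. If none is
#' available the call fails rather than assuming a default.
#'
#' @param path TIFF file path.
#' @param channel_names character vector naming the pages, in page order.
#' @param pixel_size optional calibration override in um/pixel.
#' @param bit_depth integer bit depth (default 16).
#' @return a [slide()] object.
#' @export
load_slide <- function(path, channel_names, pixel_size = NULL, bit_depth = 16L) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != length(channel_names))
    stop(sprintf("channel-count mismatch: file has %d page(s), %d name(s) supplied",
                 length(pages), length(channel_names)))
  ps <- pixel_size
  meta_path <- slide_sidecar(path)
  if (is.null(ps) && file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    ps <- meta$pixel_size
    if (!is.null(meta$bit_depth)) bit_depth <- meta$bit_depth
  }
  if (is.null(ps)) {
    at <- attributes(pages[[1]])
    if (!is.null(at$x.resolution) && !is.null(at$resolution.unit)) {
      # resolution is pixels per unit; convert to um/pixel
      per_um <- switch(at$resolution.unit,
                       inch = at$x.resolution / 25400,
                       cm = at$x.resolution / 1e4,
                       NULL)
      if (!is.null(per_um) && per_um > 0) ps <- 1 / per_um
    }
  }
  if (is.null(ps))
    stop("no pixel-size metadata found and no 'pixel_size' override supplied")
  channels <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # first sample of multi-sample pages
    matrix(p, nrow(p), ncol(p))               # drop TIFF tag attributes
  })
  names(channels) <- channel_names
  slide(channels, pixel_size = ps, bit_depth = bit_depth)
}

#' Write a slide as a multi-page 16-bit TIFF plus a JSON calibration sidecar
#'
#' @param x a `Slide`.
#' @param path output TIFF path; a `<path>.meta.json` sidecar records
#'   pixel size, bit depth and channel names so [load_slide()] can restore
#'   the calibration.
#' @return `path`, invisibly.
#' @export
write_slide <- function(x, path) {
  stopifnot(inherits(x, "Slide"))
  hi <- 2^x$bit_depth - 1
  pages <- lapply(x$channels, function(ch) ch / hi)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(pixel_size = x$pixel_size, bit_depth = x$bit_depth,
         channels = names(x$channels)),
    slide_sidecar(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a label mask as a single-page 16-bit TIFF plus a JSON legend sidecar
#' @param mask a `LabelMask`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "LabelMask"))
  tiff::writeTIFF(mask$labels / 65535, path, bits.per.sample = 16L)
  jsonlite::write_json(as.list(mask$legend), slide_sidecar(path),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read a label mask written by [write_mask()]
#' @param path TIFF path with `<path>.meta.json` legend sidecar.
#' @return a `LabelMask`.
#' @export
read_mask <- function(path) {
  labels <- tiff::readTIFF(path, as.is = TRUE)
  legend <- character()
  if (file.exists(slide_sidecar(path))) {
    lg <- jsonlite::read_json(slide_sidecar(path), simplifyVector = TRUE)
    legend <- unlist(lg)
  }
  label_mask(labels, legend)
}

# fixed column order of the density report CSV
report_fixed_cols <- c("slide", "roi_class", "area_um2", "area_mm2",
                       "bis_area_um2", "total_cells")

#' Write a density report to CSV
#'
#' One row per (slide, ROI class) with areas in um^2 and mm^2, total and
#' phenotype-positive cell counts, and densities in cells/mm^2. Phenotype
#' columns are `positive_<phenotype>` and `density_<phenotype>`.
#'
#' @param report a `DensityReport` data frame from [summarize_density()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(is.data.frame(report))
  extra <- setdiff(names(report), report_fixed_cols)
  cols <- c(intersect(report_fixed_cols, names(report)), extra)
  utils::write.csv(report[, cols, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' Read a density report CSV written by [write_report()]
#' @param path CSV path.
#' @return data frame of class `DensityReport`.
#' @export
read_report <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("DensityReport", class(out))
  out
}
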