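#' Nucleus-detection parameters
#'
#' DAPI grey values are converted to arbitrary units (a.u.) by a fixed
#' divisor so the usable detection range can be quoted on a 0--2 scale
#' (65536 g.v.l corresponds to 2.0 a.u. with the default divisor of 32768).
#' The mean nuclear area prior (35 um^2) drives the separation of touching
#' nuclei; hard area gates reject debris and unresolvable clumps.
#'
#' @param intensity_range detection range in a.u. (default `c(0, 2)`).
#' @param mean_area mean nuclear area prior in um^2 (default 35).
#' @param area_tol tolerance on the prior in um^2 (default 5).
#' @param area_gate hard acceptance gates in um^2 (default `c(10, 150)`).
#' @param au_divisor grey-value levels per a.u. (default 32768).
#' @param detect_threshold optional explicit detection threshold in a.u.;
#'   when `NULL` an Otsu threshold over the analyzed region is used.
#' @param smooth_sigma Gaussian sigma in px applied before thresholding.
#' @param ws_tolerance watershed merge tolerance in distance-map units;
#'   `NULL` derives it from the area prior (0.05 of the nucleus radius,
#'   at least 1).
#'   Components the watershed leaves fused (>= 1.6x the mean-area prior)
#'   are split by the area prior afterwards.
#' @return a list of class `NucleusParams`.
#' @export
nucleus_params <- function(intensity_range = c(0, 2), mean_area = 35,
                           area_tol = 5, area_gate = c(10, 150),
                           au_divisor = 32768, detect_threshold = NULL,
                           smooth_sigma = 1, ws_tolerance = NULL) {
  stopifnot(length(intensity_range) == 2L,
            intensity_range[1] <= intensity_range[2], mean_area > 0)
  structure(list(intensity_range = intensity_range, mean_area = mean_area,
                 area_tol = area_tol, area_gate = area_gate,
                 au_divisor = au_divisor, detect_threshold = detect_threshold,
                 smooth_sigma = smooth_sigma, ws_tolerance = ws_tolerance),
            class = "NucleusParams")
}

#' Cell-simulation parameters
#'
#' @param membrane_channel membrane channel name (e.g. `"FITC"` for CD45,
#'   `"CY3"` for CD3).
#' @param membrane_threshold delimitation threshold in grey-value levels
#'   (CD45 default 1600; for CD3 the delimitation band lower bound 48356 is
#'   the analogous setting).
#' @param mean_cell_area mean simulated cell area in um^2 (CD45 default 38).
#' @param area_tol growth tolerance above the mean area (default 5 um^2).
#' @param mode `"inside_cytoplasmic_stain"` (membrane-guided growth,
#'   default) or `"growth_from_nuclei"` (isotropic dilation ignoring the
#'   membrane signal, the fallback for weak membrane staining).
#' @return a list of class `CellParams`.
#' @export
cell_params <- function(membrane_channel = "FITC", membrane_threshold = 1600,
                        mean_cell_area = 38, area_tol = 5,
                        mode = c("inside_cytoplasmic_stain", "growth_from_nuclei")) {
  mode <- match.arg(mode)
  stopifnot(mean_cell_area > 0, membrane_threshold >= 0)
  structure(list(membrane_channel = membrane_channel,
                 membrane_threshold = membrane_threshold,
                 mean_cell_area = mean_cell_area, area_tol = area_tol,
                 mode = mode),
            class = "CellParams")
}

#' Cell-classification thresholds
#'
#' @param nuclear_min minimal nuclear-channel mean over the nucleus, in
#'   g.v.l (single-staining default 1000; double-staining 500).
#' @param marker_min named vector of minimal marker-channel means over the
#'   cell, in g.v.l (single: `c(FITC = 1300)`; double:
#'   `c(CY3 = 2500, FITC = 1500)`).
#' @param intensity_max maximum representable intensity (default 65536).
#' @return a list of class `ClassificationThresholds`.
#' @export
classification_thresholds <- function(nuclear_min = 1000,
                                      marker_min = c(FITC = 1300),
                                      intensity_max = 65536) {
  stopifnot(nuclear_min >= 0, all(marker_min >= 0),
            nuclear_min <= intensity_max, all(marker_min <= intensity_max))
  structure(list(nuclear_min = nuclear_min, marker_min = marker_min,
                 intensity_max = intensity_max),
            class = "ClassificationThresholds")
}

#' Phenotyping scheme
#'
#' `single_CD45` labels cells `positive`/`negative` by DAPI and CD45
#' (FITC) co-staining. `double_CD3_CD4` assigns one of `CD3-CD4+`,
#' `CD3+CD4-`, `CD3+CD4+`, `CD3-CD4-` by Cy3 (CD3) and FITC (CD4) means,
#' gated on the nuclear stain.
#'
#' @param name `"single_CD45"` or `"double_CD3_CD4"`.
#' @param nuclear_channel nuclear channel name (default `"DAPI"`).
#' @param marker_channels named map marker -> channel; defaults
#'   `c(CD45 = "FITC")` or `c(CD3 = "CY3", CD4 = "FITC")`.
#' @return a list of class `PhenotypeScheme` with fields `classes` and
#'   `positive_classes` (the classes counting as marker-positive).
#' @export
phenotype_scheme <- function(name = c("single_CD45", "double_CD3_CD4"),
                             nuclear_channel = "DAPI",
                             marker_channels = NULL) {
  name <- match.arg(name)
  if (name == "single_CD45") {
    if (is.null(marker_channels)) marker_channels <- c(CD45 = "FITC")
    classes <- c("positive", "negative")
    positive <- "positive"
  } else {
    if (is.null(marker_channels)) marker_channels <- c(CD3 = "CY3", CD4 = "FITC")
    classes <- c("CD3-CD4+", "CD3+CD4-", "CD3+CD4+", "CD3-CD4-")
    positive <- c("CD3-CD4+", "CD3+CD4-", "CD3+CD4+")
  }
  structure(list(name = name, nuclear_channel = nuclear_channel,
                 marker_channels = marker_channels, classes = classes,
                 positive_classes = positive),
            class = "PhenotypeScheme")
}

# connected same-class components of a class mask -> per-pixel roi object id
roi_object_map <- function(roi) {
  lab <- roi$labels
  obj <- matrix(0L, nrow(lab), ncol(lab))
  obj_class <- character(0)
  off <- 0L
  for (code in sort(unique(lab[lab > 0L]))) {
    cc <- EBImage::imageData(EBImage::bwlabel(
      EBImage::Image(matrix(as.numeric(lab == code), nrow(lab)))))
    nz <- cc > 0
    obj[nz] <- as.integer(cc[nz]) + off
    ncc <- max(cc)
    obj_class <- c(obj_class, rep(unname(roi$legend[as.character(code)]), ncc))
    off <- off + as.integer(ncc)
  }
  list(obj = obj, class = obj_class)
}

#' Detect nuclei inside selected regions
#'
#' Smoothed-threshold detection on the nuclear channel (expressed in a.u.)
#' followed by distance-transform watershed splitting, with the mean-area
#' prior setting the watershed tolerance; components outside the hard area
#' gates are rejected. Detection is restricted to the listed region
#' classes.
#'
#' @param x a `Slide` with a nuclear channel.
#' @param roi a class `LabelMask` (e.g. from [roi_mask()], upscaled to the
#'   slide resolution), or `NULL` to analyze the whole slide.
#' @param iroi_classes classes in which to detect (default all non-`bis`,
#'   non-background classes present).
#' @param params a [nucleus_params()] object.
#' @param nuclear_channel channel name (default `"DAPI"`).
#' @return a `NucleusSet`: integer label image plus a table of id, pixel
#'   count, area (um^2) and centroid.
#' @export
detect_nuclei <- function(x, roi = NULL, iroi_classes = NULL,
                          params = nucleus_params(),
                          nuclear_channel = "DAPI") {
  stopifnot(inherits(x, "Slide"), inherits(params, "NucleusParams"))
  if (!nuclear_channel %in% names(x$channels))
    stop(sprintf("no nuclear channel '%s' in slide", nuclear_channel))
  ch <- x$channels[[nuclear_channel]]
  au <- ch / params$au_divisor
  allowed <- if (is.null(roi)) {
    matrix(TRUE, nrow(ch), ncol(ch))
  } else {
    cls <- mask_classes(roi)
    if (is.null(iroi_classes))
      iroi_classes <- setdiff(unique(roi$legend),
                              c("background", roi$legend[is_bis(roi$legend)]))
    if (!all(iroi_classes %in% roi$legend))
      stop("iroi_classes not all present in the ROI legend")
    !is.na(cls) & cls %in% iroi_classes
  }
  sm <- if (params$smooth_sigma > 0)
    EBImage::imageData(EBImage::gblur(EBImage::Image(au), sigma = params$smooth_sigma))
  else au
  thr <- params$detect_threshold
  if (is.null(thr)) {
    v <- sm[allowed & au >= params$intensity_range[1] &
              au <= params$intensity_range[2]]
    thr <- if (length(v) && any(v > 0))
      EBImage::otsu(EBImage::Image(matrix(v, ncol = 1)),
                    range = params$intensity_range)
    else Inf
  }
  m <- allowed & sm >= thr & au >= params$intensity_range[1] &
    au <= params$intensity_range[2]
  nr <- nrow(ch); nc <- ncol(ch)
  if (!any(m)) return(nucleus_set(matrix(0L, nr, nc), x))
  d <- EBImage::distmap(EBImage::Image(matrix(as.numeric(m), nr)))
  r_px <- sqrt(params$mean_area / pi) / x$pixel_size
  tol <- if (is.null(params$ws_tolerance)) max(1, 0.05 * r_px) else params$ws_tolerance
  lab <- EBImage::imageData(EBImage::watershed(d, tolerance = tol, ext = 1))
  storage.mode(lab) <- "integer"
  lab <- split_by_area_prior(lab, x$pixel_size, params$mean_area)
  sizes <- tabulate(lab[lab > 0L])
  areas <- area_um2(sizes, x$pixel_size)
  keep <- which(areas >= params$area_gate[1] & areas <= params$area_gate[2])
  remap <- integer(length(sizes))
  remap[keep] <- seq_along(keep)
  nz <- lab > 0L
  lab[nz] <- remap[lab[nz]]
  nucleus_set(lab, x)
}

# second-stage splitting driven by the mean-area prior: any component far
# larger than the prior (>= 1.35x, beyond plausible single-nucleus
# variation) is a fused clump the watershed failed to separate; it is split into
# round(area / mean_area) parts by deterministic Lloyd clustering of its
# pixel coordinates (farthest-point initialization, no RNG).
split_by_area_prior <- function(lab, pixel_size, mean_area) {
  sizes <- tabulate(lab[lab > 0L])
  if (!length(sizes)) return(lab)
  areas <- area_um2(sizes, pixel_size)
  big <- which(areas >= 1.35 * mean_area)
  if (!length(big)) return(lab)
  nr <- nrow(lab)
  nxt <- length(sizes)
  for (i in big) {
    idx <- which(lab == i)
    k <- max(2L, as.integer(round(areas[i] / mean_area)))
    pts <- cbind((idx - 1L) %% nr + 1, (idx - 1L) %/% nr + 1)
    ctr <- pts[1, , drop = FALSE]
    d2 <- (pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2
    while (nrow(ctr) < k) {
      j <- which.max(d2)
      ctr <- rbind(ctr, pts[j, ])
      d2 <- pmin(d2, (pts[, 1] - pts[j, 1])^2 + (pts[, 2] - pts[j, 2])^2)
    }
    km <- suppressWarnings(stats::kmeans(pts, centers = ctr, iter.max = 50,
                                         algorithm = "Lloyd"))
    cl <- km$cluster
    lab[idx[cl > 1L]] <- nxt + as.integer(cl[cl > 1L]) - 1L
    nxt <- nxt + k - 1L
  }
  lab
}

# package a nucleus label image with its summary table
nucleus_set <- function(labels, x) {
  storage.mode(labels) <- "integer"
  n <- max(0L, max(labels))
  tab <- if (n == 0L) {
    data.frame(id = integer(), n_px = integer(), area_um2 = numeric(),
               row = numeric(), col = numeric())
  } else {
    idx <- which(labels > 0L)
    ids <- labels[idx]
    rr <- (idx - 1L) %% nrow(labels) + 1L
    cc <- (idx - 1L) %/% nrow(labels) + 1L
    npx <- tabulate(ids, nbins = n)
    data.frame(id = seq_len(n), n_px = npx,
               area_um2 = area_um2(npx, x$pixel_size),
               row = rowsum_by(as.numeric(rr), ids, n) / npx,
               col = rowsum_by(as.numeric(cc), ids, n) / npx)
  }
  structure(list(labels = labels, table = tab, pixel_size = x$pixel_size),
            class = "NucleusSet")
}

#' @export
print.NucleusSet <- function(x, ...) {
  cat(sprintf("NucleusSet: %d nuclei, mean area %.1f um^2\n",
              nrow(x$table), mean(x$table$area_um2)))
  invisible(x)
}

#' Simulate cell bodies around detected nuclei
#'
#' In `inside_cytoplasmic_stain` mode each cell grows from its nucleus into
#' contiguous membrane pixels at or above the delimitation threshold, by
#' simultaneous competitive growth (no pixel is ever claimed twice), capped
#' at `mean_cell_area + area_tol`; a nucleus with no qualifying membrane
#' signal keeps its nucleus footprint as the cell. In `growth_from_nuclei`
#' mode cells dilate isotropically to `mean_cell_area` ignoring the
#' membrane signal. Cells never cross region-class borders when a region
#' mask is supplied.
#'
#' @param nuclei a `NucleusSet`.
#' @param x the `Slide`.
#' @param params a [cell_params()] object.
#' @param roi optional class `LabelMask` at slide resolution; growth is
#'   confined to the nucleus's region and each cell is assigned to a region
#'   object (majority of cell pixels; ties resolved by the nucleus
#'   centroid).
#' @param nuclear_channel nuclear channel name for per-cell means.
#' @return a `CellSet`: cell table (areas, per-channel means over nucleus
#'   and cell, region membership) plus nucleus and cell label images.
#' @export
simulate_cells <- function(nuclei, x, params = cell_params(), roi = NULL,
                           nuclear_channel = "DAPI") {
  stopifnot(inherits(nuclei, "NucleusSet"), inherits(x, "Slide"),
            inherits(params, "CellParams"))
  if (!params$membrane_channel %in% names(x$channels))
    stop(sprintf("unknown membrane channel '%s'", params$membrane_channel))
  nlab <- nuclei$labels
  nr <- nrow(nlab); nc <- ncol(nlab)
  nn <- nrow(nuclei$table)
  if (nn == 0L)
    return(cell_set(data.frame(), nlab, matrix(0L, nr, nc), x))
  mem <- x$channels[[params$membrane_channel]]
  ps <- x$pixel_size
  grow <- if (params$mode == "inside_cytoplasmic_stain") {
    nlab > 0L | mem >= params$membrane_threshold
  } else {
    matrix(TRUE, nr, nc)
  }
  romap <- NULL
  nuc_code <- NULL
  if (!is.null(roi)) {
    romap <- roi_object_map(roi)
    # majority region-class code of each nucleus; growth stays within it
    idxn <- which(nlab > 0L)
    agg <- tapply(roi$labels[idxn], nlab[idxn], function(o) {
      o <- o[o > 0L]
      if (!length(o)) 0L else as.integer(names(which.max(table(o))))
    })
    nuc_code <- integer(nn)
    nuc_code[as.integer(names(agg))] <- unlist(agg)
  }
  cap_px <- if (params$mode == "inside_cytoplasmic_stain") {
    max(1L, as.integer(round((params$mean_cell_area + params$area_tol) / ps^2)))
  } else {
    max(1L, as.integer(round(params$mean_cell_area / ps^2)))
  }
  hi <- 2^x$bit_depth - 1
  clab <- EBImage::imageData(EBImage::propagate(
    EBImage::Image(mem / hi), EBImage::Image(nlab), mask = grow, lambda = 1e-2))
  storage.mode(clab) <- "integer"
  # region-border enforcement: drop claimed pixels outside the nucleus's class
  if (!is.null(roi)) {
    nzc <- which(clab > 0L)
    bad <- roi$labels[nzc] != nuc_code[clab[nzc]]
    if (any(bad)) clab[nzc[bad]] <- 0L
  }
  # competitive growth can only be capped afterwards: keep the pixels
  # nearest to the own nucleus, then the connected piece holding the nucleus
  D <- EBImage::imageData(EBImage::distmap(
    EBImage::Image(matrix(as.numeric(nlab == 0L), nr))))
  idx <- which(clab > 0L)
  ids <- clab[idx]
  npx <- tabulate(ids, nbins = nn)
  over <- which(npx > cap_px)
  for (i in over) {
    pix <- idx[ids == i]
    keep <- pix[order(D[pix], pix)][seq_len(cap_px)]   # deterministic tie-break
    clab[setdiff(pix, keep)] <- 0L
  }
  # enforce contiguity with the nucleus
  clab <- keep_nucleus_component(clab, nlab, nn)
  # nuclei must be inside their cell footprint
  nzn <- nlab > 0L
  clab[nzn] <- nlab[nzn]
  build_cell_table(clab, nlab, x, romap, nuclear_channel)
}

# for each cell keep only the connected component containing its nucleus
keep_nucleus_component <- function(clab, nlab, nn) {
  idx <- which(clab > 0L)
  if (!length(idx)) return(clab)
  ids <- clab[idx]
  nr <- nrow(clab)
  rr <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  for (i in seq_len(nn)) {
    sel <- ids == i
    if (!any(sel)) next
    r0 <- range(rr[sel]); c0 <- range(cc[sel])
    sub <- matrix(0, r0[2] - r0[1] + 1L, c0[2] - c0[1] + 1L)
    sub[cbind(rr[sel] - r0[1] + 1L, cc[sel] - c0[1] + 1L)] <- 1
    lb <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(sub)))
    if (max(lb) <= 1) next
    nsel <- which(nlab[idx[sel]] == i)
    comp <- if (length(nsel)) {
      lb[cbind(rr[sel][nsel[1]] - r0[1] + 1L, cc[sel][nsel[1]] - c0[1] + 1L)]
    } else {
      as.integer(names(which.max(table(lb[lb > 0]))))
    }
    off <- lb[cbind(rr[sel] - r0[1] + 1L, cc[sel] - c0[1] + 1L)] != comp
    clab[idx[sel][off]] <- 0L
  }
  clab
}

# assemble the per-cell record table
build_cell_table <- function(clab, nlab, x, romap, nuclear_channel) {
  nn <- max(0L, max(nlab))
  nr <- nrow(clab)
  idxc <- which(clab > 0L)
  idxn <- which(nlab > 0L)
  cids <- clab[idxc]; nids <- nlab[idxn]
  npx_c <- tabulate(cids, nbins = nn)
  npx_n <- tabulate(nids, nbins = nn)
  present <- which(npx_n > 0L)
  ps <- x$pixel_size
  rr <- (idxc - 1L) %% nr + 1L
  cc <- (idxc - 1L) %/% nr + 1L
  tab <- data.frame(id = seq_len(nn),
                    nucleus_area_um2 = area_um2(npx_n, ps),
                    cell_area_um2 = area_um2(npx_c, ps),
                    row = rowsum_by(as.numeric(rr), cids, nn) / pmax(npx_c, 1),
                    col = rowsum_by(as.numeric(cc), cids, nn) / pmax(npx_c, 1))
  for (nm in names(x$channels)) {
    v <- as.numeric(x$channels[[nm]])
    tab[[paste0("mean_", nm, "_nucleus")]] <-
      rowsum_by(v[idxn], nids, nn) / pmax(npx_n, 1)
    tab[[paste0("mean_", nm, "_cell")]] <-
      rowsum_by(v[idxc], cids, nn) / pmax(npx_c, 1)
  }
  if (!is.null(romap)) {
    agg <- tapply(romap$obj[idxc], cids, function(o) {
      o <- o[o > 0L]
      if (!length(o)) return(0L)
      tb <- table(o)
      mx <- tb[tb == max(tb)]
      as.integer(names(mx)[1])          # ties: first; refined below by nucleus
    })
    roi_obj <- integer(nn)
    roi_obj[as.integer(names(agg))] <- unlist(agg)
    # tie / empty fallback: region object under the nucleus centroid
    for (i in which(roi_obj == 0L & npx_n > 0L)) {
      r0 <- as.integer(round(tab$row[i])); c0 <- as.integer(round(tab$col[i]))
      if (r0 >= 1 && c0 >= 1 && r0 <= nr && c0 <= ncol(clab))
        roi_obj[i] <- romap$obj[r0, c0]
    }
    tab$roi_object_id <- roi_obj
    tab$roi_class <- ifelse(roi_obj > 0L, romap$class[pmax(roi_obj, 1L)],
                            NA_character_)
  } else {
    tab$roi_object_id <- NA_integer_
    tab$roi_class <- NA_character_
  }
  tab <- tab[present, , drop = FALSE]
  rownames(tab) <- NULL
  cell_set(tab, nlab, clab, x)
}

cell_set <- function(cells, nucleus_labels, cell_labels, x) {
  structure(list(cells = cells, nucleus_labels = nucleus_labels,
                 cell_labels = cell_labels, pixel_size = x$pixel_size,
                 channel_names = names(x$channels)),
            class = "CellSet")
}

#' @export
print.CellSet <- function(x, ...) {
  cat(sprintf("CellSet: %d cells\n", nrow(x$cells)))
  if ("phenotype" %in% names(x$cells)) print(table(x$cells$phenotype))
  invisible(x)
}

#' Suggest preliminary classification thresholds from calibration fields
#'
#' The nuclear minimum is the lowest robust nuclear intensity (5th
#' percentile of per-nucleus means) across positively stained fields; each
#' marker minimum is the highest robust background intensity (99.5th
#' percentile of marker pixels) across no-primary-antibody control fields.
#' These are starting points; the stored configuration remains the
#' authoritative thresholds.
#'
#' @param positive_fields list of `Slide`s with genuine staining.
#' @param control_fields list of control `Slide`s without primary antibody.
#' @param marker_channels character vector of marker channel names.
#' @param nuclear_channel nuclear channel name.
#' @param params [nucleus_params()] used to detect nuclei in the positive
#'   fields.
#' @return a [classification_thresholds()] object.
#' @export
calibrate_thresholds <- function(positive_fields, control_fields,
                                 marker_channels = "FITC",
                                 nuclear_channel = "DAPI",
                                 params = nucleus_params()) {
  if (!length(positive_fields) || !length(control_fields))
    stop("at least one positive and one control field are required")
  nuc_stat <- vapply(positive_fields, function(f) {
    ns <- detect_nuclei(f, roi = NULL, params = params,
                        nuclear_channel = nuclear_channel)
    if (nrow(ns$table) == 0L) return(0)
    idx <- which(ns$labels > 0L)
    ids <- ns$labels[idx]
    mu <- rowsum_by(as.numeric(f$channels[[nuclear_channel]][idx]), ids,
                    nrow(ns$table)) / ns$table$n_px
    stats::quantile(mu, 0.05, names = FALSE)
  }, numeric(1))
  marker_min <- vapply(marker_channels, function(ch) {
    max(vapply(control_fields, function(f)
      stats::quantile(as.numeric(f$channels[[ch]]), 0.995, names = FALSE),
      numeric(1)))
  }, numeric(1))
  message(sprintf(
    "suggested thresholds (starting points): nuclear_min %.0f g.v.l; %s",
    min(nuc_stat),
    paste(sprintf("%s %.0f g.v.l", names(marker_min), marker_min),
          collapse = ", ")))
  classification_thresholds(nuclear_min = min(nuc_stat),
                            marker_min = marker_min)
}

#' Assign a phenotype to every cell by co-staining thresholds
#'
#' All comparisons are inclusive (`>=`). A cell is marker-positive only if
#' its nuclear mean passes `nuclear_min` *and* the marker mean over the
#' cell passes the marker threshold — the co-staining gate that keeps
#' fluorochrome aggregates (membrane signal without a nucleus) out of the
#' positive class.
#'
#' @param cells a `CellSet`.
#' @param thresholds a [classification_thresholds()] object.
#' @param scheme a [phenotype_scheme()] object.
#' @return the `CellSet` with a `phenotype` column filled; every cell gets
#'   exactly one label from the scheme.
#' @export
classify_cells <- function(cells, thresholds, scheme) {
  stopifnot(inherits(cells, "CellSet"),
            inherits(thresholds, "ClassificationThresholds"),
            inherits(scheme, "PhenotypeScheme"))
  tb <- cells$cells
  if (nrow(tb) == 0L) {
    cells$cells$phenotype <- character(0)
    return(cells)
  }
  need <- unname(c(scheme$nuclear_channel, scheme$marker_channels))
  have <- cells$channel_names
  if (!all(need %in% have))
    stop(sprintf("scheme channel(s) missing from slide: %s",
                 paste(setdiff(need, have), collapse = ", ")))
  nuc <- tb[[paste0("mean_", scheme$nuclear_channel, "_nucleus")]]
  nuc_ok <- nuc >= thresholds$nuclear_min
  marker_pos <- sapply(names(scheme$marker_channels), function(mk) {
    ch <- scheme$marker_channels[[mk]]
    thr <- thresholds$marker_min[[ch]]
    if (is.null(thr) || is.na(thr))
      stop(sprintf("no marker threshold for channel '%s'", ch))
    tb[[paste0("mean_", ch, "_cell")]] >= thr
  })
  marker_pos <- matrix(marker_pos, nrow = nrow(tb),
                       dimnames = list(NULL, names(scheme$marker_channels)))
  if (scheme$name == "single_CD45") {
    tb$phenotype <- ifelse(nuc_ok & marker_pos[, "CD45"], "positive", "negative")
  } else {
    cd3 <- nuc_ok & marker_pos[, "CD3"]
    cd4 <- nuc_ok & marker_pos[, "CD4"]
    tb$phenotype <- paste0("CD3", ifelse(cd3, "+", "-"),
                           "CD4", ifelse(cd4, "+", "-"))
  }
  cells$cells <- tb
  cells
}

#' Exclude artifact and edge cells, with a reason log
#'
#' Applies, in order: (i) the co-staining gate is structural — membrane
#' blobs without a nucleus never become cells, asserted here; (ii) cells
#' whose centroid lies in a `*_bis` edge class are removed from all counts
#' (their region's `bis` area still enters density denominators, handled in
#' [summarize_density()]); (iii) cells below the minimal cell area are
#' dropped.
#'
#' @param cells a classified `CellSet`.
#' @param roi optional class `LabelMask` for the `*_bis` check.
#' @param min_cell_area minimal cell area in um^2 (default 10).
#' @return list with `cells` (filtered `CellSet`) and `log` (data frame
#'   `id`, `reason` with reasons `edge_exclusion` / `below_min_area`).
#' @export
exclude_artifacts <- function(cells, roi = NULL, min_cell_area = 10) {
  stopifnot(inherits(cells, "CellSet"))
  tb <- cells$cells
  stopifnot(all(tb$nucleus_area_um2 > 0))   # co-staining gate: every cell has a nucleus
  drop <- logical(nrow(tb))
  reason <- character(nrow(tb))
  if (!is.null(roi) && nrow(tb)) {
    r0 <- pmin(pmax(as.integer(round(tb$row)), 1L), nrow(roi$labels))
    c0 <- pmin(pmax(as.integer(round(tb$col)), 1L), ncol(roi$labels))
    code <- roi$labels[cbind(r0, c0)]
    cls <- ifelse(code > 0L, unname(roi$legend[as.character(code)]), NA)
    bis <- !is.na(cls) & is_bis(cls)
    drop[bis] <- TRUE
    reason[bis] <- "edge_exclusion"
  }
  small <- !drop & tb$cell_area_um2 < min_cell_area
  drop[small] <- TRUE
  reason[small] <- "below_min_area"
  log <- data.frame(id = tb$id[drop], reason = reason[drop])
  if (any(drop)) {
    gone <- tb$id[drop]
    cells$cells <- tb[!drop, , drop = FALSE]
    cells$cell_labels[cells$cell_labels %in% gone] <- 0L
    cells$nucleus_labels[cells$nucleus_labels %in% gone] <- 0L
  }
  list(cells = cells, log = log)
}

#' Upscale a label mask by an integer factor (block replication)
#' @param mask a `LabelMask`.
#' @param factor integer upscale factor.
#' @return a `LabelMask` at `factor`-times resolution; class areas in um^2
#'   are preserved exactly when the pixel size is divided by `factor`.
#' @export
upscale_mask <- function(mask, factor) {
  stopifnot(inherits(mask, "LabelMask"), factor >= 1, factor == round(factor))
  if (factor == 1) return(mask)
  up <- mask$labels %x% matrix(1L, factor, factor)
  label_mask(up, mask$legend)
}
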