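#' Partition detected tissue into primitive objects
#'
#' Primitive objects are the atomic units of object-based image analysis:
#' small, edge-respecting pixel clusters whose target mean area is
#' controlled by a dimensionless scale index. Seeds are laid on a hexagonal
#' grid with spacing derived from the target area `base_area / scale^2`
#' (um^2) and grown by seeded region growing on the guide channel within
#' the tissue mask, so object boundaries follow strong intensity edges.
#' Mask components that receive no seed become objects of their own, so the
#' result always tiles the mask exactly.
#'
#' @param x a [slide()] object.
#' @param mask a binary `LabelMask` from [detect_tissue()].
#' @param scale dimensionless segmentation scale (> 0); higher values give
#'   smaller primitives (default 4).
#' @param base_area base object area in um^2 at scale 1 (default 1024,
#'   giving ~64 um^2 primitives at scale 4).
#' @param guide_channel channel steering the region growing (default the
#'   first channel).
#' @param lambda regularization of the growing metric: small values follow
#'   intensity edges tightly, large values give near-Voronoi cells.
#' @return an `ObjectLayer`: integer label image (0 outside tissue), a
#'   per-object feature table (populated by [compute_features()]), the
#'   object boundary-contact table and the segmentation scale.
#' @export
segment_primitives <- function(x, mask, scale = 4, base_area = 1024,
                               guide_channel = names(x$channels)[1],
                               lambda = 1e-4) {
  stopifnot(inherits(x, "Slide"), inherits(mask, "LabelMask"))
  if (scale <= 0) stop("'scale' must be > 0")
  if (!identical(dim(x$channels[[1]]), dim(mask$labels)))
    stop("slide and mask dimensions differ")
  m <- mask$labels != 0L
  nr <- nrow(m); nc <- ncol(m)
  if (!any(m)) {
    return(object_layer(matrix(0L, nr, nc), scale, x))
  }
  target_px <- max((base_area / scale^2) / x$pixel_size^2, 4)
  s <- sqrt(2 * target_px / sqrt(3))            # hex grid spacing, px
  dy <- s * sqrt(3) / 2
  rows <- seq(1 + dy / 2, nr, by = dy)
  seeds <- matrix(0L, nr, nc)
  id <- 0L
  for (k in seq_along(rows)) {
    off <- if (k %% 2 == 0) s / 2 else 0
    cols <- seq(1 + s / 2 + off, nc, by = s)
    ri <- as.integer(round(rows[k]))
    ci <- as.integer(round(cols))
    ci <- ci[ci >= 1 & ci <= nc]
    for (cj in ci) {
      if (m[ri, cj]) {
        id <- id + 1L
        seeds[ri, cj] <- id
      }
    }
  }
  hi <- 2^x$bit_depth - 1
  guide <- x$channels[[guide_channel]] / hi
  lab <- if (id > 0L) {
    EBImage::imageData(EBImage::propagate(
      EBImage::Image(guide), EBImage::Image(seeds), mask = m, lambda = lambda))
  } else matrix(0L, nr, nc)
  storage.mode(lab) <- "integer"
  # mask pixels missed by the growing (seedless components) become objects
  orphan <- m & lab == 0L
  if (any(orphan)) {
    ol <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(matrix(as.numeric(orphan), nr))))
    lab[orphan] <- as.integer(ol[orphan]) + max(lab)
  }
  # relabel contiguously 1..n (propagate can drop seed ids)
  u <- sort(unique(lab[lab > 0L]))
  remap <- integer(max(u)); remap[u] <- seq_along(u)
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  object_layer(lab, scale, x)
}

# internal constructor: label image -> ObjectLayer skeleton
object_layer <- function(labels, scale, x) {
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, scale = scale,
                 pixel_size = x$pixel_size,
                 channel_names = names(x$channels),
                 features = NULL, boundary = NULL),
            class = "ObjectLayer")
}

#' @export
print.ObjectLayer <- function(x, ...) {
  n <- max(x$labels)
  cat(sprintf("ObjectLayer: %d primitive objects at scale %g (%s features)\n",
              n, x$scale, if (is.null(x$features)) "no" else "with"))
  invisible(x)
}

#' Number of primitive objects in a layer
#' @param layer an `ObjectLayer`.
#' @return integer count.
#' @export
n_objects <- function(layer) max(0L, max(layer$labels))

# contact table between labels across 4-connected pixel edges.
# Returns data.frame(a, b, n): for object a, n pixel-edges shared with b
# (b = 0 encodes the mask border / image edge). Directional: both (a,b)
# and (b,a) rows are present for object-object contacts.
boundary_contacts <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  a <- c(labels[, -nc], labels[-nr, ])
  b <- c(labels[, -1],  labels[-1, ])
  d <- a != b
  a1 <- a[d]; b1 <- b[d]
  A <- c(a1, b1); B <- c(b1, a1)
  keep <- A > 0L
  A <- A[keep]; B <- B[keep]
  # image-edge exposure counts as mask border
  edge <- c(labels[1, ], labels[nr, ], labels[, 1], labels[, nc])
  edge <- edge[edge > 0L]
  A <- c(A, edge); B <- c(B, integer(length(edge)))
  if (!length(A)) return(data.frame(a = integer(), b = integer(), n = integer()))
  key <- as.numeric(A) * (max(A, B) + 1) + B
  cnt <- tapply(rep.int(1L, length(key)), key, sum)
  k <- as.numeric(names(cnt))
  base <- max(A, B) + 1
  data.frame(a = as.integer(k %/% base), b = as.integer(k %% base),
             n = as.integer(cnt), row.names = NULL)
}

#' Compute per-object features of a primitive-object layer
#'
#' Populates, for every primitive object: pixel count, area (um^2),
#' perimeter (um), compactness `4*pi*area/perimeter^2` (clamped to 1 for
#' tiny rasterized objects), per-channel mean and standard deviation
#' (grey-value levels), heterogeneity (coefficient of variation of the
#' nuclear channel), local nuclear density (nuclei per mm^2 within a
#' `density_radius_um` neighborhood, estimated from nuclear coverage; a texture/complexity
#' feature usable in rules), per-channel contextual (neighborhood-mean)
#' intensities, the neighbor contact table and the neighbor id list.
#'
#' @param layer an `ObjectLayer`.
#' @param x the originating `Slide`.
#' @param nuclear_channel channel used for heterogeneity and local density
#'   (default the first channel).
#' @param density_radius_um neighborhood radius for local density and the
#'   contextual means (default 25).
#' @return the layer with `features` and `boundary` populated.
#' @export
compute_features <- function(layer, x, nuclear_channel = layer$channel_names[1],
                             density_radius_um = 25) {
  stopifnot(inherits(layer, "ObjectLayer"), inherits(x, "Slide"))
  if (!identical(dim(layer$labels), dim(x$channels[[1]])))
    stop("layer and slide dimensions differ")
  lab <- layer$labels
  n <- n_objects(layer)
  ps <- x$pixel_size
  if (n == 0L) {
    layer$features <- data.frame(id = integer())
    layer$boundary <- data.frame(a = integer(), b = integer(), n = integer())
    return(layer)
  }
  idx <- which(lab > 0L)
  ids <- lab[idx]
  npx <- tabulate(ids, nbins = n)
  shp <- EBImage::computeFeatures.shape(EBImage::Image(lab))
  perim_px <- numeric(n)
  perim_px[as.integer(rownames(shp))] <- shp[, "s.perimeter"]
  area <- area_um2(npx, ps)
  perim <- perim_px * ps
  compact <- pmin(4 * pi * area / pmax(perim, 1e-9)^2, 1)
  feats <- data.frame(id = seq_len(n), n_px = npx, area = area,
                      perimeter = perim, compactness = compact)
  for (nm in layer$channel_names) {
    v <- as.numeric(x$channels[[nm]][idx])
    s1 <- rowsum_by(v, ids, n)
    s2 <- rowsum_by(v^2, ids, n)
    mu <- s1 / npx
    va <- pmax(s2 / npx - mu^2, 0)
    feats[[paste0("mean_", nm)]] <- mu
    feats[[paste0("sd_", nm)]] <- sqrt(va)
  }
  mu_n <- feats[[paste0("mean_", nuclear_channel)]]
  feats$heterogeneity <- feats[[paste0("sd_", nuclear_channel)]] / pmax(mu_n, 1e-9)
  dens_map <- nuclear_blob_density(x, nuclear_channel, density_radius_um)
  feats$local_density <- rowsum_by(as.numeric(dens_map[idx]), ids, n) / npx
  # contextual features: per-channel neighborhood mean intensity. Primitive
  # objects hold only a couple of cells, so their own channel means are
  # dominated by nucleus-coverage noise; the neighborhood mean carries the
  # stable regional signature (diffuse background level, staining density).
  r_px <- max(1, round(density_radius_um / x$pixel_size))
  r_px <- min(r_px, (min(dim(lab)) - 1) %/% 2)   # clamp for small frames
  k <- EBImage::makeBrush(2 * r_px + 1, shape = "disc")
  k <- k / sum(k)
  for (nm in layer$channel_names) {
    ctx <- EBImage::imageData(EBImage::filter2(
      EBImage::Image(x$channels[[nm]]), k, boundary = "replicate"))
    feats[[paste0("context_", nm)]] <-
      rowsum_by(as.numeric(ctx[idx]), ids, n) / npx
  }
  layer$features <- feats
  layer$boundary <- boundary_contacts(lab)
  layer
}

# rowsum over integer group ids 1..n, returning a dense numeric vector
rowsum_by <- function(v, ids, n) {
  out <- numeric(n)
  s <- rowsum(v, ids)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

# local nuclear density map (nuclei/mm^2) within a disk neighborhood,
# estimated as the local bright-pixel (nuclear) coverage divided by the
# mean nuclear footprint; robust to fused nuclei in dense regions. Used as
# the "tissue complexity/density" rule feature.
nuclear_blob_density <- function(x, channel, radius_um,
                                 mean_nucleus_area_um2 = 35) {
  ch <- x$channels[[channel]]
  hi <- 2^x$bit_depth - 1
  thr <- EBImage::otsu(EBImage::Image(ch / hi), range = c(0, 1)) * hi
  bright <- matrix(as.numeric(ch >= thr), nrow(ch))
  r_px <- max(1, round(radius_um / x$pixel_size))
  r_px <- min(r_px, (min(dim(ch)) - 1) %/% 2)    # clamp for small frames
  k <- EBImage::makeBrush(2 * r_px + 1, shape = "disc")
  cov <- EBImage::imageData(EBImage::filter2(EBImage::Image(bright), k,
                                             boundary = 0)) / sum(k)
  pmax(cov, 0) * 1e6 / mean_nucleus_area_um2
}

#' Neighbor ids of a primitive object
#' @param layer an `ObjectLayer` with features computed.
#' @param id object id.
#' @return integer vector of adjacent object ids (mask border excluded).
#' @export
object_neighbors <- function(layer, id) {
  b <- layer$boundary
  sort(unique(b$b[b$a == id & b$b > 0L]))
}

#' Relative border fractions of primitive objects against a class map
#'
#' For object `i`, the fraction of its boundary contact length shared with
#' objects of each class; the remainder (1 minus the row sum) is contact
#' with the mask border.
#'
#' @param layer an `ObjectLayer` with boundary computed.
#' @param class_of character vector: class of each object id.
#' @return matrix objects x classes of fractions in `[0, 1]`.
#' @export
relative_border <- function(layer, class_of) {
  b <- layer$boundary
  n <- n_objects(layer)
  classes <- sort(unique(class_of))
  out <- matrix(0, n, length(classes), dimnames = list(NULL, classes))
  tot <- rowsum_by(as.numeric(b$n), b$a, n)
  obj <- b$b > 0L
  for (cl in classes) {
    sel <- obj
    sel[obj] <- class_of[b$b[obj]] == cl
    if (any(sel))
      out[, cl] <- rowsum_by(as.numeric(b$n[sel]), b$a[sel], n) / pmax(tot, 1)
  }
  out
}
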