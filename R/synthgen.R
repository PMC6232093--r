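#' Configuration of the synthetic colon-slide generator
#'
#' The generator emulates a stained colon section on a dark background:
#' a textured mucosal band in which dense round lymphoid-follicle nuclear
#' clusters and an irregular tumor blob are embedded, an other-tissue
#' (submucosa/muscularis) band, a DAPI nuclear channel with ~35 um^2
#' nuclei, membrane channels with ring staining on phenotype-positive
#' cells, background noise, fluorochrome-aggregate artifacts and optional
#' tissue-edge autofluorescence. Every nucleus, phenotype and artifact is
#' recorded as exact ground truth.
#'
#' Default positive densities are the region means reported for CD45+
#' leucocytes in the APC(Min/+) colon: lymphoid follicle 2.10e4, mucosa
#' 2.97e3, tumor 3.22e3 cells/mm^2.
#'
#' @param size image edge in pixels (square; default 2048).
#' @param pixel_size um/pixel (default 0.161028).
#' @param seed integer seed; the generator is fully deterministic given it.
#' @param scheme `"single_CD45"` or `"double_CD3_CD4"` (decides which
#'   membrane channels are rendered).
#' @param positive_density named positives/mm^2 per region.
#' @param positive_fraction named fraction of cells that are
#'   marker-positive per region; total density is
#'   `positive_density / positive_fraction` where the fraction is > 0.
#' @param total_density_other total cells/mm^2 in `other_tissue` (which has
#'   no positives by default).
#' @param double_split for the double scheme: how the positive fraction
#'   splits across CD3+CD4+, CD3+CD4- and CD3-CD4+ (normalized).
#' @param nucleus_area_mean,nucleus_area_sd nucleus area distribution, um^2.
#' @param cell_area_um2 simulated positive-cell footprint area, um^2.
#' @param sep_factor named minimal-separation factors (x nucleus diameter)
#'   per region; the follicle default of 0.7 packs lymphocytes close
#'   enough to produce the blurry, fused DAPI appearance of follicles.
#' @param mucosa_frac,other_frac,margin_frac layout fractions (mucosal band
#'   height, other-tissue band height, background margin).
#' @param n_follicles,follicle_radius_frac follicle disks and their radius
#'   as a fraction of the image edge.
#' @param n_tumors,tumor_radius_frac irregular tumor blobs.
#' @param dapi_base named diffuse DAPI background per region, g.v.l.
#' @param dapi_nucleus_mean,dapi_nucleus_sd nuclear peak intensity, g.v.l.
#' @param nucleus_gain named per-region multiplier on the nuclear peak
#'   (tumor nuclei hyperchromatic, follicle lymphocytes dimmer).
#' @param ring_mean,ring_sd membrane ring intensity, g.v.l.
#' @param noise_sd additive Gaussian noise sd on all channels, g.v.l.
#' @param follicle_blur_sigma extra DAPI blur inside follicles, px.
#' @param n_aggregates fluorochrome-aggregate artifacts (bright membrane
#'   blobs with no nucleus).
#' @param aggregate_intensity,aggregate_area_um2 aggregate rendering.
#' @param edge_autofluorescence render a bright membrane rim along the
#'   tissue border (exercises the `*_bis` edge-exclusion path).
#' @param edge_rim_um,edge_rim_intensity rim geometry and intensity.
#' @return a list of class `SynthConfig`.
#' @export
synth_config <- function(size = 2048L, pixel_size = 0.161028, seed = 42L,
                         scheme = c("single_CD45", "double_CD3_CD4"),
                         positive_density = c(mucosa = 2970,
                                              lymphoid_follicle = 21000,
                                              tumor = 3220,
                                              other_tissue = 0),
                         positive_fraction = c(mucosa = 0.35,
                                               lymphoid_follicle = 1,
                                               tumor = 0.4,
                                               other_tissue = 0),
                         total_density_other = 3000,
                         double_split = c(`CD3+CD4+` = 0.5,
                                          `CD3+CD4-` = 0.35,
                                          `CD3-CD4+` = 0.15),
                         nucleus_area_mean = 35, nucleus_area_sd = 4,
                         cell_area_um2 = 38,
                         sep_factor = c(mucosa = 1, lymphoid_follicle = 0.7,
                                        tumor = 1, other_tissue = 1),
                         mucosa_frac = 0.45, other_frac = 0.2,
                         margin_frac = 0.05,
                         n_follicles = 2L, follicle_radius_frac = 0.11,
                         n_tumors = 1L, tumor_radius_frac = 0.15,
                         dapi_base = c(mucosa = 1500,
                                       lymphoid_follicle = 2600,
                                       tumor = 3500, other_tissue = 1100,
                                       background = 0),
                         dapi_nucleus_mean = 22000, dapi_nucleus_sd = 2500,
                         nucleus_gain = c(mucosa = 1,
                                          lymphoid_follicle = 0.9,
                                          tumor = 1.45, other_tissue = 1),
                         ring_mean = 9000, ring_sd = 1200,
                         noise_sd = 120, follicle_blur_sigma = 0.8,
                         n_aggregates = 6L, aggregate_intensity = 25000,
                         aggregate_area_um2 = 20,
                         edge_autofluorescence = FALSE,
                         edge_rim_um = 4, edge_rim_intensity = 6000) {
  scheme <- match.arg(scheme)
  stopifnot(all(positive_density >= 0), all(positive_fraction >= 0),
            all(positive_fraction <= 1), nucleus_area_mean > 0,
            size >= 256, pixel_size > 0)
  cfg <- as.list(environment())
  structure(cfg, class = "SynthConfig")
}

# region class codes used by the generator's ground-truth mask
synth_legend <- c(`1` = "mucosa", `2` = "lymphoid_follicle", `3` = "tumor",
                  `4` = "other_tissue", `5` = "background")

# total cell density per region implied by the config
synth_total_density <- function(cfg) {
  pd <- cfg$positive_density; pf <- cfg$positive_fraction
  tot <- ifelse(pf > 0, pd / pf, 0)
  tot["other_tissue"] <- cfg$total_density_other
  tot
}

# build the region-class code matrix
synth_region_codes <- function(cfg) {
  n <- cfg$size
  margin <- round(cfg$margin_frac * n)
  codes <- matrix(5L, n, n)                      # background
  t0 <- margin + 1L; t1 <- n - margin
  codes[t0:t1, t0:t1] <- 1L                      # default tissue: mucosa
  th <- t1 - t0 + 1L
  other_top <- t1 - round(cfg$other_frac * th) + 1L
  codes[other_top:t1, t0:t1] <- 4L               # other tissue band
  # follicle disks and tumor blobs sit in the band below the upper mucosa
  mid0 <- t0 + round(cfg$mucosa_frac * th)
  mid1 <- other_top - 1L
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  cy <- (mid0 + mid1) / 2
  w <- t1 - t0
  rf <- cfg$follicle_radius_frac * n
  if (cfg$n_follicles > 0) {
    fx <- t0 + seq(0.18, 0.5, length.out = max(cfg$n_follicles, 2L)) * w
    for (k in seq_len(cfg$n_follicles)) {
      d2 <- (rows - cy)^2 + (cols - fx[k])^2
      codes[d2 <= rf^2 & codes != 5L] <- 2L
    }
  }
  if (cfg$n_tumors > 0) {
    rt <- cfg$tumor_radius_frac * n
    tx <- t0 + seq(0.75, 0.9, length.out = max(cfg$n_tumors, 2L)) * w
    for (k in seq_len(cfg$n_tumors)) {
      dy <- rows - cy; dx <- cols - tx[k]
      th_ <- atan2(dx, dy)
      rmod <- rt * (1 + 0.3 * sin(3 * th_ + k))
      # tumors grow inside the mucosa only, so follicles keep their shape
      sel <- dy^2 + dx^2 <= rmod^2 & codes == 1L
      codes[sel] <- 3L
    }
  }
  codes
}

# batch hard-core (RSA) placement of n points inside a region
# codes matrix, code: target class; min_sep in px. Errors on overcrowding.
# A shared `grid` environment (with its fixed `cell` bin size >= any
# min_sep used with it) extends the hard-core exclusion across regions.
rsa_place <- function(codes, code, n_pts, min_sep, max_batches = 800L,
                      grid = NULL, cell = NULL) {
  if (is.null(grid)) grid <- new.env(hash = TRUE, parent = emptyenv())
  if (is.null(cell)) cell <- max(min_sep, 1)
  stopifnot(cell >= min_sep)
  if (n_pts == 0L)
    return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  idx_all <- which(codes == code)
  if (!length(idx_all))
    stop(sprintf("region code %d has no pixels to place cells in", code))
  nr <- nrow(codes)
  acc_r <- numeric(0); acc_c <- numeric(0)
  gkey <- function(r, c) paste(floor(r / cell), floor(c / cell))
  ok_point <- function(r, c) {
    gr <- floor(r / cell); gc <- floor(c / cell)
    for (dr in -1:1) for (dc in -1:1) {
      k <- paste(gr + dr, gc + dc)
      pts <- grid[[k]]
      if (!is.null(pts) &&
          any((pts[, 1] - r)^2 + (pts[, 2] - c)^2 < min_sep^2))
        return(FALSE)
    }
    TRUE
  }
  batches <- 0L
  while (length(acc_r) < n_pts && batches < max_batches) {
    batches <- batches + 1L
    m <- min(4L * (n_pts - length(acc_r)) + 16L, 4096L)
    pick <- idx_all[sample.int(length(idx_all), m, replace = TRUE)]
    pr <- ((pick - 1L) %% nr) + 1 + stats::runif(m, -0.49, 0.49)
    pc <- ((pick - 1L) %/% nr) + 1 + stats::runif(m, -0.49, 0.49)
    for (i in seq_len(m)) {
      if (length(acc_r) >= n_pts) break
      if (ok_point(pr[i], pc[i])) {
        acc_r <- c(acc_r, pr[i]); acc_c <- c(acc_c, pc[i])
        k <- gkey(pr[i], pc[i])
        grid[[k]] <- rbind(grid[[k]], c(pr[i], pc[i]))
      }
    }
  }
  if (length(acc_r) < n_pts)
    stop(sprintf(
      "overcrowding: placed only %d of %d cells in region %d at min separation %.1f px",
      length(acc_r), n_pts, code, min_sep))
  cbind(row = acc_r, col = acc_c)
}

# paint filled disks (value = per-disk intensity, max-composited) onto img
paint_disks <- function(img, rows, cols, radii, values) {
  n <- nrow(img)
  for (i in seq_along(rows)) {
    r <- radii[i]
    r0 <- max(1L, floor(rows[i] - r)); r1 <- min(n, ceiling(rows[i] + r))
    c0 <- max(1L, floor(cols[i] - r)); c1 <- min(ncol(img), ceiling(cols[i] + r))
    if (r0 > r1 || c0 > c1) next
    rr <- r0:r1; cc <- c0:c1
    d2 <- outer((rr - rows[i])^2, (cc - cols[i])^2, `+`)
    sub <- img[rr, cc]
    hit <- d2 <= r^2
    sub[hit] <- pmax(sub[hit], values[i])
    img[rr, cc] <- sub
  }
  img
}

# paint annuli (rings) with inner/outer radii
paint_rings <- function(img, rows, cols, r_in, r_out, values) {
  n <- nrow(img)
  for (i in seq_along(rows)) {
    r <- r_out[i]
    r0 <- max(1L, floor(rows[i] - r)); r1 <- min(n, ceiling(rows[i] + r))
    c0 <- max(1L, floor(cols[i] - r)); c1 <- min(ncol(img), ceiling(cols[i] + r))
    if (r0 > r1 || c0 > c1) next
    rr <- r0:r1; cc <- c0:c1
    d2 <- outer((rr - rows[i])^2, (cc - cols[i])^2, `+`)
    sub <- img[rr, cc]
    hit <- d2 <= r^2 & d2 >= r_in[i]^2
    sub[hit] <- pmax(sub[hit], values[i])
    img[rr, cc] <- sub
  }
  img
}

#' Generate a synthetic multichannel slide with exact ground truth
#'
#' @param cfg a [synth_config()] object.
#' @param .omit_marker internal: marker channel name whose rings are
#'   suppressed (used by [generate_negative_control()]).
#' @return list with `slide` (a [slide()]), and `truth`: `roi` (a
#'   `LabelMask` with the five region classes), `cells` (data frame of
#'   centroid `row`/`col`, `region`, `phenotype`, `nucleus_area_um2`) and
#'   `artifacts` (data frame `row`, `col`, `kind`).
#' @export
generate_slide <- function(cfg, .omit_marker = NULL) {
  stopifnot(inherits(cfg, "SynthConfig"))
  set.seed(cfg$seed)
  n <- cfg$size; ps <- cfg$pixel_size
  codes <- synth_region_codes(cfg)
  tot <- synth_total_density(cfg)
  regions <- c("mucosa", "lymphoid_follicle", "tumor", "other_tissue")
  nuc_d_px <- 2 * sqrt(cfg$nucleus_area_mean / pi) / ps
  cells <- list()
  # one exclusion grid across all regions: the hard-core separation also
  # holds for pairs straddling region borders
  grid <- new.env(hash = TRUE, parent = emptyenv())
  grid_cell <- max(unlist(cfg$sep_factor)) * nuc_d_px
  for (k in seq_along(regions)) {
    reg <- regions[k]
    area_mm2 <- sum(codes == k) * ps^2 / 1e6
    lambda <- tot[[reg]] * area_mm2
    n_k <- stats::rpois(1L, lambda)
    sep <- cfg$sep_factor[[reg]] * nuc_d_px
    pts <- rsa_place(codes, k, n_k, sep, grid = grid, cell = grid_cell)
    if (n_k > 0L) {
      a <- pmax(stats::rnorm(n_k, cfg$nucleus_area_mean, cfg$nucleus_area_sd), 15)
      pf <- cfg$positive_fraction[[reg]]
      pos <- stats::runif(n_k) < pf
      phen <- if (cfg$scheme == "single_CD45") {
        ifelse(pos, "positive", "negative")
      } else {
        spl <- cfg$double_split / sum(cfg$double_split)
        out <- rep("CD3-CD4-", n_k)
        if (any(pos))
          out[pos] <- sample(names(spl), sum(pos), replace = TRUE, prob = spl)
        out
      }
      cells[[reg]] <- data.frame(row = pts[, 1], col = pts[, 2],
                                 region = reg, phenotype = phen,
                                 nucleus_area_um2 = a,
                                 stringsAsFactors = FALSE)
    }
  }
  cells <- if (length(cells)) do.call(rbind, cells) else
    data.frame(row = numeric(), col = numeric(), region = character(),
               phenotype = character(), nucleus_area_um2 = numeric())
  rownames(cells) <- NULL

  # ---- DAPI channel ----
  dapi <- matrix(0, n, n)
  for (k in seq_along(regions))
    dapi[codes == k] <- cfg$dapi_base[[regions[k]]]
  # mucosal crypt-like stripes
  stripe <- 1 + 0.35 * sin(2 * pi * seq_len(n) * ps / 25)
  muc <- codes == 1L
  dapi[muc] <- dapi[muc] * matrix(stripe, n, n, byrow = TRUE)[muc]
  # tumor speckle texture
  tum <- codes == 3L
  if (any(tum)) {
    spk <- EBImage::imageData(EBImage::gblur(
      EBImage::Image(matrix(stats::rnorm(n * n), n)), sigma = 6))
    spk <- spk / max(abs(spk))
    dapi[tum] <- dapi[tum] * (1 + 0.4 * spk[tum])
  }
  if (nrow(cells)) {
    gain <- cfg$nucleus_gain[cells$region]
    peak <- pmax(stats::rnorm(nrow(cells), cfg$dapi_nucleus_mean,
                              cfg$dapi_nucleus_sd), 4000) * gain
    r_px <- sqrt(cells$nucleus_area_um2 / pi) / ps
    dapi <- paint_disks(dapi, cells$row, cells$col, r_px, peak)
  }
  dapi <- EBImage::imageData(EBImage::gblur(EBImage::Image(dapi), sigma = 0.8))
  fol <- codes == 2L
  if (any(fol) && cfg$follicle_blur_sigma > 0) {
    # the blurry DAPI appearance of densely packed follicles
    db <- EBImage::imageData(EBImage::gblur(EBImage::Image(dapi),
                                            sigma = cfg$follicle_blur_sigma))
    dapi[fol] <- db[fol]
  }

  # ---- membrane channel(s) ----
  marker_of <- if (cfg$scheme == "single_CD45") {
    list(FITC = "positive")
  } else {
    list(CY3 = c("CD3+CD4+", "CD3+CD4-"), FITC = c("CD3+CD4+", "CD3-CD4+"))
  }
  r_cell <- sqrt(cfg$cell_area_um2 / pi) / ps
  membranes <- list()
  artifacts <- data.frame(row = numeric(), col = numeric(), kind = character())
  tissue <- codes != 5L
  for (ch in names(marker_of)) {
    mimg <- matrix(0, n, n)
    if (nrow(cells) && !identical(ch, .omit_marker)) {
      sel <- cells$phenotype %in% marker_of[[ch]]
      if (any(sel)) {
        vals <- pmax(stats::rnorm(sum(sel), cfg$ring_mean, cfg$ring_sd), 3000)
        # thin annulus at the cell perimeter: realistic membrane staining
        # that barely invades neighboring cells; the inner radius is
        # clamped so the ring always touches its own nucleus
        rn <- sqrt(cells$nucleus_area_um2[sel] / pi) / ps
        mimg <- paint_rings(mimg, cells$row[sel], cells$col[sel],
                            r_in = pmin(0.85 * r_cell, 0.95 * rn),
                            r_out = rep(1.05 * r_cell, sum(sel)),
                            values = vals)
      }
    }
    membranes[[ch]] <- mimg
  }
  # fluorochrome aggregates: bright membrane blobs with no nucleus, kept
  # clear of real cells so they can only create false positives
  if (cfg$n_aggregates > 0L) {
    agg_r <- sqrt(cfg$aggregate_area_um2 / pi) / ps
    cand <- which(tissue)
    placed <- 0L; tries <- 0L
    agg <- matrix(numeric(0), 0, 2)
    while (placed < cfg$n_aggregates && tries < 200L * cfg$n_aggregates) {
      tries <- tries + 1L
      p <- cand[sample.int(length(cand), 1L)]
      pr <- (p - 1L) %% n + 1; pc <- (p - 1L) %/% n + 1
      clear <- if (nrow(cells))
        min((cells$row - pr)^2 + (cells$col - pc)^2) > (3 * r_cell)^2
      else TRUE
      if (clear) {
        agg <- rbind(agg, c(pr, pc)); placed <- placed + 1L
      }
    }
    for (ch in names(membranes))
      membranes[[ch]] <- paint_disks(membranes[[ch]], agg[, 1], agg[, 2],
                                     rep(agg_r, nrow(agg)),
                                     rep(cfg$aggregate_intensity, nrow(agg)))
    if (nrow(agg))
      artifacts <- rbind(artifacts,
                         data.frame(row = agg[, 1], col = agg[, 2],
                                    kind = "aggregate"))
  }
  # paraffin-edge autofluorescence rim on the membrane channel(s)
  if (isTRUE(cfg$edge_autofluorescence)) {
    dt <- EBImage::imageData(EBImage::distmap(
      EBImage::Image(matrix(as.numeric(tissue), n))))
    rim <- tissue & dt <= cfg$edge_rim_um / ps
    for (ch in names(membranes))
      membranes[[ch]][rim] <- pmax(membranes[[ch]][rim], cfg$edge_rim_intensity)
    artifacts <- rbind(artifacts,
                       data.frame(row = NA_real_, col = NA_real_,
                                  kind = "edge_autofluorescence"))
  }

  # ---- noise, clipping, assembly ----
  finish <- function(img) {
    img <- img + stats::rnorm(length(img), 0, cfg$noise_sd)
    img[!tissue] <- abs(img[!tissue])      # background: pure noise floor
    matrix(as.integer(pmin(pmax(round(img), 0), 65535)), n, n)
  }
  channels <- c(list(DAPI = finish(dapi)),
                lapply(membranes, finish))
  sl <- slide(channels, pixel_size = ps, bit_depth = 16L)
  truth <- list(roi = label_mask(codes, synth_legend),
                cells = cells, artifacts = artifacts)
  list(slide = sl, truth = truth)
}

#' Generate a no-primary-antibody negative control slide
#'
#' Identical to [generate_slide()] except that the omitted marker channel
#' contains only sub-threshold background (no rings, no aggregates on that
#' channel would be unrealistic to drop, so aggregates are suppressed
#' entirely on control slides); ground truth marks every cell negative for
#' the omitted marker.
#'
#' @param cfg a [synth_config()].
#' @param omit channel to omit: `"FITC"` (single-staining default) or
#'   `"CY3"`.
#' @return same structure as [generate_slide()].
#' @export
generate_negative_control <- function(cfg, omit = "FITC") {
  stopifnot(inherits(cfg, "SynthConfig"))
  cfg$n_aggregates <- 0L
  out <- generate_slide(cfg, .omit_marker = omit)
  tc <- out$truth$cells
  if (nrow(tc)) {
    if (cfg$scheme == "single_CD45") {
      if (omit == "FITC") tc$phenotype <- "negative"
    } else {
      if (omit == "CY3") {
        tc$phenotype <- sub("^CD3\\+", "CD3-", tc$phenotype)
      } else if (omit == "FITC") {
        tc$phenotype <- sub("CD4\\+$", "CD4-", tc$phenotype)
      }
    }
    out$truth$cells <- tc
  }
  out
}
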