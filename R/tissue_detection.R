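#' Parameters for global tissue detection
#'
#' Tissue is the set of pixels that are both bright enough (on a smoothed
#' copy of the detection channel) and texturally homogeneous enough; small
#' disconnected fragments are discarded by a minimal-size rule.
#'
#' @param channel channel name used for detection (normally the nuclear
#'   counterstain, e.g. `"DAPI"`).
#' @param brightness_min minimal smoothed brightness, in grey-value levels.
#' @param homogeneity_max maximal local-heterogeneity statistic. The
#'   statistic is a bounded rescaling of the local coefficient of variation,
#'   `scale * cv / (1 + cv)`, mapping `[0, Inf)` onto `[0, scale)`.
#' @param min_area minimal connected-component area in um^2 (default 10):
#'   smaller fragments are treated as non-tissue debris and removed.
#' @param homogeneity_scale either 5 (default) or 255; the upper end of the
#'   heterogeneity statistic's range, so thresholds can be quoted on a 0-5
#'   or a 0-255 scale.
#' @param smooth_sigma Gaussian smoothing sigma in pixels applied to the
#'   channel before the brightness test (default 2), suppressing shot noise.
#' @param window local-statistics window edge in pixels (odd; default 15).
#' @return a list of class `TissueParams`.
#' @export
tissue_params <- function(channel = "DAPI", brightness_min = 500,
                          homogeneity_max = 5, min_area = 10,
                          homogeneity_scale = 5, smooth_sigma = 2,
                          window = 15L) {
  stopifnot(min_area >= 0, brightness_min >= 0, homogeneity_max >= 0,
            homogeneity_scale %in% c(5, 255), window >= 3)
  structure(list(channel = channel, brightness_min = brightness_min,
                 homogeneity_max = homogeneity_max, min_area = min_area,
                 homogeneity_scale = homogeneity_scale,
                 smooth_sigma = smooth_sigma, window = as.integer(window)),
            class = "TissueParams")
}

# box-filter local mean via EBImage::filter2 (circular padding avoided by
# replicated borders through normalization with a ones-image)
local_mean <- function(x, w) {
  k <- matrix(1, w, w)
  ones <- matrix(1, nrow(x), ncol(x))
  s <- EBImage::imageData(EBImage::filter2(EBImage::Image(x), k, boundary = 0))
  n <- EBImage::imageData(EBImage::filter2(EBImage::Image(ones), k, boundary = 0))
  s / n
}

# local coefficient of variation rescaled onto [0, scale)
local_heterogeneity <- function(x, w, scale) {
  m <- local_mean(x, w)
  m2 <- local_mean(x^2, w)
  v <- pmax(m2 - m^2, 0)
  cv <- sqrt(v) / pmax(m, 1e-9)
  scale * cv / (1 + cv)
}

#' Detect the tissue section on a slide
#'
#' A pixel is tissue iff its Gaussian-smoothed brightness on the detection
#' channel is at least `brightness_min` and its local heterogeneity is at
#' most `homogeneity_max`; connected components smaller than `min_area`
#' (um^2) are then removed.
#'
#' @param x a [slide()] object.
#' @param params a [tissue_params()] object.
#' @return a binary `LabelMask` (label 1 = `"tissue"`).
#' @export
detect_tissue <- function(x, params = tissue_params()) {
  stopifnot(inherits(x, "Slide"), inherits(params, "TissueParams"))
  if (!params$channel %in% names(x$channels))
    stop(sprintf("unknown channel '%s'", params$channel))
  hi <- 2^x$bit_depth
  if (params$brightness_min >= hi)
    stop("brightness_min outside representable intensity range")
  ch <- x$channels[[params$channel]]
  sm <- if (params$smooth_sigma > 0) {
    EBImage::imageData(EBImage::gblur(EBImage::Image(ch), sigma = params$smooth_sigma))
  } else ch
  het <- local_heterogeneity(ch, params$window, params$homogeneity_scale)
  m <- (sm >= params$brightness_min) & (het <= params$homogeneity_max)
  m <- drop_small_components(m, params$min_area, x$pixel_size)
  label_mask(matrix(as.integer(m), nrow(ch), ncol(ch)), c(`1` = "tissue"))
}

# remove connected components below an area threshold (um^2)
drop_small_components <- function(m, min_area, pixel_size) {
  if (!any(m)) return(m)
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(matrix(as.numeric(m), nrow(m)))))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(area_um2(sizes, pixel_size) >= min_area)
  matrix(lab %in% keep, nrow(m), ncol(m))
}

#' Suggest a brightness threshold by Otsu's method
#'
#' A starting point for calibrating [tissue_params()]; the stored,
#' explicit configuration remains authoritative.
#'
#' @param x a `Slide`; @param channel detection channel name.
#' @param smooth_sigma smoothing sigma in pixels (default 2).
#' @return suggested `brightness_min` in grey-value levels.
#' @export
suggest_brightness_min <- function(x, channel = "DAPI", smooth_sigma = 2) {
  stopifnot(inherits(x, "Slide"))
  ch <- x$channels[[channel]]
  if (is.null(ch)) stop(sprintf("unknown channel '%s'", channel))
  hi <- 2^x$bit_depth - 1
  sm <- EBImage::gblur(EBImage::Image(ch / hi), sigma = smooth_sigma)
  EBImage::otsu(sm, range = c(0, 1)) * hi
}

#' Restrict a slide to a mask, zeroing all non-mask pixels
#' @param x a `Slide`; @param mask a `LabelMask` (nonzero = keep).
#' @return a `Slide` with identical calibration.
#' @export
mask_slide <- function(x, mask) {
  stopifnot(inherits(x, "Slide"), inherits(mask, "LabelMask"))
  keep <- mask$labels != 0L
  x$channels <- lapply(x$channels, function(ch) {
    ch[!keep] <- 0L
    ch
  })
  x
}
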