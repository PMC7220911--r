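# OCT layer segmentation, thickness measurement, and registration of OCT
# boundaries into a/LCI depth pixels.

#' Named retinal layer boundaries
#'
#' Row indices of the NFL, OPL and RPE bands in an OCT B-scan, 0-based and
#' half-open (`[top, bottom)`), ordered NFL above OPL above RPE, together
#' with the OCT axial pixel size and (after [map_to_alci()]) the mapped
#' a/LCI depth-pixel intervals.
#'
#' @param top_px,bottom_px numeric length-3 vectors (NFL, OPL, RPE order).
#' @param oct_axial_pixel OCT axial pixel size, um/px.
#' @param top_alci_px,bottom_alci_px optional mapped a/LCI intervals.
#' @param alci_pixel_to_depth a/LCI depth pixel size, um/px (set by
#'   [map_to_alci()]).
#' @return a data.frame of class `layer_boundary_set` with one row per layer.
#' @export
layer_boundary_set <- function(top_px, bottom_px, oct_axial_pixel,
                               top_alci_px = NULL, bottom_alci_px = NULL,
                               alci_pixel_to_depth = NULL) {
  stopifnot(length(top_px) == 3, length(bottom_px) == 3,
            all(top_px >= 0), all(bottom_px > top_px),
            is_scalar(oct_axial_pixel), oct_axial_pixel > 0)
  if (!(bottom_px[1] <= top_px[2] && bottom_px[2] <= top_px[3])) {
    stop("layers must be ordered NFL above OPL above RPE without overlap")
  }
  out <- data.frame(layer = c("NFL", "OPL", "RPE"),
                    top_px = top_px, bottom_px = bottom_px,
                    stringsAsFactors = FALSE)
  if (!is.null(top_alci_px)) {
    out$top_alci_px <- top_alci_px
    out$bottom_alci_px <- bottom_alci_px
  }
  attr(out, "oct_axial_pixel") <- oct_axial_pixel
  attr(out, "alci_pixel_to_depth") <- alci_pixel_to_depth
  class(out) <- c("layer_boundary_set", "data.frame")
  out
}

#' Segment NFL/OPL/RPE boundaries in a B-scan
#'
#' Automated analogue of manual OCT segmentation: each column is smoothed
#' with a 3-pixel boxcar along depth, thresholded between robust low/high
#' intensity quantiles, and scanned for exactly three bright bands; columns
#' not showing three bands are ignored. The per-column band edges are then
#' reduced to a single boundary set by taking the median across columns
#' (robust to speckle). When fewer than `min_valid_frac` of columns yield
#' three bands the B-scan is deemed unsegmentable and a classed error
#' (`retscat_segmentation_failure`) is signalled, mirroring the exclusion of
#' low-contrast B-scans from analysis.
#'
#' @param bscan a B-scan image matrix (rows = depth) or the list returned by
#'   [make_bscan()].
#' @param oct_axial_pixel axial pixel size, um/px (taken from a
#'   [make_bscan()] object when available).
#' @param min_run minimum band height, pixels.
#' @param min_valid_frac minimum fraction of columns with three bands.
#' @return a [layer_boundary_set()].
#' @export
segment_layers <- function(bscan, oct_axial_pixel = NULL, min_run = 2,
                           min_valid_frac = 0.25) {
  if (is.list(bscan) && !is.null(bscan$image)) {
    if (is.null(oct_axial_pixel)) {
      oct_axial_pixel <- attr(bscan$truth, "oct_axial_pixel")
    }
    bscan <- bscan$image
  }
  stopifnot(is.matrix(bscan), is_scalar(oct_axial_pixel))
  n <- nrow(bscan)
  if (all(bscan <= 0) || stats::sd(bscan) == 0) {
    stop_retscat("no resolvable bands (flat or empty B-scan)",
                 "retscat_segmentation_failure")
  }
  sm <- apply(bscan, 2, function(v) {
    s <- as.numeric(stats::filter(v, rep(1 / 3, 3), sides = 2))
    s[1] <- v[1]; s[n] <- v[n]
    s
  })
  lo <- stats::quantile(sm, 0.20, names = FALSE)
  hi <- stats::quantile(sm, 0.995, names = FALSE)
  thr <- lo + 0.45 * (hi - lo)
  per_col <- apply(sm, 2, function(v) {
    r <- rle(v > thr)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values & r$lengths >= min_run
    if (sum(keep) != 3) return(rep(NA_real_, 6))
    as.numeric(rbind(starts[keep] - 1, ends[keep])) # 0-based half-open
  })
  valid <- colSums(is.na(per_col)) == 0
  if (mean(valid) < min_valid_frac) {
    stop_retscat(
      sprintf("fewer than 3 bright bands detected in %.0f%% of columns",
              100 * (1 - mean(valid))),
      "retscat_segmentation_failure"
    )
  }
  b <- round_half_away(apply(per_col[, valid, drop = FALSE], 1, stats::median))
  layer_boundary_set(top_px = b[c(1, 3, 5)], bottom_px = b[c(2, 4, 6)],
                     oct_axial_pixel = oct_axial_pixel)
}

#' Layer thickness in microns
#'
#' @param bounds a [layer_boundary_set()].
#' @param layer one of `"NFL"`, `"OPL"`, `"RPE"`.
#' @return thickness `(bottom_px - top_px) * oct_axial_pixel`, microns.
#' @export
layer_thickness <- function(bounds, layer) {
  stopifnot(inherits(bounds, "layer_boundary_set"))
  i <- match(layer, bounds$layer)
  if (is.na(i)) stop(sprintf("unknown layer '%s'", layer))
  (bounds$bottom_px[i] - bounds$top_px[i]) * attr(bounds, "oct_axial_pixel")
}

#' Map OCT boundaries into a/LCI depth pixels
#'
#' Scales OCT row indices by the ratio of the OCT axial pixel to the a/LCI
#' pixel-to-depth conversion factor, rounding half away from zero. Mapped
#' intervals are half-open and widened to a minimum height of one depth
#' pixel; intervals extending past `n_depth` (when given) are clamped with
#' a warning.
#'
#' @param bounds a [layer_boundary_set()].
#' @param alci_pixel_to_depth a/LCI depth pixel size, um/px.
#' @param n_depth optional depth extent of the target volume, pixels.
#' @return the boundary set with `top_alci_px` / `bottom_alci_px` columns.
#' @export
map_to_alci <- function(bounds, alci_pixel_to_depth, n_depth = NULL) {
  stopifnot(inherits(bounds, "layer_boundary_set"),
            is_scalar(alci_pixel_to_depth), alci_pixel_to_depth > 0)
  s <- attr(bounds, "oct_axial_pixel") / alci_pixel_to_depth
  top <- round_half_away(bounds$top_px * s)
  bot <- pmax(top + 1, round_half_away(bounds$bottom_px * s))
  if (!is.null(n_depth)) {
    if (any(bot > n_depth)) {
      warning("mapped interval exceeds volume depth; clamped")
      bot <- pmin(bot, n_depth)
      top <- pmin(top, bot - 1)
    }
  }
  layer_boundary_set(bounds$top_px, bounds$bottom_px,
                     attr(bounds, "oct_axial_pixel"),
                     top_alci_px = top, bottom_alci_px = bot,
                     alci_pixel_to_depth = alci_pixel_to_depth)
}

#' Extract a per-layer 2D angular scattering plane from a volume
#'
#' Averages volume intensity over the layer's mapped a/LCI depth interval,
#' yielding one theta_x by theta_y plane (mean by default so thin and thick
#' layers stay comparable; `agg = "sum"` integrates instead). The returned
#' plane carries an empty exclusion mask.
#'
#' @param volume a [scattering_volume()].
#' @param bounds a mapped [layer_boundary_set()] (see [map_to_alci()]).
#' @param layer layer name.
#' @param agg `"mean"` or `"sum"` depth aggregation.
#' @return an [angular_plane()].
#' @export
extract_layer_plane <- function(volume, bounds, layer, agg = c("mean", "sum")) {
  agg <- match.arg(agg)
  stopifnot(inherits(volume, "scattering_volume"),
            inherits(bounds, "layer_boundary_set"),
            !is.null(bounds$top_alci_px))
  i <- match(layer, bounds$layer)
  if (is.na(i)) stop(sprintf("unknown layer '%s'", layer))
  top <- bounds$top_alci_px[i]
  bot <- bounds$bottom_alci_px[i]
  nd <- dim(volume$intensity)[1]
  if (top < 0 || bot > nd) {
    stop(sprintf("mapped interval [%d, %d) outside volume depth %d",
                 top, bot, nd))
  }
  idx <- (top + 1):bot # half-open [top, bot) in 0-based pixels
  sl <- volume$intensity[idx, , , drop = FALSE]
  plane <- apply(sl, c(2, 3), if (agg == "mean") mean else sum)
  angular_plane(plane, layer = layer)
}

#' Read / write externally supplied boundary tables
#'
#' Import path for manual segmentations: a CSV with columns `eye`,
#' `location`, `layer`, `top_px`, `bottom_px`.
#'
#' @param path CSV file path.
#' @param oct_axial_pixel axial pixel size attached to each boundary set.
#' @return named list (by `eye:location`) of [layer_boundary_set()] objects.
#' @export
read_boundaries <- function(path, oct_axial_pixel) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("eye", "location", "layer", "top_px", "bottom_px")
                %in% names(d)))
  keys <- unique(paste(d$eye, d$location, sep = ":"))
  out <- lapply(keys, function(k) {
    sub <- d[paste(d$eye, d$location, sep = ":") == k, ]
    sub <- sub[match(c("NFL", "OPL", "RPE"), sub$layer), ]
    layer_boundary_set(sub$top_px, sub$bottom_px, oct_axial_pixel)
  })
  names(out) <- keys
  out
}
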