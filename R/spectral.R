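# Spectral-domain processing: raw interferometric scans -> depth-resolved
# angular scattering.

#' Transform a raw spectral scan to a depth-resolved angular profile
#'
#' Computes, per theta_x column, the magnitude of the one-sided discrete
#' Fourier transform along the spectral (wavenumber) dimension, so that a
#' fringe of `m` cycles across the sampled band maps to depth pixel `m`.
#'
#' Conventions (documented constants): spectra are apodized with a Hann
#' window by default (`"none"` for oracle-exact tests); DC suppression
#' subtracts each column's spectral mean before the transform, which empties
#' the depth-0 bin without touching finite-depth fringes; magnitudes are
#' scaled by `2 / (n_k * mean(window))` so a unit-amplitude cosine fringe
#' yields a unit peak (the depth-0 bin, not doubled, is scaled by
#' `1 / (n_k * mean(window))`).
#'
#' @param scan a [raw_alci_scan()].
#' @param window apodization: `"hann"` (default) or `"none"`.
#' @param dc_suppress subtract each column's spectral mean first.
#' @return numeric matrix, depth pixel (rows, `n_k/2`) by theta_x, with
#'   attribute `depth_um` when the scan carries pixel scale metadata.
#' @export
spectra_to_depth <- function(scan, window = c("hann", "none"),
                             dc_suppress = TRUE) {
  window <- match.arg(window)
  stopifnot(inherits(scan, "raw_alci_scan"))
  k <- scan$k_axis
  dk <- diff(k)
  if (max(abs(dk - mean(dk))) > 1e-6 * abs(mean(dk))) {
    stop(paste("wavenumber axis is not evenly spaced (relative deviation >",
               "1e-6); resample the spectrum onto a uniform axis first"))
  }
  x <- scan$intensity
  nk <- nrow(x)
  if (dc_suppress) x <- sweep(x, 2, colMeans(x))
  w <- if (window == "hann") {
    0.5 - 0.5 * cos(2 * pi * (seq_len(nk) - 1) / (nk - 1))
  } else {
    rep(1, nk)
  }
  x <- x * w
  sp <- stats::mvfft(x)
  half <- nk %/% 2
  mag <- Mod(sp[seq_len(half), , drop = FALSE])
  scale <- 2 / (nk * mean(w))
  mag <- mag * scale
  mag[1, ] <- mag[1, ] / 2 # depth-0 bin is its own conjugate; not doubled
  mag
}

#' Depth-resolved stack of 2D angular scattering planes
#'
#' @param intensity 3D array, depth pixel by theta_x by theta_y, nonnegative.
#' @param depth_um depth axis, microns.
#' @param theta_x,theta_y angular axes, radians.
#' @param provenance optional identifiers of the source scans.
#' @return object of class `scattering_volume`.
#' @export
scattering_volume <- function(intensity, depth_um, theta_x, theta_y,
                              provenance = NULL) {
  stopifnot(length(dim(intensity)) == 3, all(intensity >= 0),
            length(depth_um) == dim(intensity)[1],
            length(theta_x) == dim(intensity)[2],
            length(theta_y) == dim(intensity)[3])
  structure(list(intensity = intensity, depth_um = depth_um,
                 theta_x = theta_x, theta_y = theta_y,
                 provenance = provenance),
            class = "scattering_volume")
}

#' @export
print.scattering_volume <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("Scattering volume: %d depth px x %d theta_x x %d theta_y (%.1f um deep)\n",
              d[1], d[2], d[3], max(x$depth_um)))
  invisible(x)
}

#' Assemble a scattering volume from scans acquired over theta_y
#'
#' Applies [spectra_to_depth()] to each scan and stacks the results along
#' theta_y (scans are sorted by their theta_y tags; the galvanometer order
#' of acquisition is irrelevant). All scans must share identical wavenumber
#' and theta_x axes.
#'
#' @param scans list of [raw_alci_scan()] with strictly increasing (after
#'   sorting) distinct theta_y tags.
#' @param cfg an [optical_config()] supplying the pixel-to-depth factor.
#' @param ... passed to [spectra_to_depth()] (window, dc_suppress).
#' @return a [scattering_volume()].
#' @export
assemble_volume <- function(scans, cfg, ...) {
  stopifnot(length(scans) >= 1,
            all(vapply(scans, inherits, logical(1), "raw_alci_scan")))
  ty <- vapply(scans, function(s) s$theta_y, numeric(1))
  if (anyDuplicated(ty)) stop("duplicate theta_y tags in scan list")
  ord <- order(ty)
  scans <- scans[ord]
  ref <- scans[[1]]
  for (j in seq_along(scans)) {
    s <- scans[[j]]
    if (!isTRUE(all.equal(s$k_axis, ref$k_axis)) ||
        !isTRUE(all.equal(s$theta_x, ref$theta_x))) {
      stop(sprintf("scan %d (theta_y = %.4f) has mismatched axes", j,
                   s$theta_y))
    }
  }
  mats <- lapply(scans, spectra_to_depth, ...)
  half <- nrow(mats[[1]])
  vol <- array(unlist(mats, use.names = FALSE),
               dim = c(half, ncol(mats[[1]]), length(mats)))
  scattering_volume(vol, depth_um = (seq_len(half) - 1) * cfg$alci_pixel_to_depth,
                    theta_x = ref$theta_x, theta_y = sort(ty))
}
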