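# Synthetic raw interferometric scans and layered OCT B-scans.

#' Construct a raw a/LCI scan object
#'
#' One unit of spectral-domain acquisition: scattered intensity as a
#' function of wavenumber and theta_x at a single galvanometer (theta_y)
#' position.
#'
#' @param intensity numeric matrix, wavenumber index by theta_x index,
#'   finite and nonnegative.
#' @param k_axis strictly increasing, evenly spaced wavenumber axis (1/um).
#' @param theta_x strictly increasing angular axis (radians).
#' @param theta_y scalar theta_y tag (radians).
#' @return object of class `raw_alci_scan`.
#' @export
raw_alci_scan <- function(intensity, k_axis, theta_x, theta_y = 0) {
  stopifnot(is.matrix(intensity), all(is.finite(intensity)),
            all(intensity >= 0),
            length(k_axis) == nrow(intensity),
            length(theta_x) == ncol(intensity),
            all(diff(k_axis) > 0), all(diff(theta_x) > 0),
            is_scalar(theta_y))
  structure(list(intensity = intensity, k_axis = k_axis,
                 theta_x = theta_x, theta_y = theta_y),
            class = "raw_alci_scan")
}

#' Synthesize a raw a/LCI scan from a depth-reflectivity profile
#'
#' Encodes each reflector as an interferometric fringe across the spectral
#' axis: a reflector at depth pixel `m` (depth `m * alci_pixel_to_depth`
#' microns) produces `m` cosine cycles across the sampled wavenumber band,
#' so the one-sided spectral Fourier transform of [spectra_to_depth()]
#' recovers a peak at depth pixel `m`. Reflectivity may be a scalar or a
#' vector over theta_x (angular structure at that depth).
#'
#' @param depth_profile data.frame with columns `depth_um` and
#'   `reflectivity`, or a list of `(depth_um, reflectivity)` pairs where
#'   reflectivity may be a length-`n_theta_x` vector. An empty profile gives
#'   a flat (DC-only) spectrum.
#' @param cfg an [optical_config()].
#' @param seed seed for the additive Gaussian read noise.
#' @param noise_sd standard deviation of additive detector read noise
#'   (clamped at zero intensity).
#' @param theta_y theta_y tag for the scan.
#' @return a [raw_alci_scan()].
#' @export
make_raw_scan <- function(depth_profile, cfg, seed = 1L, noise_sd = 0,
                          theta_y = 0) {
  stopifnot(inherits(cfg, "optical_config"))
  nk <- cfg$n_wavenumber_samples
  nx <- cfg$n_theta_x
  dpx <- cfg$alci_pixel_to_depth
  max_depth <- (nk / 2 - 1) * dpx
  if (is.data.frame(depth_profile)) {
    depth_profile <- lapply(seq_len(nrow(depth_profile)), function(i) {
      list(depth_um = depth_profile$depth_um[i],
           reflectivity = depth_profile$reflectivity[i])
    })
  }
  base <- matrix(0, nk, nx)
  i <- seq_len(nk) - 1
  for (ref in depth_profile) {
    d <- ref$depth_um
    r <- ref$reflectivity
    stopifnot(is_scalar(d), d >= 0, length(r) %in% c(1L, nx), all(r >= 0))
    m <- d / dpx
    if (m >= nk / 2) {
      stop_retscat(
        sprintf("depth %.1f um beyond the unambiguous (Nyquist) depth %.1f um",
                d, max_depth),
        "retscat_depth_error"
      )
    }
    fringe <- 1 + cos(2 * pi * m * i / nk)
    base <- base + outer(fringe, rep(r, length.out = nx))
  }
  if (noise_sd > 0) {
    set.seed(seed)
    base <- base + matrix(stats::rnorm(nk * nx, sd = noise_sd), nk, nx)
  }
  base <- pmax(base, 0)
  k0 <- 1 / cfg$center_wavelength
  dk <- 1 / (nk * dpx)  # so one fringe cycle per depth pixel
  raw_alci_scan(base, k0 + (i - nk / 2) * dk,
                seq(-cfg$theta_span / 2, cfg$theta_span / 2, length.out = nx),
                theta_y)
}

#' Synthesize a layered OCT B-scan with ground-truth boundaries
#'
#' Builds a piecewise-constant axial reflectivity template with three bright
#' bands (NFL, OPL, RPE from the top) separated by dimmer plexiform/nuclear
#' gaps, then applies multiplicative speckle `1 + speckle_level * (E - 1)`
#' with `E` exponential(1), the standard fully-developed-speckle model at
#' `speckle_level = 1`. Ground-truth boundaries are the exact row indices of
#' the noiseless template, 0-based half-open `[top, bottom)`.
#'
#' @param layer_thicknesses_um named vector `c(NFL=, OPL=, RPE=)`, microns.
#' @param cfg an [optical_config()]; `oct_axial_pixel` sets the row size.
#' @param contrasts named band reflectivities.
#' @param speckle_level multiplicative speckle strength in `[0, 1]`.
#' @param n_columns lateral width of the B-scan.
#' @param vitreous_um,gap_um vitreous offset above the NFL and inter-band
#'   gap, microns.
#' @param background,gap_level reflectivity outside / between bands.
#' @param seed seed for the speckle.
#' @return list with `image` (rows = depth), `truth` (a
#'   [layer_boundary_set()]), and the generation parameters.
#' @export
make_bscan <- function(layer_thicknesses_um = c(NFL = 18, OPL = 16, RPE = 14),
                       cfg = optical_config(),
                       contrasts = c(NFL = 1.0, OPL = 0.7, RPE = 0.9),
                       speckle_level = 0, n_columns = 64,
                       vitreous_um = 16, gap_um = 20,
                       background = 0.05, gap_level = 0.15, seed = 1L) {
  stopifnot(all(c("NFL", "OPL", "RPE") %in% names(layer_thicknesses_um)),
            all(layer_thicknesses_um > 0), speckle_level >= 0)
  px <- cfg$oct_axial_pixel
  th_px <- pmax(1, round_half_away(layer_thicknesses_um[c("NFL", "OPL", "RPE")] / px))
  gap_px <- max(1, round_half_away(gap_um / px))
  t0 <- max(1, round_half_away(vitreous_um / px))
  tops <- c(t0,
            t0 + th_px[1] + gap_px,
            t0 + th_px[1] + gap_px + th_px[2] + gap_px)
  bots <- tops + th_px
  n_rows <- bots[3] + t0 + gap_px
  img <- matrix(background, n_rows, n_columns)
  img[(tops[1] + 1):bots[3], ] <- gap_level
  for (j in 1:3) img[(tops[j] + 1):bots[j], ] <- contrasts[j]
  if (speckle_level > 0) {
    set.seed(seed)
    img <- img * (1 + speckle_level *
                    (matrix(stats::rexp(n_rows * n_columns), n_rows, n_columns) - 1))
  }
  truth <- layer_boundary_set(top_px = as.numeric(tops),
                              bottom_px = as.numeric(bots),
                              oct_axial_pixel = px)
  list(image = img, truth = truth,
       layer_thicknesses_um = layer_thicknesses_um,
       speckle_level = speckle_level, seed = as.integer(seed))
}
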