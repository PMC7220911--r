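#' Optical configuration for the combined a/LCI + OCT system
#'
#' Collects the geometric and spectral sampling parameters shared by the
#' synthetic-data generator and the analysis chain. A single small-angle
#' coordinate convention is used throughout: an angle theta maps to spatial
#' frequency `q = theta / lambda` (cycles per micron), so the Fourier
#' transform of an angular plane sampled over a total span `theta_span` has
#' spatial-lag spacing `delta_r = lambda / theta_span` and maximum lag
#' `r_max = (n/2) * delta_r`.
#'
#' The defaults choose `theta_span = center_wavelength` (in radians) so that
#' `delta_r` is exactly 1 micron, which places 8 lag samples inside the
#' default 2-10 micron short-range fit window.
#'
#' @param center_wavelength source center wavelength in microns (0.830 by
#'   default, a Ti:Sapphire source).
#' @param n_wavenumber_samples number of spectral samples per angular scan.
#' @param n_theta_x,n_theta_y angular samples per axis.
#' @param theta_span total angular span per axis, radians.
#' @param alci_pixel_to_depth conversion factor from a/LCI depth pixel to
#'   physical depth, microns per pixel.
#' @param oct_axial_pixel OCT axial pixel size, microns per pixel.
#' @return an object of class `optical_config`.
#' @examples
#' cfg <- optical_config()
#' lag_spacing(cfg)  # 1 micron
#' @export
optical_config <- function(center_wavelength = 0.830,
                           n_wavenumber_samples = 128,
                           n_theta_x = 64,
                           n_theta_y = 64,
                           theta_span = center_wavelength,
                           alci_pixel_to_depth = 5,
                           oct_axial_pixel = 2) {
  stopifnot(
    is_scalar(center_wavelength), center_wavelength > 0,
    is_count(n_wavenumber_samples, 8), is_count(n_theta_x, 8),
    is_count(n_theta_y, 8),
    is_scalar(theta_span), theta_span > 0,
    is_scalar(alci_pixel_to_depth), alci_pixel_to_depth > 0,
    is_scalar(oct_axial_pixel), oct_axial_pixel > 0
  )
  if (n_wavenumber_samples %% 2 != 0) {
    stop("n_wavenumber_samples must be even (one-sided depth transform)")
  }
  structure(
    list(
      center_wavelength = center_wavelength,
      n_wavenumber_samples = as.integer(n_wavenumber_samples),
      n_theta_x = as.integer(n_theta_x),
      n_theta_y = as.integer(n_theta_y),
      theta_span = theta_span,
      alci_pixel_to_depth = alci_pixel_to_depth,
      oct_axial_pixel = oct_axial_pixel
    ),
    class = "optical_config"
  )
}

#' @rdname optical_config
#' @param cfg an `optical_config`.
#' @export
lag_spacing <- function(cfg) cfg$center_wavelength / cfg$theta_span

#' @rdname optical_config
#' @export
max_lag <- function(cfg) (min(cfg$n_theta_x, cfg$n_theta_y) / 2) * lag_spacing(cfg)

#' @export
print.optical_config <- function(x, ...) {
  cat("Optical configuration\n")
  cat(sprintf("  lambda: %.3f um   theta span: %.3f rad\n",
              x$center_wavelength, x$theta_span))
  cat(sprintf("  angular grid: %d x %d   spectral samples: %d\n",
              x$n_theta_x, x$n_theta_y, x$n_wavenumber_samples))
  cat(sprintf("  lag spacing: %.3f um   max lag: %.1f um\n",
              lag_spacing(x), max_lag(x)))
  cat(sprintf("  a/LCI depth pixel: %.2f um/px   OCT axial pixel: %.2f um/px\n",
              x$alci_pixel_to_depth, x$oct_axial_pixel))
  invisible(x)
}

#' Specification of a synthetic scattering medium
#'
#' Parameterizes one synthetic 2D angular scattering plane: the ground-truth
#' power-law exponent of its radial correlation-energy curve, the intensity
#' scale, and the length-scale window over which the power law is guaranteed.
#' Below `inner_scale` the correlation profile plateaus; the law `C(r)
#' proportional to r^(-alpha_true)` holds for lags in `[inner_scale,
#' outer_scale]`.
#'
#' @param alpha_true target log-log slope of the azimuthally integrated
#'   correlation-energy curve, in `[0, 3)`.
#' @param amplitude mean intensity of the plane (arbitrary units).
#' @param inner_scale,outer_scale power-law window bounds, microns.
#' @param texture_contrast relative pixel-intensity standard deviation of the
#'   textured field before clipping (dimensionless).
#' @param seed integer seed; identical spec + seed gives bit-identical planes.
#' @return an object of class `medium_spec`.
#' @export
medium_spec <- function(alpha_true, amplitude = 1, inner_scale = 1.5,
                        outer_scale = 12, texture_contrast = 0.3, seed = 1L) {
  stopifnot(
    is_scalar(alpha_true), alpha_true >= 0, alpha_true < 3,
    is_scalar(amplitude), amplitude > 0,
    is_scalar(inner_scale), inner_scale > 0,
    is_scalar(outer_scale),
    is_scalar(texture_contrast), texture_contrast > 0
  )
  if (inner_scale >= outer_scale) stop("inner_scale must be < outer_scale")
  structure(
    list(alpha_true = alpha_true, amplitude = amplitude,
         inner_scale = inner_scale, outer_scale = outer_scale,
         texture_contrast = texture_contrast, seed = as.integer(seed)),
    class = "medium_spec"
  )
}

#' Two-group cohort specification
#'
#' Describes a synthetic wild-type (WT) vs disease-model (AD) cohort of eyes,
#' each sampled at `n_locations` retinal locations around the optic nerve
#' head. Per layer and group, `layer_params` gives the means and standard
#' deviations of the ground-truth correlation slope alpha, layer thickness
#' (microns) and scattering-intensity scale. Location-level deviations of
#' every parameter are drawn per eye from a multivariate normal with a
#' compound-symmetric correlation `within_eye_rho` across locations.
#'
#' The default parameters encode the disease-direction configuration studied
#' by the package's validation suite: a thinner AD nerve fiber layer (16 vs
#' 18 microns), a higher AD correlation slope in all three layers, and an AD
#' scattering-intensity elevation confined to the superior retinal locations
#' of the NFL. Intensity variation is dominated by a common-mode
#' per-(eye, location) coupling factor shared by the three layers
#' (`intensity_common_sd`), on top of small layer-specific fluctuations.
#'
#' @param n_wt_eyes,n_ad_eyes eyes per group (study design: 10 WT, 13 AD).
#' @param n_locations retinal locations per eye (study design: 8, at +-500
#'   and +-1000 micron offsets along the horizontal and vertical axes).
#' @param layer_params nested list `layer_params[[layer]][[group]]` with
#'   elements `alpha_mean`, `alpha_sd`, `thickness_mean`, `thickness_sd`,
#'   `intensity_mean`, `intensity_sd`; layers NFL, OPL, RPE; groups WT, AD.
#' @param superior_intensity_delta named per-layer additive intensity effect
#'   applied to AD eyes at superior locations only.
#' @param intensity_common_sd standard deviation of the cross-layer
#'   common-mode intensity factor.
#' @param within_eye_rho compound-symmetry correlation across locations;
#'   must lie in `(-1/(n_locations-1), 1)`.
#' @param artifact_rate fraction of records receiving an injected specular
#'   artifact (with ground-truth footprint recorded).
#' @param seed master seed for the cohort.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_wt_eyes = 10, n_ad_eyes = 13, n_locations = 8,
                        layer_params = default_layer_params(),
                        superior_intensity_delta = c(NFL = 0.5, OPL = 0, RPE = 0),
                        intensity_common_sd = 0.10,
                        within_eye_rho = -0.14,
                        artifact_rate = 0,
                        seed = 1L) {
  stopifnot(
    is_count(n_wt_eyes, 2), is_count(n_ad_eyes, 2), is_count(n_locations, 2),
    is_scalar(within_eye_rho), is_scalar(intensity_common_sd),
    intensity_common_sd >= 0,
    is_scalar(artifact_rate), artifact_rate >= 0, artifact_rate <= 1
  )
  lo <- -1 / (n_locations - 1)
  if (within_eye_rho <= lo || within_eye_rho >= 1) {
    stop(sprintf("within_eye_rho must lie in (%.4f, 1) for %d locations",
                 lo, n_locations))
  }
  layers <- c("NFL", "OPL", "RPE")
  stopifnot(all(layers %in% names(layer_params)))
  for (l in layers) {
    for (g in c("WT", "AD")) {
      p <- layer_params[[l]][[g]]
      stopifnot(all(c("alpha_mean", "alpha_sd", "thickness_mean",
                      "thickness_sd", "intensity_mean", "intensity_sd")
                    %in% names(p)))
    }
  }
  sd_ <- superior_intensity_delta
  if (is.null(names(sd_))) names(sd_) <- layers
  structure(
    list(n_wt_eyes = as.integer(n_wt_eyes), n_ad_eyes = as.integer(n_ad_eyes),
         n_locations = as.integer(n_locations), layer_params = layer_params,
         superior_intensity_delta = sd_[layers],
         intensity_common_sd = intensity_common_sd,
         within_eye_rho = within_eye_rho, artifact_rate = artifact_rate,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' @rdname cohort_spec
#' @param group_effects named list of additive AD-minus-WT effects used to
#'   build the default parameter table: `alpha` (same for all layers),
#'   `nfl_thickness_um`. Set both to 0 for a global-null cohort.
#' @export
default_layer_params <- function(group_effects = list(alpha = 0.25,
                                                      nfl_thickness_um = -2)) {
  base <- list(
    NFL = list(alpha = 0.80, thickness = 18, intensity = 1.0),
    OPL = list(alpha = 1.00, thickness = 16, intensity = 1.0),
    RPE = list(alpha = 1.20, thickness = 14, intensity = 1.0)
  )
  out <- list()
  for (l in names(base)) {
    b <- base[[l]]
    wt <- list(alpha_mean = b$alpha, alpha_sd = 0.15,
               thickness_mean = b$thickness, thickness_sd = 1.5,
               intensity_mean = b$intensity, intensity_sd = 0.03)
    ad <- wt
    ad$alpha_mean <- b$alpha + group_effects$alpha
    if (l == "NFL") ad$thickness_mean <- b$thickness + group_effects$nfl_thickness_um
    out[[l]] <- list(WT = wt, AD = ad)
  }
  out
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Cohort spec: %d WT + %d AD eyes x %d locations (rho = %.3f, seed %d)\n",
              x$n_wt_eyes, x$n_ad_eyes, x$n_locations, x$within_eye_rho, x$seed))
  invisible(x)
}

#' Retinal sampling locations and quadrant tags
#'
#' The eight default locations are the +-500 and +-1000 micron offsets from
#' the optic nerve head along the horizontal and vertical axes. With the
#' superior quadrant aligned to +Y: +Y offsets are superior, -Y inferior,
#' +X nasal, -X temporal. For `n_locations != 8` the offsets are interleaved
#' multiples of 500 microns along the two axes.
#'
#' @param n_locations number of locations.
#' @return data.frame with columns `location`, `x_um`, `y_um`, `quadrant`.
#' @export
location_layout <- function(n_locations = 8) {
  steps <- ceiling(n_locations / 4)
  offs <- rep(500 * seq_len(steps), each = 4)
  dirx <- rep(c(1, -1, 0, 0), steps)
  diry <- rep(c(0, 0, 1, -1), steps)
  x <- (offs * dirx)[seq_len(n_locations)]
  y <- (offs * diry)[seq_len(n_locations)]
  quadrant <- ifelse(y > 0, "superior",
              ifelse(y < 0, "inferior",
              ifelse(x > 0, "nasal", "temporal")))
  data.frame(location = seq_len(n_locations), x_um = x, y_um = y,
             quadrant = quadrant, stringsAsFactors = FALSE)
}
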