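# Synthesis of 2D angular scattering planes with a prescribed radial
# correlation power law. The construction works directly in the correlation
# (spatial-lag) domain: a target magnitude is laid down on the lag grid,
# given Hermitian random phases, and transformed to the angular domain, so
# the analysis chain (|FFT| -> azimuthal sum -> log-log fit) sees exactly
# the prescribed curve up to the nonnegativity clip.

# Radial annulus geometry of an n x m lag grid with spacing dr and bin
# width bw: bin index per pixel (unshifted FFT order), per-bin pixel counts
# and centers. Cached per geometry because cohort generation reuses it
# thousands of times.
radial_geometry <- local({
  cache <- new.env(parent = emptyenv())
  function(n, m, dr, bw = dr) {
    key <- paste(n, m, signif(dr, 12), signif(bw, 12), sep = "_")
    if (!is.null(cache[[key]])) return(cache[[key]])
    fx <- c(0:(n %/% 2 - 1), -(n - n %/% 2):-1) * dr
    fy <- c(0:(m %/% 2 - 1), -(m - m %/% 2):-1) * dr
    R <- sqrt(outer(fx^2, fy^2, `+`))
    bin <- matrix(as.integer(floor(R / bw)), n, m)
    counts <- tabulate(bin + 1L)
    geom <- list(R = R, bin = bin, counts = counts,
                 centers = (seq_along(counts) - 0.5) * bw, bw = bw)
    cache[[key]] <- geom
    geom
  }
})

# Per-pixel target correlation magnitude for a medium spec: bin energies
# E_b = A * r_b^(-alpha) for bin centers >= inner_scale (plateau below),
# split evenly over each annulus's pixels so the azimuthal *sum* follows
# the law exactly. profile_fun(r_centers) can override the bin-energy law.
target_correlation <- function(spec, geom, profile_fun = NULL) {
  ctr <- geom$centers
  if (is.null(profile_fun)) {
    r_eff <- pmax(ctr, spec$inner_scale)
    Eb <- r_eff^(-spec$alpha_true)
  } else {
    Eb <- profile_fun(ctr)
    stopifnot(length(Eb) == length(ctr), all(is.finite(Eb)), all(Eb >= 0))
  }
  ppx <- Eb / geom$counts
  C <- matrix(ppx[geom$bin + 1L], nrow(geom$bin), ncol(geom$bin))
  C[1, 1] <- 0 # zero lag carried by the mean offset instead
  C
}

#' Synthesize a 2D angular scattering plane with known correlation slope
#'
#' Builds a nonnegative angular intensity plane (theta_x by theta_y) whose
#' azimuthally integrated two-point correlation-energy curve follows
#' `C(r) = A * r^(-alpha_true)` for lags between `inner_scale` and
#' `outer_scale`. The target magnitude is placed on the spatial-lag grid,
#' given Hermitian-symmetric random phases (so the inverse transform is
#' real), standardized, and mapped to intensities
#' `amplitude * max(1 + texture_contrast * z, 0)`. The clip to nonnegative
#' values affects a negligible fraction of pixels at the default contrast;
#' the zero-lag (total power) bin absorbs the mean offset and is excluded
#' from slope fits downstream.
#'
#' @param spec a [medium_spec()].
#' @param cfg an [optical_config()]; sets the grid size and lag spacing.
#' @param profile_fun optional function of radial bin centers (microns)
#'   returning target per-annulus correlation energies; overrides the
#'   power law (used e.g. for broken-power-law planes).
#' @return matrix `n_theta_x` x `n_theta_y` of nonnegative intensities, with
#'   attribute `alpha_true`.
#' @examples
#' cfg <- optical_config()
#' p <- make_angular_plane(medium_spec(alpha_true = 1, seed = 7), cfg)
#' range(p)
#' @export
make_angular_plane <- function(spec, cfg, profile_fun = NULL) {
  stopifnot(inherits(spec, "medium_spec"), inherits(cfg, "optical_config"))
  dr <- lag_spacing(cfg)
  rmax <- max_lag(cfg)
  n_in_window <- floor(spec$outer_scale / dr) - ceiling(spec$inner_scale / dr) + 1
  if (spec$outer_scale > rmax || n_in_window < 8) {
    stop_retscat(
      sprintf(paste0("power-law window [%.2f, %.2f] um not realizable: lag ",
                     "spacing delta_r = %.3f um, maximum lag r_max = %.2f um ",
                     "(need outer_scale <= r_max and >= 8 lag samples in window)"),
              spec$inner_scale, spec$outer_scale, dr, rmax),
      "retscat_config_error"
    )
  }
  n <- cfg$n_theta_x
  m <- cfg$n_theta_y
  geom <- radial_geometry(n, m, dr)
  C <- target_correlation(spec, geom, profile_fun)
  set.seed(spec$seed)
  W <- stats::fft(matrix(stats::rnorm(n * m), n, m))
  U <- W / pmax(Mod(W), 1e-300)
  z <- Re(stats::fft(C * U, inverse = TRUE)) / (n * m)
  z <- (z - mean(z)) / stats::sd(z)
  plane <- spec$amplitude * pmax(1 + spec$texture_contrast * z, 0)
  attr(plane, "alpha_true") <- spec$alpha_true
  plane
}

#' Inject a specular-reflection hot spot into an angular plane
#'
#' Multiplies the pixels inside a disc by `gain`, emulating the saturating
#' specular reflection from the crystalline lens seen in measured angular
#' scattering distributions. The injected footprint is returned as an
#' attribute so downstream artifact detection can be validated against
#' ground truth.
#'
#' @param plane numeric matrix.
#' @param center integer `(row, col)` indices of the disc center (1-based).
#' @param radius disc radius in pixels.
#' @param gain multiplicative gain applied inside the disc.
#' @return the modified plane with attribute `specular_footprint` (logical
#'   matrix, `TRUE` inside the disc).
#' @export
inject_specular <- function(plane, center, radius, gain) {
  stopifnot(is.matrix(plane), length(center) == 2,
            is_scalar(radius), radius >= 0, is_scalar(gain))
  n <- nrow(plane); m <- ncol(plane)
  if (center[1] - radius < 1 || center[1] + radius > n ||
      center[2] - radius < 1 || center[2] + radius > m) {
    stop("specular disc must lie entirely inside the plane")
  }
  d2 <- outer((seq_len(n) - center[1])^2, (seq_len(m) - center[2])^2, `+`)
  foot <- d2 <= radius^2
  out <- plane
  out[foot] <- out[foot] * gain
  attr(out, "alpha_true") <- attr(plane, "alpha_true")
  attr(out, "specular_footprint") <- foot
  out
}
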