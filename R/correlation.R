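# Two-point spatial correlation analysis of angular scattering planes:
# Fourier transform to the lag domain, azimuthal integration, and log-log
# power-law slope / fractal dimension extraction.

fftshift2 <- function(x) {
  n <- nrow(x); m <- ncol(x)
  x[c((n %/% 2 + 1):n, 1:(n %/% 2)), c((m %/% 2 + 1):m, 1:(m %/% 2))]
}

#' Two-point spatial correlation map of an angular plane
#'
#' The Fourier transform of the angular scattering distribution yields the
#' two-point spatial correlation of the optical field; this computes the
#' magnitude of the centered 2D DFT of the (mask-filled) plane, with lag
#' axes given by the small-angle conversion `delta_r = lambda / theta_span`.
#' Excluded pixels are filled with the median of the retained pixels by
#' default (avoids the spectral leakage of hard zeros); `fill = "zero"`
#' zero-fills instead.
#'
#' @param plane an [angular_plane()] or numeric matrix.
#' @param cfg an [optical_config()].
#' @param fill `"median"` or `"zero"` replacement for excluded pixels.
#' @return object of class `correlation_map`: list with `magnitude`
#'   (fftshifted), `lag_x`, `lag_y` (microns), `lag_spacing`.
#' @export
angular_to_correlation <- function(plane, cfg, fill = c("median", "zero")) {
  fill <- match.arg(fill)
  p <- as_angular_plane(plane)
  x <- p$intensity
  if (all(p$mask)) stop("all pixels excluded; nothing to transform")
  if (any(p$mask)) {
    x[p$mask] <- if (fill == "median") stats::median(x[!p$mask]) else 0
  }
  dr <- lag_spacing(cfg)
  n <- nrow(x); m <- ncol(x)
  mag <- fftshift2(Mod(stats::fft(x)))
  structure(
    list(magnitude = mag,
         lag_x = (seq_len(n) - 1 - n %/% 2) * dr,
         lag_y = (seq_len(m) - 1 - m %/% 2) * dr,
         lag_spacing = dr),
    class = "correlation_map"
  )
}

#' Azimuthally integrate a correlation map to radial correlation energy
#'
#' Sums correlation magnitudes over annuli `[r_i, r_i + bin_width)` of the
#' radial lag (integration, not averaging, so annulus area contributes to
#' the energy), excluding the zero-lag pixel, which carries total power
#' rather than texture. Only complete annuli are reported: bins extending
#' beyond the inscribed circle of the lag grid (radius `r_max`) would be
#' truncated by the grid corners and bias the curve downward.
#'
#' @param corr a [correlation_map()].
#' @param bin_width annulus width, microns; at least the lag spacing
#'   (default: equal to it).
#' @return data.frame of class `correlation_curve` with columns `lag`
#'   (bin centers, microns), `energy`, `n_pixels`.
#' @export
azimuthal_integrate <- function(corr, bin_width = NULL) {
  stopifnot(inherits(corr, "correlation_map"))
  dr <- corr$lag_spacing
  bw <- bin_width %||% dr
  if (bw < dr) stop("bin_width must be >= the lag spacing")
  R <- sqrt(outer(corr$lag_x^2, corr$lag_y^2, `+`))
  zero <- R == 0
  bin <- as.integer(floor(R / bw))
  keep <- !zero
  energy <- tapply(corr$magnitude[keep], bin[keep], sum)
  counts <- tapply(corr$magnitude[keep], bin[keep], length)
  idx <- as.integer(names(energy))
  r_edge <- min(max(abs(corr$lag_x)), max(abs(corr$lag_y)))
  complete <- (idx + 1) * bw <= r_edge + 1e-9
  idx <- idx[complete]
  out <- data.frame(lag = (idx + 0.5) * bw,
                    energy = as.numeric(energy)[complete],
                    n_pixels = as.integer(counts)[complete])
  out <- out[order(out$lag), ]
  rownames(out) <- NULL
  class(out) <- c("correlation_curve", "data.frame")
  out
}

#' Fit the log-log power-law slope of a correlation curve
#'
#' Ordinary least squares of `log10(energy)` on `log10(lag)` restricted to
#' the window, with `alpha = -slope` and fractal dimension `fd = 3 - alpha`.
#' The default 2-10 micron window targets cellular and sub-cellular length
#' scales.
#'
#' @param curve a [correlation_curve][azimuthal_integrate()].
#' @param window `(r_lo, r_hi)` window, microns.
#' @return object of class `slope_fit`: `alpha`, `fd`, `window`,
#'   `r_squared`, `n_points`, `intercept`.
#' @export
fit_slope <- function(curve, window = c(2, 10)) {
  stopifnot(inherits(curve, "correlation_curve") || is.data.frame(curve),
            length(window) == 2, window[1] < window[2])
  use <- curve$lag >= window[1] & curve$lag <= window[2] & curve$energy > 0 &
    curve$n_pixels > 0
  n <- sum(use)
  if (n < 4) {
    dr <- if (nrow(curve) > 1) min(diff(sort(curve$lag))) else NA_real_
    stop_retscat(
      sprintf(paste0("only %d usable bins in window [%g, %g] um ",
                     "(bin spacing %.3g um); need >= 4"),
              n, window[1], window[2], dr),
      "retscat_fit_error"
    )
  }
  lx <- log10(curve$lag[use])
  ly <- log10(curve$energy[use])
  fit <- stats::lm.fit(cbind(1, lx), ly)
  slope <- fit$coefficients[2]
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((ly - mean(ly))^2)
  alpha <- as.numeric(-slope)
  structure(
    list(alpha = alpha, fd = 3 - alpha,
         window = as.numeric(window),
         r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
         n_points = n, intercept = as.numeric(fit$coefficients[1])),
    class = "slope_fit"
  )
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf("Power-law fit [%g, %g] um: alpha = %.3f (FD = %.3f), R2 = %.3f, n = %d\n",
              x$window[1], x$window[2], x$alpha, x$fd,
              x$r_squared, x$n_points))
  invisible(x)
}

#' Long-range correlation slope
#'
#' [fit_slope()] over the long-range window (20-100 microns by default);
#' the window must lie inside the realizable lag axis of the map the curve
#' came from (an error names the window otherwise, via the usable-bin
#' check).
#'
#' @inheritParams fit_slope
#' @export
long_range_slope <- function(curve, window = c(20, 100)) {
  fit_slope(curve, window = window)
}

#' Full per-plane correlation analysis
#'
#' Convenience chain: correlation map, azimuthal integration, short-range
#' slope fit.
#'
#' @param plane an [angular_plane()] or matrix.
#' @param cfg an [optical_config()].
#' @param window fit window, microns.
#' @param ... passed to [angular_to_correlation()].
#' @return a [fit_slope()] result.
#' @export
plane_slope <- function(plane, cfg, window = c(2, 10), ...) {
  fit_slope(azimuthal_integrate(angular_to_correlation(plane, cfg, ...)),
            window = window)
}
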