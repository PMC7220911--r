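# Two-point correlation, azimuthal integration, slope fitting.

test_that("FFT correlation equals the brute-force DFT double sum", {
  cfg <- small_cfg(32)
  set.seed(6)
  for (i in 1:3) {
    p <- matrix(runif(32 * 32), 32, 32)
    corr <- angular_to_correlation(p, cfg)
    bf <- brute_force_correlation(p)
    expect_lt(max(abs(corr$magnitude - bf)) / max(bf), 1e-9)
  }
})

test_that("correlation maps have the documented structure", {
  cfg <- optical_config()
  p <- make_angular_plane(medium_spec(0.9, seed = 3L), cfg)
  corr <- angular_to_correlation(p, cfg)
  n <- nrow(corr$magnitude)
  ctr <- n %/% 2 + 1
  # maximum at zero lag, equal to |sum of plane|
  expect_equal(which(corr$magnitude == max(corr$magnitude))[1],
               (ctr - 1) * n + ctr)
  expect_equal(corr$magnitude[ctr, ctr], sum(p), tolerance = 1e-9)
  # point-reflection symmetry (excluding the unpaired Nyquist row/col)
  sub <- corr$magnitude[2:n, 2:n]
  expect_lt(max(abs(sub - sub[(n - 1):1, (n - 1):1])) / max(sub), 1e-9)
  # uniform plane: all energy at zero lag
  cu <- angular_to_correlation(matrix(2, 64, 64), cfg)
  expect_equal(sum(cu$magnitude > 1e-9 * max(cu$magnitude)), 1)
})

test_that("a Gaussian angular profile transforms to its conjugate width", {
  # intensity exp(-theta^2 / (2 s^2)) -> correlation width lambda/(2 pi s)
  cfg <- optical_config(n_theta_x = 256, n_theta_y = 256)
  th <- seq(-cfg$theta_span / 2, cfg$theta_span / 2, length.out = 256)
  s <- cfg$theta_span / 24
  p <- outer(exp(-th^2 / (2 * s^2)), exp(-th^2 / (2 * s^2)))
  corr <- angular_to_correlation(p, cfg)
  ctr <- 129
  prof <- corr$magnitude[, ctr]
  r <- abs(corr$lag_x)
  fit <- lm(log(prof[prof > max(prof) * 1e-4]) ~
              I(r[prof > max(prof) * 1e-4]^2))
  width_hat <- sqrt(-1 / (2 * coef(fit)[2]))
  width_expect <- cfg$center_wavelength / (2 * pi * s)
  expect_lt(abs(width_hat - width_expect) / width_expect, 0.02)
})

test_that("masked pixels are filled before the transform", {
  cfg <- optical_config()
  p <- make_angular_plane(medium_spec(1.0, seed = 8L), cfg)
  mask <- matrix(FALSE, 64, 64); mask[10:12, 20:22] <- TRUE
  cm <- angular_to_correlation(apply_mask(p, mask), cfg)
  expect_true(all(is.finite(cm$magnitude)))
  cz <- angular_to_correlation(apply_mask(p, mask), cfg, fill = "zero")
  expect_false(identical(cm$magnitude, cz$magnitude))
  expect_error(angular_to_correlation(
    apply_mask(p, matrix(TRUE, 64, 64)), cfg), "all pixels excluded")
})

test_that("azimuthal integration matches per-pixel binning and annulus geometry", {
  cfg <- optical_config()
  p <- make_angular_plane(medium_spec(0.6, seed = 12L), cfg)
  corr <- angular_to_correlation(p, cfg)
  curve <- azimuthal_integrate(corr, bin_width = 2)
  oracle <- azimuthal_oracle(corr, 2)
  expect_equal(curve$lag, oracle$lag)
  expect_equal(curve$energy, oracle$energy, tolerance = 1e-12)
  expect_true(all(diff(curve$lag) > 0))
  expect_true(all(curve$energy >= 0))
  # transposing the map (90-degree rotation + reflection about the
  # diagonal, which preserves every radius) leaves the curve unchanged
  corr90 <- corr
  corr90$magnitude <- t(corr$magnitude)
  expect_equal(azimuthal_integrate(corr90)$energy,
               azimuthal_integrate(corr)$energy, tolerance = 1e-12)
  expect_error(azimuthal_integrate(corr, bin_width = 0.5), "bin_width")
})

test_that("a ring impulse lands in the bin containing its radius", {
  cfg <- optical_config()
  corr <- angular_to_correlation(matrix(1, 64, 64), cfg)
  R <- sqrt(outer(corr$lag_x^2, corr$lag_y^2, `+`))
  corr$magnitude <- 1 * (abs(R - 7.2) < 0.5)
  curve <- azimuthal_integrate(corr)
  expect_equal(curve$lag[which.max(curve$energy)], 7.5) # bin [7, 8)
})

test_that("slope fits are exact on analytic power laws", {
  f <- fit_slope(power_curve(1))
  expect_equal(f$alpha, 1, tolerance = 1e-9)
  expect_identical(f$fd, 3 - f$alpha)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)

  fc <- fit_slope(power_curve(0))
  expect_equal(fc$alpha, 0, tolerance = 1e-12)
  expect_equal(fc$fd, 3)

  expect_error(fit_slope(power_curve(1, lags = c(3, 4, 5))), "usable bins",
               class = "retscat_fit_error")
})

test_that("scale equivariance: rescaling shifts only the intercept", {
  cfg <- optical_config()
  p <- make_angular_plane(medium_spec(1.1, seed = 19L), cfg)
  c1 <- azimuthal_integrate(angular_to_correlation(p, cfg))
  c5 <- azimuthal_integrate(angular_to_correlation(p * 5, cfg))
  expect_equal(c5$energy, 5 * c1$energy, tolerance = 1e-12)
  f1 <- fit_slope(c1); f5 <- fit_slope(c5)
  expect_equal(f5$alpha, f1$alpha, tolerance = 1e-10)
  expect_equal(f5$intercept - f1$intercept, log10(5), tolerance = 1e-9)
})

test_that("long-range windows behave consistently", {
  cfg <- optical_config(n_theta_x = 256, n_theta_y = 256)
  # single power law across both windows
  p <- make_angular_plane(medium_spec(1.0, inner_scale = 1.5,
                                      outer_scale = 110, seed = 4L), cfg)
  curve <- azimuthal_integrate(angular_to_correlation(p, cfg))
  fs <- fit_slope(curve)
  fl <- long_range_slope(curve)
  expect_lt(abs(fl$alpha - fs$alpha) / fs$alpha, 0.05)

  # broken power law: steeper tail raises the long-window slope
  geom_alpha <- function(r) ifelse(r < 15, r^(-0.5), 15 * r^(-1.5))
  pb <- make_angular_plane(medium_spec(0.5, outer_scale = 110, seed = 5L),
                           cfg, profile_fun = geom_alpha)
  cb <- azimuthal_integrate(angular_to_correlation(pb, cfg))
  expect_gt(long_range_slope(cb)$alpha, fit_slope(cb)$alpha)

  # window beyond the realizable lag axis errors
  small_curve <- azimuthal_integrate(
    angular_to_correlation(make_angular_plane(medium_spec(1, seed = 1L),
                                              optical_config()),
                           optical_config()))
  expect_error(long_range_slope(small_curve, window = c(40, 100)),
               class = "retscat_fit_error")
})
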