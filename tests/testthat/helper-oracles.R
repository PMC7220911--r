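# Shared fixtures and independent oracles.

small_cfg <- function(n = 32) {
  optical_config(n_theta_x = n, n_theta_y = n, n_wavenumber_samples = 64)
}

# Brute-force centered 2D DFT magnitude via explicit exponential matrices
# (no fft call): F[u, v] = sum_{x,y} P[x, y] exp(-2 pi i (ux/n + vy/m)).
brute_force_correlation <- function(plane) {
  n <- nrow(plane); m <- ncol(plane)
  wx <- exp(-2i * pi * outer(0:(n - 1), 0:(n - 1)) / n)
  wy <- exp(-2i * pi * outer(0:(m - 1), 0:(m - 1)) / m)
  F <- wx %*% plane %*% wy
  mag <- Mod(F)
  # center (fftshift) to match correlation_map layout
  mag[c((n %/% 2 + 1):n, 1:(n %/% 2)), c((m %/% 2 + 1):m, 1:(m %/% 2))]
}

# Direct-sum moment oracle (population divisor).
moment_oracle <- function(x) {
  N <- length(x)
  mu <- sum(x) / N
  m2 <- sum((x - mu)^2) / N
  m3 <- sum((x - mu)^3) / N
  m4 <- sum((x - mu)^4) / N
  list(mean = mu, variance = m2, skewness = m3 / m2^1.5,
       kurtosis = m4 / m2^2 - 3)
}

# Per-pixel azimuthal binning oracle on a centered correlation map
# (complete annuli only, matching the documented convention).
azimuthal_oracle <- function(corr, bw) {
  R <- sqrt(outer(corr$lag_x^2, corr$lag_y^2, `+`))
  keep <- R > 0
  bin <- floor(R[keep] / bw)
  en <- tapply(corr$magnitude[keep], bin, sum)
  idx <- as.numeric(names(en))
  r_edge <- min(max(abs(corr$lag_x)), max(abs(corr$lag_y)))
  ok <- (idx + 1) * bw <= r_edge + 1e-9
  data.frame(lag = (idx[ok] + 0.5) * bw, energy = as.numeric(en)[ok])
}

# Exact power-law correlation curve (for fit oracles).
power_curve <- function(alpha, lags = seq(1.5, 15, by = 0.5)) {
  structure(data.frame(lag = lags, energy = lags^(-alpha),
                       n_pixels = rep(10L, length(lags))),
            class = c("correlation_curve", "data.frame"))
}

tiny_cohort_spec <- function(...) {
  cohort_spec(n_wt_eyes = 3, n_ad_eyes = 3, ...)
}
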