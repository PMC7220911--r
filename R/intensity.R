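# Masked intensity-histogram statistics of angular scattering planes.

#' Histogram and moment statistics of a masked angular plane
#'
#' Computes the intensity histogram (pixel counts `k` per bin out of `N`
#' retained pixels) and the mean, population variance (divisor `N`),
#' skewness and excess kurtosis of the retained pixel intensities. Moments
#' are computed from the raw retained pixels, not from binned counts, which
#' is exactly the singleton-bin limit of the count-weighted formulas; the
#' histogram is a reporting artifact. For a degenerate (zero-variance)
#' plane, skewness and excess kurtosis are reported as 0 by convention.
#'
#' @param plane an [angular_plane()] or matrix; excluded pixels are ignored.
#' @param n_bins number of histogram bins.
#' @param min_pixels minimum retained pixels before the record is flagged.
#' @return list with `histogram` (`breaks`, `counts`, `N`) and `stats`
#'   (object of class `intensity_stats`: `mean`, `variance`, `skewness`,
#'   `kurtosis`, `n`, `flagged`).
#' @export
histogram_stats <- function(plane, n_bins = 50, min_pixels = 100) {
  p <- as_angular_plane(plane)
  x <- p$intensity[!p$mask]
  N <- length(x)
  if (N == 0) stop("no retained pixels")
  flagged <- N < min_pixels
  m <- mean(x)
  v <- sum((x - m)^2) / N
  if (v > 0) {
    sk <- (sum((x - m)^3) / N) / v^1.5
    ku <- (sum((x - m)^4) / N) / v^2 - 3
  } else {
    sk <- 0
    ku <- 0
  }
  rng <- range(x)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- graphics::hist(x, breaks = breaks, plot = FALSE)$counts
  stats <- structure(
    list(mean = m, variance = v, skewness = sk, kurtosis = ku,
         n = N, flagged = flagged),
    class = "intensity_stats"
  )
  list(histogram = list(breaks = breaks, counts = counts, N = N),
       stats = stats)
}

#' @export
print.intensity_stats <- function(x, ...) {
  cat(sprintf("Intensity stats (N = %d%s): mean %.4g, var %.4g, skew %.3f, ex.kurt %.3f\n",
              x$n, if (x$flagged) ", FLAGGED" else "", x$mean, x$variance,
              x$skewness, x$kurtosis))
  invisible(x)
}

#' Normalize per-record metric values to the WT group mean
#'
#' Display normalization used for group summaries: every value is divided
#' by the reference (WT) group mean of that metric, so the normalized WT
#' mean is 1 by construction. Inference is performed on raw values; this
#' rescaling leaves every test statistic unchanged.
#'
#' @param values numeric vector of per-record metric values.
#' @param group character/factor vector of group labels, same length.
#' @param reference_group label of the reference group.
#' @return normalized values.
#' @export
normalize_group <- function(values, group, reference_group = "WT") {
  stopifnot(length(values) == length(group),
            reference_group %in% group)
  ref <- mean(values[group == reference_group])
  if (!is.finite(ref) || ref == 0) {
    stop("reference group mean is zero; cannot normalize")
  }
  values / ref
}
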