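# Two-group synthetic cohorts with compound-symmetric within-eye
# correlation and full ground-truth bookkeeping.

# Sample one compound-symmetric N(0, CS(rho)) k-vector: scale the mean
# component by sqrt(1 + (k-1) rho) and the centered component by
# sqrt(1 - rho) (the two eigenspaces of the CS matrix).
rnorm_cs <- function(k, rho) {
  z <- stats::rnorm(k)
  zb <- mean(z)
  sqrt(1 + (k - 1) * rho) * zb + sqrt(1 - rho) * (z - zb)
}

#' Generate a synthetic WT vs AD cohort
#'
#' Draws ground-truth parameters for every (eye, location, layer) record --
#' correlation slope alpha, layer thickness and scattering-intensity scale,
#' each as group mean plus a compound-symmetric location deviation -- and
#' synthesizes the corresponding measurement data. Group effects are
#' applied additively to the per-layer means; the AD superior-quadrant
#' intensity effect of the spec is added only at superior locations.
#'
#' Detail levels: `"truth"` draws ground truth only (for marginal and
#' correlation checks at large n); `"planes"` (default) additionally
#' synthesizes per-layer angular scattering planes and a speckled B-scan
#' per record; `"spectra"` also encodes each record's planes into raw
#' interferometric scans over theta_y (use a small [optical_config()]; this
#' level exercises the full spectral chain and is intended for small
#' cohorts).
#'
#' All randomness derives from `spec$seed` through the documented
#' per-stage, per-record counter scheme of [derive_seed()], so identical
#' spec + configuration reproduce the cohort byte for byte.
#'
#' @param spec a [cohort_spec()].
#' @param cfg an [optical_config()].
#' @param level detail level, see above.
#' @param speckle_level B-scan speckle strength.
#' @return object of class `alci_cohort`: `records` (list; each has `eye`,
#'   `group`, `location`, `quadrant`, `bscan`, `planes`, optionally
#'   `scans`, `artifact`), `truth` (long data.frame of ground-truth
#'   parameters), `locations`, `spec`, `cfg`, `level`.
#' @export
generate_cohort <- function(spec, cfg = optical_config(),
                            level = c("planes", "spectra", "truth"),
                            speckle_level = 0.3) {
  level <- match.arg(level)
  stopifnot(inherits(spec, "cohort_spec"), inherits(cfg, "optical_config"))
  layers <- c("NFL", "OPL", "RPE")
  locs <- location_layout(spec$n_locations)
  k <- spec$n_locations
  rho <- spec$within_eye_rho
  eyes <- c(sprintf("WT%02d", seq_len(spec$n_wt_eyes)),
            sprintf("AD%02d", seq_len(spec$n_ad_eyes)))
  groups <- rep(c("WT", "AD"), c(spec$n_wt_eyes, spec$n_ad_eyes))

  truth <- vector("list", length(eyes))
  for (e in seq_along(eyes)) {
    set.seed(derive_seed(spec$seed, 1L, e))
    common <- rnorm_cs(k, rho) * spec$intensity_common_sd
    g <- groups[e]
    per_layer <- lapply(layers, function(l) {
      p <- spec$layer_params[[l]][[g]]
      alpha <- p$alpha_mean + p$alpha_sd * rnorm_cs(k, rho)
      thick <- p$thickness_mean + p$thickness_sd * rnorm_cs(k, rho)
      inten <- p$intensity_mean + common + p$intensity_sd * rnorm_cs(k, rho)
      if (g == "AD") {
        sup <- locs$quadrant == "superior"
        inten[sup] <- inten[sup] + spec$superior_intensity_delta[[l]]
      }
      data.frame(eye = eyes[e], group = g, location = locs$location,
                 quadrant = locs$quadrant, layer = l,
                 alpha_true = pmin(pmax(alpha, 0.02), 2.9),
                 thickness_true_um = pmax(thick, cfg$oct_axial_pixel),
                 intensity_true = pmax(inten, 0.05),
                 stringsAsFactors = FALSE)
    })
    truth[[e]] <- do.call(rbind, per_layer)
  }
  truth <- do.call(rbind, truth)
  truth <- truth[order(match(truth$eye, eyes), truth$location,
                       match(truth$layer, layers)), ]
  rownames(truth) <- NULL
  truth$artifact <- FALSE

  records <- NULL
  if (level != "truth") {
    rec_idx <- 0L
    records <- vector("list", length(eyes) * k)
    for (e in seq_along(eyes)) {
      for (li in seq_len(k)) {
        rec_idx <- rec_idx + 1L
        tr <- truth[truth$eye == eyes[e] & truth$location == li, ]
        tr <- tr[match(layers, tr$layer), ]
        th <- stats::setNames(tr$thickness_true_um, layers)
        bscan <- make_bscan(th, cfg, speckle_level = speckle_level,
                            seed = derive_seed(spec$seed, 3L, rec_idx))
        planes <- lapply(seq_along(layers), function(j) {
          make_angular_plane(
            medium_spec(alpha_true = tr$alpha_true[j],
                        amplitude = tr$intensity_true[j],
                        seed = derive_seed(spec$seed, 2L,
                                           (rec_idx - 1L) * 3L + j)),
            cfg
          )
        })
        names(planes) <- layers
        artifact <- NULL
        if (spec$artifact_rate > 0) {
          set.seed(derive_seed(spec$seed, 4L, rec_idx))
          if (stats::runif(1) < spec$artifact_rate) {
            r <- sample(2:4, 1)
            ctr <- c(sample((r + 1):(cfg$n_theta_x - r), 1),
                     sample((r + 1):(cfg$n_theta_y - r), 1))
            gain <- stats::runif(1, 8, 15)
            planes <- lapply(planes, inject_specular, center = ctr,
                             radius = r, gain = gain)
            artifact <- list(center = ctr, radius = r, gain = gain,
                             footprint = attr(planes[[1]],
                                              "specular_footprint"))
            truth$artifact[truth$eye == eyes[e] &
                             truth$location == li] <- TRUE
          }
        }
        rec <- list(eye = eyes[e], group = groups[e], location = li,
                    quadrant = locs$quadrant[li], bscan = bscan,
                    planes = planes, artifact = artifact)
        if (level == "spectra") {
          rec$scans <- encode_record_scans(
            planes, bscan$truth, cfg,
            seed = derive_seed(spec$seed, 5L, rec_idx)
          )
        }
        records[[rec_idx]] <- rec
      }
    }
  }

  structure(
    list(records = records, truth = truth, locations = locs, spec = spec,
         cfg = cfg, level = level, speckle_level = speckle_level),
    class = "alci_cohort"
  )
}

# Encode per-layer angular planes into raw spectral scans: each layer's
# plane amplitudes are laid down as fringes at the depth pixels of the
# layer's mapped a/LCI interval, one scan per theta_y.
encode_record_scans <- function(planes, bounds, cfg, seed = 1L,
                                noise_sd = 0) {
  mapped <- map_to_alci(bounds, cfg$alci_pixel_to_depth,
                        n_depth = cfg$n_wavenumber_samples / 2)
  lapply(seq_len(cfg$n_theta_y), function(j) {
    profile <- list()
    for (i in seq_len(nrow(mapped))) {
      px <- mapped$top_alci_px[i]:(mapped$bottom_alci_px[i] - 1)
      amp <- planes[[mapped$layer[i]]][, j] / length(px)
      for (d in px) {
        profile[[length(profile) + 1]] <-
          list(depth_um = d * cfg$alci_pixel_to_depth, reflectivity = amp)
      }
    }
    make_raw_scan(profile, cfg, seed = derive_seed(seed, 6L, j),
                  noise_sd = noise_sd,
                  theta_y = (j - 1 - cfg$n_theta_y / 2) *
                    cfg$theta_span / cfg$n_theta_y)
  })
}

#' @export
print.alci_cohort <- function(x, ...) {
  cat(sprintf("a/LCI cohort (%s level): %d WT + %d AD eyes x %d locations = %d records\n",
              x$level, x$spec$n_wt_eyes, x$spec$n_ad_eyes,
              x$spec$n_locations,
              (x$spec$n_wt_eyes + x$spec$n_ad_eyes) * x$spec$n_locations))
  invisible(x)
}

#' Ground truth of a cohort as a long table
#'
#' @param cohort an `alci_cohort`.
#' @return the ground-truth data.frame (one row per eye, location, layer).
#' @export
cohort_truth <- function(cohort) {
  stopifnot(inherits(cohort, "alci_cohort"))
  cohort$truth
}
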