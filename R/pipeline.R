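# Orchestration: cohort -> per-record metrics -> group statistics, with
# drop accounting and reproducible configuration.

#' Compute per-record metrics for a cohort
#'
#' Runs the measurement chain on every record: B-scan segmentation and
#' layer thicknesses; per-layer specular-artifact masking; masked intensity
#' statistics; two-point correlation and short-range slope fit. Per-record
#' failures (segmentation failure, mask over-exclusion, too few retained
#' pixels) do not abort the cohort -- the record is dropped and logged with
#' a reason code, mirroring the exclusion of unsegmentable B-scans from
#' analysis.
#'
#' For `"spectra"`-level cohorts the angular planes are first recovered
#' from the raw scans (volume assembly, boundary mapping, per-layer
#' extraction); otherwise the generated planes are measured directly.
#'
#' @param cohort an [generate_cohort()] result (level `"planes"` or
#'   `"spectra"`).
#' @param window short-range fit window, microns.
#' @param use_truth_boundaries use the generator's ground-truth boundaries
#'   instead of automated segmentation (external-boundary import analogue).
#' @return list with `table` (long cohort table: columns `eye`, `group`,
#'   `location`, `quadrant`, `layer`, `metric`, `value`), `drops`
#'   (data.frame `eye`, `location`, `reason`), `n_generated`,
#'   `n_analyzed`, `n_dropped`.
#' @export
cohort_metrics <- function(cohort, window = c(2, 10),
                           use_truth_boundaries = FALSE) {
  stopifnot(inherits(cohort, "alci_cohort"))
  if (cohort$level == "truth") {
    stop("cohort was generated at level='truth'; no measurement data")
  }
  cfg <- cohort$cfg
  layers <- c("NFL", "OPL", "RPE")
  rows <- vector("list", length(cohort$records))
  drops <- list()
  for (i in seq_along(cohort$records)) {
    rec <- cohort$records[[i]]
    res <- tryCatch({
      bounds <- if (use_truth_boundaries) {
        rec$bscan$truth
      } else {
        segment_layers(rec$bscan)
      }
      planes <- rec$planes
      if (!is.null(rec$scans)) {
        vol <- assemble_volume(rec$scans, cfg, window = "none",
                               dc_suppress = FALSE)
        mapped <- map_to_alci(bounds, cfg$alci_pixel_to_depth,
                              n_depth = dim(vol$intensity)[1])
        planes <- lapply(layers, function(l) {
          extract_layer_plane(vol, mapped, l)$intensity
        })
        names(planes) <- layers
      }
      out <- list()
      for (l in layers) {
        plane <- angular_plane(unclass(planes[[l]]), layer = l,
                               eye = rec$eye, location = rec$location)
        mask <- detect_specular(plane)
        if (isTRUE(attr(mask, "flagged"))) {
          stop_retscat("more than 50% of pixels excluded",
                       "retscat_mask_overexclusion")
        }
        masked <- apply_mask(plane, mask)
        hs <- histogram_stats(masked)
        if (hs$stats$flagged) {
          stop_retscat("fewer than 100 retained pixels",
                       "retscat_insufficient_pixels")
        }
        sf <- plane_slope(masked, cfg, window = window)
        out[[l]] <- data.frame(
          eye = rec$eye, group = rec$group, location = rec$location,
          quadrant = rec$quadrant, layer = l,
          metric = c("alpha", "fd", "thickness_um", "intensity_mean",
                     "intensity_variance", "intensity_skewness",
                     "intensity_kurtosis"),
          value = c(sf$alpha, sf$fd, layer_thickness(bounds, l),
                    hs$stats$mean, hs$stats$variance, hs$stats$skewness,
                    hs$stats$kurtosis),
          stringsAsFactors = FALSE
        )
      }
      do.call(rbind, out)
    },
    retscat_error = function(e) {
      reason <- setdiff(class(e), c("retscat_error", "error", "condition"))[1]
      data.frame(eye = rec$eye, location = rec$location,
                 reason = sub("^retscat_", "", reason),
                 stringsAsFactors = FALSE)
    })
    if (identical(names(res)[3], "reason")) {
      drops[[length(drops) + 1]] <- res
    } else {
      rows[[i]] <- res
    }
  }
  table <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  drops <- if (length(drops)) do.call(rbind, drops) else
    data.frame(eye = character(), location = integer(),
               reason = character(), stringsAsFactors = FALSE)
  rownames(table) <- NULL
  n_gen <- length(cohort$records)
  n_drop <- nrow(drops)
  list(table = table, drops = drops, n_generated = n_gen,
       n_analyzed = n_gen - n_drop, n_dropped = n_drop)
}

#' Run configuration for the full pipeline
#'
#' @param cfg an [optical_config()].
#' @param spec a [cohort_spec()].
#' @param window short-range fit window, microns.
#' @param alpha significance level for group tests.
#' @param quadrants quadrant subsets reported alongside the unstratified
#'   analysis.
#' @param metrics metrics to test at group level.
#' @param seed master seed (overrides `spec$seed`).
#' @return object of class `run_config`.
#' @export
run_config <- function(cfg = optical_config(), spec = cohort_spec(),
                       window = c(2, 10), alpha = 0.05,
                       quadrants = c("superior", "inferior"),
                       metrics = c("alpha", "thickness_um", "intensity_mean",
                                   "intensity_variance"),
                       seed = NULL) {
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  structure(list(cfg = cfg, spec = spec, window = window, alpha = alpha,
                 quadrants = quadrants, metrics = metrics),
            class = "run_config")
}

#' Group-level statistics over a cohort metrics table
#'
#' One [rm_anova_between()] row per metric and layer, plus
#' [quadrant_analysis()] rows for each requested quadrant.
#'
#' @param table long cohort table (see [cohort_metrics()]).
#' @param metrics metrics to test.
#' @param alpha significance level.
#' @param quadrants quadrants for stratified rows (character vector; use
#'   `character()` to skip).
#' @return data.frame with one row per (metric, layer, scope).
#' @export
run_stats <- function(table, metrics = c("alpha", "thickness_um",
                                         "intensity_mean",
                                         "intensity_variance"),
                      alpha = 0.05, quadrants = c("superior", "inferior")) {
  check_cohort_table(table)
  layers <- unique(table$layer)
  rows <- list()
  for (m in metrics) {
    for (l in layers) {
      fits <- c(list(all = rm_anova_between(table, m, l)),
                stats::setNames(
                  lapply(quadrants, function(q)
                    quadrant_analysis(table, m, l, q)),
                  quadrants))
      for (scope in names(fits)) {
        f <- fits[[scope]]
        rows[[length(rows) + 1]] <- data.frame(
          metric = m, layer = l, scope = scope,
          estimate = f$estimate, f_statistic = f$f_statistic,
          p_value = f$p_value, rho_hat = f$rho_hat,
          n_wt = f$n_wt, n_ad = f$n_ad, balanced = f$balanced,
          significant = !is.na(f$p_value) && f$p_value < alpha,
          direction = ifelse(f$estimate > 0, "AD>WT",
                             ifelse(f$estimate < 0, "AD<WT", "none")),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full simulate-process-measure-test pipeline
#'
#' Generates the cohort from the configuration, measures every record,
#' runs the group statistics, and (optionally) writes `metrics.csv`,
#' `stats.csv`, `drops.csv`, `truth.csv` and a YAML manifest to `out_dir`.
#' Deterministic given the master seed.
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory.
#' @param level cohort detail level (see [generate_cohort()]).
#' @return object of class `pipeline_run`: `metrics`, `stats`, `drops`,
#'   `truth`, `manifest`, `config`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         level = "planes") {
  stopifnot(inherits(config, "run_config"))
  cohort <- generate_cohort(config$spec, config$cfg, level = level)
  met <- cohort_metrics(cohort, window = config$window)
  stats_tab <- run_stats(met$table, metrics = config$metrics,
                         alpha = config$alpha,
                         quadrants = config$quadrants)
  manifest <- list(
    package_version = as.character(utils::packageVersion("retscat")),
    master_seed = config$spec$seed,
    level = level,
    n_generated = met$n_generated,
    n_analyzed = met$n_analyzed,
    n_dropped = met$n_dropped,
    drop_reasons = as.list(table(met$drops$reason)),
    window_um = config$window,
    alpha = config$alpha
  )
  run <- structure(
    list(metrics = met$table, stats = stats_tab, drops = met$drops,
         truth = cohort$truth, manifest = manifest, config = config),
    class = "pipeline_run"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(run$metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(run$stats, file.path(out_dir, "stats.csv"),
                     row.names = FALSE)
    utils::write.csv(run$drops, file.path(out_dir, "drops.csv"),
                     row.names = FALSE)
    utils::write.csv(run$truth, file.path(out_dir, "truth.csv"),
                     row.names = FALSE)
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
    write_run_config(config, file.path(out_dir, "config.yaml"))
  }
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("Pipeline run (seed %d): %d generated, %d analyzed, %d dropped\n",
              m$master_seed, m$n_generated, m$n_analyzed, m$n_dropped))
  sig <- x$stats[x$stats$significant & x$stats$scope == "all", ]
  if (nrow(sig)) {
    cat("Significant group effects (unstratified):\n")
    for (i in seq_len(nrow(sig))) {
      cat(sprintf("  %s / %s: %s, p = %.4g\n", sig$metric[i], sig$layer[i],
                  sig$direction[i], sig$p_value[i]))
    }
  }
  invisible(x)
}

#' Table of dropped records with reasons
#'
#' Every generated record is either analyzed or listed here; the
#' conservation `generated = analyzed + dropped` holds for every run.
#'
#' @param run a [run_pipeline()] result.
#' @return data.frame `eye`, `location`, `reason`.
#' @export
drop_log <- function(run) {
  stopifnot(inherits(run, "pipeline_run"))
  run$drops
}

#' Serialize / restore a run configuration (YAML)
#'
#' @param config a [run_config()].
#' @param path file path.
#' @return `read_run_config` returns a [run_config()] equivalent to the one
#'   written.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- list(cfg = unclass(config$cfg),
            spec = unclass(config$spec),
            window = config$window, alpha = config$alpha,
            quadrants = as.list(config$quadrants),
            metrics = as.list(config$metrics))
  x$spec$superior_intensity_delta <- as.list(x$spec$superior_intensity_delta)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  cfg <- do.call(optical_config, x$cfg)
  sp <- x$spec
  spec <- cohort_spec(
    n_wt_eyes = sp$n_wt_eyes, n_ad_eyes = sp$n_ad_eyes,
    n_locations = sp$n_locations, layer_params = sp$layer_params,
    superior_intensity_delta = unlist(sp$superior_intensity_delta),
    intensity_common_sd = sp$intensity_common_sd,
    within_eye_rho = sp$within_eye_rho,
    artifact_rate = sp$artifact_rate, seed = sp$seed
  )
  run_config(cfg = cfg, spec = spec, window = unlist(x$window),
             alpha = x$alpha, quadrants = unlist(x$quadrants),
             metrics = unlist(x$metrics))
}
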