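# Synthetic-data generator: planes, raw scans, B-scans, cohorts.

test_that("angular planes are deterministic, nonnegative, and honor flat targets", {
  cfg <- optical_config()
  spec <- medium_spec(alpha_true = 0.7, seed = 11L)
  p1 <- make_angular_plane(spec, cfg)
  p2 <- make_angular_plane(spec, cfg)
  expect_identical(p1, p2)
  expect_true(all(is.finite(p1)) && all(p1 >= 0))

  flat <- make_angular_plane(medium_spec(alpha_true = 0, seed = 2L), cfg)
  expect_lt(abs(plane_slope(flat, cfg)$alpha), 0.05)
})

test_that("closed-loop slope recovery hits the target over seeds", {
  cfg <- optical_config()
  est <- vapply(1:10, function(s) {
    plane_slope(make_angular_plane(medium_spec(1.0, seed = s), cfg), cfg)$alpha
  }, numeric(1))
  expect_true(all(est >= 0.9 & est <= 1.1))
})

test_that("unrealizable power-law windows raise a configuration error", {
  cfg <- optical_config(n_theta_x = 16, n_theta_y = 16)  # r_max = 8 um
  expect_error(
    make_angular_plane(medium_spec(1, inner_scale = 2, outer_scale = 20), cfg),
    "r_max", class = "retscat_config_error"
  )
})

test_that("raw scans encode depths as recoverable fringes", {
  cfg <- optical_config()  # 128 spectral samples, 5 um/px, Nyquist px 64
  sc <- make_raw_scan(data.frame(depth_um = 40 * 5, reflectivity = 1), cfg)
  prof <- spectra_to_depth(sc, window = "none")
  expect_equal(which.max(rowMeans(prof)) - 1, 40)

  # empty profile: flat spectrum, all energy at DC
  sc0 <- make_raw_scan(list(), cfg)
  prof0 <- spectra_to_depth(sc0, window = "none", dc_suppress = FALSE)
  expect_equal(which.max(rowMeans(prof0)) - 1, 0)
  expect_true(all(prof0[-1, ] < 1e-9))

  # two distinct reflectors give two local maxima at their pixels
  sc2 <- make_raw_scan(data.frame(depth_um = c(15, 45) * 5,
                                  reflectivity = c(1, 0.6)), cfg)
  prof2 <- rowMeans(spectra_to_depth(sc2, window = "none"))
  expect_equal(sort(order(prof2, decreasing = TRUE)[1:2]) - 1, c(15, 45))

  expect_error(
    make_raw_scan(data.frame(depth_um = 70 * 5, reflectivity = 1), cfg),
    "Nyquist", class = "retscat_depth_error"
  )
})

test_that("B-scan templates honor pixel arithmetic and ground truth", {
  cfg <- optical_config(oct_axial_pixel = 2)
  b <- make_bscan(c(NFL = 18, OPL = 16, RPE = 14), cfg, speckle_level = 0)
  i <- match("NFL", b$truth$layer)
  expect_equal(b$truth$bottom_px[i] - b$truth$top_px[i], 9) # 18 um / 2 um per px
  expect_equal(layer_thickness(b$truth, "NFL"), 18)

  # noiseless scans segment exactly to ground truth
  seg <- segment_layers(b)
  expect_equal(seg$top_px, b$truth$top_px)
  expect_equal(seg$bottom_px, b$truth$bottom_px)

  # thickness 16 vs 18 templates differ only in rows at the NFL boundary
  b16 <- make_bscan(c(NFL = 16, OPL = 16, RPE = 14), cfg, speckle_level = 0)
  expect_equal(b$truth$bottom_px[1] - b16$truth$bottom_px[1], 1)
})

test_that("specular injection modifies exactly the disc and is maskable", {
  cfg <- optical_config()
  p <- make_angular_plane(medium_spec(0.8, seed = 5L), cfg)
  expect_equal(unclass(inject_specular(p, c(30, 30), 3, gain = 1)),
               unclass(p), ignore_attr = TRUE)

  inj <- inject_specular(p, c(30, 30), 3, gain = 10)
  foot <- attr(inj, "specular_footprint")
  expect_true(all(inj[foot] > 5 * median(inj)))
  expect_true(all(inj[!foot] <= 5 * median(inj)))
  expect_identical(inj[!foot], p[!foot])

  # excluding the footprint restores the clean-plane moments exactly
  clean <- histogram_stats(apply_mask(p, foot))$stats
  masked <- histogram_stats(apply_mask(inj, foot))$stats
  expect_equal(masked$mean, clean$mean, tolerance = 1e-12)
  expect_equal(masked$variance, clean$variance, tolerance = 1e-12)
})

test_that("cohorts have the designed record counts and reproduce exactly", {
  spec <- tiny_cohort_spec(seed = 9L)
  cfg <- small_cfg()
  c1 <- generate_cohort(spec, cfg)
  c2 <- generate_cohort(spec, cfg)
  expect_identical(c1, c2)
  expect_equal(length(c1$records), 6 * 8)
  expect_equal(nrow(c1$truth), 6 * 8 * 3)

  full <- generate_cohort(cohort_spec(seed = 1L), level = "truth")
  expect_equal(nrow(full$truth), (10 + 13) * 8 * 3)
  expect_equal(sum(full$truth$group == "WT"), 10 * 8 * 3)
})

test_that("cohort ground-truth marginals converge to the specified means", {
  spec <- cohort_spec(n_wt_eyes = 500, n_ad_eyes = 500,
                      superior_intensity_delta = c(NFL = 0, OPL = 0, RPE = 0),
                      seed = 33L)
  tr <- cohort_truth(generate_cohort(spec, level = "truth"))
  for (l in c("NFL", "OPL", "RPE")) {
    for (g in c("WT", "AD")) {
      p <- spec$layer_params[[l]][[g]]
      sub <- tr[tr$layer == l & tr$group == g, ]
      # SE of the mean ~ sd / sqrt(n_eyes); allow 4 SEs
      se_a <- p$alpha_sd / sqrt(500)
      expect_lt(abs(mean(sub$alpha_true) - p$alpha_mean), 4 * se_a)
      se_t <- p$thickness_sd / sqrt(500)
      expect_lt(abs(mean(sub$thickness_true_um) - p$thickness_mean), 4 * se_t)
    }
  }
  # zero-effect groups: alpha difference within 2 pooled SEs
  spec0 <- cohort_spec(n_wt_eyes = 200, n_ad_eyes = 200,
                       layer_params = default_layer_params(
                         list(alpha = 0, nfl_thickness_um = 0)),
                       superior_intensity_delta = c(NFL = 0, OPL = 0, RPE = 0),
                       seed = 14L)
  tr0 <- cohort_truth(generate_cohort(spec0, level = "truth"))
  nfl <- tr0[tr0$layer == "NFL", ]
  m <- tapply(nfl$alpha_true, nfl$group, mean)
  eye_means <- tapply(nfl$alpha_true, nfl$eye, mean)
  grp <- substr(names(eye_means), 1, 2)
  pooled_se <- sqrt(var(eye_means[grp == "WT"]) / 200 +
                    var(eye_means[grp == "AD"]) / 200)
  expect_lt(abs(m["AD"] - m["WT"]), 2 * pooled_se)
})

test_that("within-eye correlation of generated deviations matches rho", {
  spec <- cohort_spec(n_wt_eyes = 250, n_ad_eyes = 250, within_eye_rho = 0.5,
                      superior_intensity_delta = c(NFL = 0, OPL = 0, RPE = 0),
                      seed = 8L)
  tr <- cohort_truth(generate_cohort(spec, level = "truth"))
  nfl <- tr[tr$layer == "NFL", ]
  # residuals after removing group means, arranged eyes x locations
  nfl$res <- nfl$alpha_true - ave(nfl$alpha_true, nfl$group)
  Y <- matrix(nfl$res[order(nfl$eye, nfl$location)], ncol = 8, byrow = TRUE)
  cm <- cor(Y)
  rho_hat <- mean(cm[upper.tri(cm)])
  expect_gte(rho_hat, 0.45)
  expect_lte(rho_hat, 0.55)
})
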