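# Repeated-measures group inference and assumption checks.

make_table <- function(Y, groups, metric = "value", layer = "NFL") {
  n <- nrow(Y); k <- ncol(Y)
  data.frame(
    eye = rep(sprintf("E%03d", seq_len(n)), each = k),
    group = rep(groups, each = k),
    location = rep(seq_len(k), n),
    quadrant = rep(location_layout(k)$quadrant, n),
    layer = layer, metric = metric, value = as.vector(t(Y)),
    stringsAsFactors = FALSE
  )
}

test_that("balanced F equals the squared pooled t on eye means", {
  set.seed(71)
  groups <- rep(c("WT", "AD"), c(6, 7))
  Y <- matrix(rnorm(13 * 8), 13, 8)
  fit <- rm_anova_between(make_table(Y, groups), "value", "NFL")
  m <- rowMeans(Y)
  tt <- t.test(m[groups == "AD"], m[groups == "WT"], var.equal = TRUE)
  expect_equal(fit$f_statistic, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(fit$p_value, tt$p.value, tolerance = 1e-9)
  expect_true(fit$balanced)
  expect_equal(fit$df, c(1, 11))
})

test_that("rho_hat agrees with a generalized least squares fit", {
  skip_if_not_installed("nlme")
  set.seed(23)
  groups <- rep(c("WT", "AD"), c(10, 13))
  Y <- t(replicate(23, {
    z <- rnorm(8); zb <- mean(z)
    sqrt(1 + 7 * 0.3) * zb + sqrt(1 - 0.3) * (z - zb)
  }))
  tab <- make_table(Y, groups)
  fit <- rm_anova_between(tab, "value", "NFL")
  g <- nlme::gls(value ~ group, data = tab,
                 correlation = nlme::corCompSymm(form = ~ 1 | eye))
  rho_gls <- coef(g$modelStruct$corStruct, unconstrained = FALSE)
  expect_lt(abs(fit$rho_hat - unname(rho_gls)), 0.05)
})

test_that("degenerate and malformed inputs are reported", {
  groups <- rep(c("WT", "AD"), c(3, 3))
  fit <- rm_anova_between(make_table(matrix(5, 6, 4), groups), "value", "NFL")
  expect_true(fit$degenerate)
  expect_true(is.na(fit$p_value))
  expect_error(
    rm_anova_between(make_table(matrix(rnorm(12), 3, 4),
                                c("WT", "AD", "AD")), "value", "NFL"),
    "at least 2 eyes"
  )
})

test_that("permuting locations within eyes leaves the test invariant", {
  set.seed(41)
  groups <- rep(c("WT", "AD"), c(5, 6))
  Y <- matrix(rnorm(11 * 8), 11, 8)
  f0 <- rm_anova_between(make_table(Y, groups), "value", "NFL")
  Yp <- t(apply(Y, 1, sample))
  fp <- rm_anova_between(make_table(Yp, groups), "value", "NFL")
  expect_equal(fp$f_statistic, f0$f_statistic, tolerance = 1e-12)
  expect_equal(fp$p_value, f0$p_value, tolerance = 1e-12)
  expect_equal(fp$rho_hat, f0$rho_hat, tolerance = 1e-12)
})

test_that("unbalanced designs fall back to Welch on eye means", {
  set.seed(52)
  groups <- rep(c("WT", "AD"), c(5, 6))
  tab <- make_table(matrix(rnorm(88), 11, 8), groups)
  tab <- tab[-3, ]  # remove one location from one eye
  fit <- rm_anova_between(tab, "value", "NFL")
  expect_false(fit$balanced)
  expect_true(is.na(fit$rho_hat))
  expect_true(fit$p_value > 0 && fit$p_value < 1)
})

test_that("normality check passes Gaussian and rejects exponential samples", {
  set.seed(61)
  groups <- rep(c("WT", "AD"), each = 25)
  pass_norm <- mean(replicate(400, {
    check_normality(make_table(matrix(rnorm(100), 50, 2), groups),
                    "value", "NFL")$pass
  }))
  expect_gte(pass_norm, 0.99)
  fail_exp <- mean(replicate(400, {
    check_normality(make_table(matrix(rexp(100), 50, 2), groups),
                    "value", "NFL")$pass == FALSE
  }))
  expect_gte(fail_exp, 0.90)
  expect_error(
    check_normality(make_table(matrix(1:2, 1, 2), "WT"), "value", "NFL"),
    "at least 3"
  )
})

test_that("variance-homogeneity check has the expected operating range", {
  set.seed(62)
  groups <- rep(c("WT", "AD"), each = 20)
  pass_equal <- mean(replicate(400, {
    check_variance_homogeneity(make_table(matrix(rnorm(40), 40, 1), groups),
                               "value", "NFL")$pass
  }))
  expect_gte(pass_equal, 0.93)
  # power against a four-fold variance ratio (Brown-Forsythe, n = 20/group)
  fail_4x <- mean(replicate(400, {
    Y <- matrix(c(rnorm(20, 0, 1), rnorm(20, 0, 2)), 40, 1)
    !check_variance_homogeneity(make_table(Y, groups), "value", "NFL")$pass
  }))
  expect_gte(fail_4x, 0.60)
  # near-certain detection at a sixteen-fold ratio
  fail_16x <- mean(replicate(200, {
    Y <- matrix(c(rnorm(20, 0, 1), rnorm(20, 0, 4)), 40, 1)
    !check_variance_homogeneity(make_table(Y, groups), "value", "NFL")$pass
  }))
  expect_gte(fail_16x, 0.95)
  # identical constant groups are degenerate
  dg <- check_variance_homogeneity(make_table(matrix(3, 8, 2),
                                              rep(c("WT", "AD"), each = 4)),
                                   "value", "NFL")
  expect_true(dg$degenerate)
})

test_that("quadrant stratification restricts and degenerates correctly", {
  set.seed(81)
  groups <- rep(c("WT", "AD"), c(6, 6))
  Y <- matrix(rnorm(96), 12, 8)
  tab <- make_table(Y, groups)
  all_q <- quadrant_analysis(tab, "value", "NFL",
                             c("superior", "inferior", "nasal", "temporal"))
  full <- rm_anova_between(tab, "value", "NFL")
  expect_equal(all_q$f_statistic, full$f_statistic, tolerance = 1e-12)

  sup <- quadrant_analysis(tab, "value", "NFL", "superior")
  expect_equal(sup$k, 2)

  one_loc <- quadrant_analysis(tab[tab$location == 1, ], "value", "NFL",
                               "nasal")
  expect_equal(one_loc$k, 1)
  expect_true(is.na(one_loc$rho_hat))
  expect_true(is.finite(one_loc$p_value))

  expect_error(quadrant_analysis(tab, "value", "NFL", "macular"),
               "no records")
})

test_that("a superior-confined effect is localized by quadrant analysis", {
  set.seed(91)
  groups <- rep(c("WT", "AD"), c(10, 13))
  hits <- replicate(20, {
    Y <- t(replicate(23, {
      z <- rnorm(8); zb <- mean(z)
      0.1 * (sqrt(1 - 7 * 0.14) * zb + sqrt(1.14) * (z - zb))
    }))
    sup <- location_layout(8)$quadrant == "superior"
    Y[groups == "AD", sup] <- Y[groups == "AD", sup] + 0.5
    tab <- make_table(Y, groups)
    c(sup = quadrant_analysis(tab, "value", "NFL", "superior")$p_value < 0.05,
      inf = quadrant_analysis(tab, "value", "NFL", "inferior")$p_value < 0.05)
  })
  expect_gte(mean(hits["sup", ]), 0.90)
  expect_lte(mean(hits["inf", ]), 0.30)
})
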