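# Group-level inference: balanced mixed repeated-measures ANOVA under
# compound symmetry, assumption checks, quadrant-stratified analysis.

cohort_columns <- c("eye", "group", "location", "quadrant", "layer",
                    "metric", "value")

check_cohort_table <- function(table) {
  stopifnot(is.data.frame(table), all(cohort_columns %in% names(table)))
  invisible(table)
}

select_cell <- function(table, metric, layer) {
  check_cohort_table(table)
  d <- table[table$metric == metric & table$layer == layer, ]
  if (nrow(d) == 0) stop(sprintf("no records for metric '%s', layer '%s'",
                                 metric, layer))
  if (anyDuplicated(d[c("eye", "location")])) {
    stop("duplicate (eye, location) records for this metric/layer")
  }
  d
}

#' Between-group mixed repeated-measures ANOVA
#'
#' Compares WT and AD group means of one metric in one layer while
#' accounting for the correlation among the repeated locations within each
#' eye. For a balanced design (every eye measured at the same complete set
#' of locations) the test is computed exactly from sums of squares:
#' `F = MS_group / MS_eye(group)` with `(1, n_eyes - 2)` degrees of
#' freedom, which is exact under a compound-symmetric within-eye
#' covariance. The compound-symmetry correlation is estimated from the
#' variance components as
#' `rho_hat = (MS_eye - MS_within) / (MS_eye + (k - 1) * MS_within)`;
#' negative estimates are reported as-is (the admissible range extends to
#' `-1/(k-1)`). Unbalanced designs fall back to a Welch two-sample test on
#' eye-level means (`balanced = FALSE`).
#'
#' @param table long-format cohort table with columns `eye`, `group`
#'   (WT/AD), `location`, `quadrant`, `layer`, `metric`, `value`.
#' @param metric,layer the cell to analyze.
#' @return object of class `rm_anova_result`: `metric`, `layer`,
#'   `estimate` (AD minus WT), `f_statistic`, `p_value`, `rho_hat`,
#'   `df`, `n_wt`, `n_ad`, `k`, `balanced`, `degenerate`.
#' @export
rm_anova_between <- function(table, metric, layer) {
  d <- select_cell(table, metric, layer)
  eyes <- unique(d$eye)
  grp <- vapply(eyes, function(e) as.character(d$group[d$eye == e][1]),
                character(1))
  if (!all(vapply(eyes, function(e) length(unique(d$group[d$eye == e])) == 1,
                  logical(1)))) {
    stop("group must be constant within eye")
  }
  n_wt <- sum(grp == "WT")
  n_ad <- sum(grp == "AD")
  if (n_wt < 2 || n_ad < 2) stop("each group needs at least 2 eyes")
  locs <- sort(unique(d$location))
  k <- length(locs)
  tab <- table(d$eye)
  balanced <- length(unique(tab)) == 1 && all(tab == k) &&
    all(vapply(eyes, function(e) {
      setequal(d$location[d$eye == e], locs)
    }, logical(1)))
  eye_means <- vapply(eyes, function(e) mean(d$value[d$eye == e]), numeric(1))
  est <- mean(eye_means[grp == "AD"]) - mean(eye_means[grp == "WT"])
  n <- length(eyes)
  if (balanced) {
    gm_of_eye <- ave(eye_means, grp)
    ss_group <- k * sum((gm_of_eye - mean(eye_means))^2)
    ss_eye <- k * sum((eye_means - gm_of_eye)^2)
    within_dev <- d$value - eye_means[match(d$eye, eyes)]
    ss_within <- sum(within_dev^2)
    ms_group <- ss_group / 1
    ms_eye <- ss_eye / (n - 2)
    ms_within <- if (k > 1) ss_within / (n * (k - 1)) else NA_real_
    degenerate <- ms_eye <= 0
    f <- if (degenerate) NA_real_ else ms_group / ms_eye
    p <- if (degenerate) NA_real_ else
      stats::pf(f, 1, n - 2, lower.tail = FALSE)
    rho <- if (k > 1 && is.finite(ms_within) &&
               (ms_eye + (k - 1) * ms_within) > 0) {
      (ms_eye - ms_within) / (ms_eye + (k - 1) * ms_within)
    } else {
      NA_real_
    }
    df <- c(1, n - 2)
  } else {
    wt <- eye_means[grp == "WT"]
    ad <- eye_means[grp == "AD"]
    degenerate <- stats::sd(wt) == 0 && stats::sd(ad) == 0
    if (degenerate) {
      f <- p <- NA_real_
      df <- c(1, NA)
    } else {
      tt <- stats::t.test(ad, wt)
      f <- unname(tt$statistic)^2
      p <- tt$p.value
      df <- c(1, unname(tt$parameter))
    }
    rho <- NA_real_
  }
  structure(
    list(metric = metric, layer = layer, estimate = est,
         f_statistic = f, p_value = p, rho_hat = rho, df = df,
         n_wt = n_wt, n_ad = n_ad, k = k, balanced = balanced,
         degenerate = degenerate),
    class = "rm_anova_result"
  )
}

#' @export
print.rm_anova_result <- function(x, ...) {
  cat(sprintf("RM-ANOVA %s / %s: AD-WT = %.4g, F(%g, %g) = %.3f, p = %.4g%s\n",
              x$metric, x$layer, x$estimate, x$df[1], x$df[2],
              ifelse(is.na(x$f_statistic), NaN, x$f_statistic), x$p_value,
              if (x$degenerate) " [degenerate]"
              else if (!x$balanced) " [unbalanced: Welch on eye means]"
              else ""))
  if (!is.na(x$rho_hat)) {
    cat(sprintf("  compound-symmetry rho_hat = %.4f (k = %d locations)\n",
                x$rho_hat, x$k))
  }
  invisible(x)
}

#' Shapiro-Wilk normality check
#'
#' Tests normality of the residuals of the group-means model (values minus
#' their group mean, which preserves the shape of the error distribution)
#' at the Bonferroni-corrected level `alpha = 0.003`.
#'
#' @inheritParams rm_anova_between
#' @param alpha significance level for the check.
#' @return list `statistic`, `p_value`, `pass`.
#' @export
check_normality <- function(table, metric, layer, alpha = 0.003) {
  d <- select_cell(table, metric, layer)
  res <- d$value - ave(d$value, d$group)
  if (length(res) < 3) stop("need at least 3 residuals for Shapiro-Wilk")
  sw <- stats::shapiro.test(res)
  list(statistic = unname(sw$statistic), p_value = sw$p.value,
       pass = sw$p.value >= alpha)
}

#' Levene (Brown-Forsythe) variance-homogeneity check
#'
#' Tests equality of error variances between the WT and AD groups on
#' eye-level means (the independent units of the design), using absolute
#' deviations from group medians (the Brown-Forsythe variant of Levene's
#' test), at `alpha = 0.05`.
#'
#' @inheritParams rm_anova_between
#' @param alpha significance level for the check.
#' @param center `"median"` (Brown-Forsythe) or `"mean"` (classic Levene).
#' @return list `statistic`, `p_value`, `pass`, `degenerate`.
#' @export
check_variance_homogeneity <- function(table, metric, layer, alpha = 0.05,
                                       center = c("median", "mean")) {
  center <- match.arg(center)
  d <- select_cell(table, metric, layer)
  eyes <- unique(d$eye)
  m <- vapply(eyes, function(e) mean(d$value[d$eye == e]), numeric(1))
  g <- factor(vapply(eyes, function(e) as.character(d$group[d$eye == e][1]),
                     character(1)))
  if (any(table(g) < 2)) stop("both groups need at least 2 eyes")
  if (all(tapply(m, g, stats::sd) == 0)) {
    return(list(statistic = NA_real_, p_value = NA_real_, pass = NA,
                degenerate = TRUE))
  }
  lt <- car::leveneTest(m, g, center = if (center == "median") stats::median
                                       else mean)
  list(statistic = lt[1, "F value"], p_value = lt[1, "Pr(>F)"],
       pass = lt[1, "Pr(>F)"] >= alpha, degenerate = FALSE)
}

#' Quadrant-stratified group comparison
#'
#' Restricts the cohort table to the locations belonging to the named
#' quadrants and reruns [rm_anova_between()]. With a single location per
#' eye the analysis collapses to a comparison of eye values (`k = 1`,
#' `rho_hat` undefined).
#'
#' @inheritParams rm_anova_between
#' @param quadrants character vector of quadrant names.
#' @return an `rm_anova_result` with the `quadrants` field set.
#' @export
quadrant_analysis <- function(table, metric, layer, quadrants) {
  check_cohort_table(table)
  stopifnot(length(quadrants) >= 1)
  sub <- table[table$quadrant %in% quadrants, ]
  if (nrow(sub) == 0) stop("no records in the requested quadrants")
  out <- rm_anova_between(sub, metric, layer)
  out$quadrants <- quadrants
  out
}
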