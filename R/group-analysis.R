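#' Two-sample Welch's t-test
#'
#' Two-tailed two-sample t-test not assuming equal variances, with
#' Welch-Satterthwaite (fractional) degrees of freedom, as used for all
#' between-group comparisons in the cohort workflow. Wraps
#' [stats::t.test()] and adds the degenerate-case convention: if both
#' groups have zero variance and equal means the test is reported as
#' t = 0, p = 1; zero variance with unequal means is an error.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return a list with `statistic` (t, for the x - y contrast), `dof`,
#'   `p_value`, `group_means` and `group_sds`.
#' @export
welch_t_test <- function(x, y) {
  check_group_vector(x, "x"); check_group_vector(y, "y")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y))
      return(list(statistic = 0, dof = length(x) + length(y) - 2,
                  p_value = 1, group_means = c(mean(x), mean(y)),
                  group_sds = c(0, 0)))
    stop("both groups have zero variance with unequal means: t undefined")
  }
  fit <- stats::t.test(x, y, var.equal = FALSE, alternative = "two.sided")
  list(statistic = unname(fit$statistic), dof = unname(fit$parameter),
       p_value = fit$p.value, group_means = c(mean(x), mean(y)),
       group_sds = c(stats::sd(x), stats::sd(y)))
}

#' One-sample t-test
#'
#' Two-tailed one-sample t-test of the mean against `mu0`, used to test
#' for non-zero bias per ROI. Degenerate convention: zero variance with
#' mean equal to `mu0` gives t = 0, p = 1; zero variance otherwise is
#' an error.
#'
#' @param x numeric vector of length >= 2.
#' @param mu0 null-hypothesis mean (0 for bias tests).
#' @return a list with `statistic`, `dof` (n - 1), `p_value`, `mean`,
#'   `sd`, `n`.
#' @export
one_sample_t_test <- function(x, mu0 = 0) {
  check_group_vector(x, "x")
  if (stats::sd(x) == 0) {
    if (mean(x) == mu0)
      return(list(statistic = 0, dof = length(x) - 1, p_value = 1,
                  mean = mean(x), sd = 0, n = length(x)))
    stop("zero variance with mean different from mu0: t undefined")
  }
  fit <- stats::t.test(x, mu = mu0, alternative = "two.sided")
  list(statistic = unname(fit$statistic), dof = unname(fit$parameter),
       p_value = fit$p.value, mean = mean(x), sd = stats::sd(x),
       n = length(x))
}

check_group_vector <- function(v, name) {
  if (!is.numeric(v) || length(v) < 2L)
    stop(sprintf("'%s' must be a numeric vector of length >= 2", name))
  if (any(!is.finite(v)))
    stop(sprintf("'%s' contains non-finite values", name))
  invisible(TRUE)
}

#' Bonferroni family-wise error correction
#'
#' Adjusts a family of p-values by multiplying each by the family size
#' (capped at 1) and flags significance at `alpha` on the adjusted
#' values, controlling the family-wise error rate at `alpha`. In the
#' cohort workflow the family is the set of ROIs within one
#' metric-by-test combination.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param alpha significance level on the adjusted p-values.
#' @return a list with `p_adjusted`, `significant` (logical), `k`
#'   (family size) and `alpha`.
#' @export
bonferroni <- function(p, alpha = 0.05) {
  if (length(p) == 0L)
    return(list(p_adjusted = numeric(), significant = logical(),
                k = 0L, alpha = alpha))
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p, method = "bonferroni")
  list(p_adjusted = adj, significant = adj < alpha, k = length(p),
       alpha = alpha)
}

#' Cohen's d_s standardised mean difference
#'
#' Standardised mean difference between two independent samples using
#' the pooled, Bessel-corrected standard deviation:
#' `(mean(x) - mean(y)) / s_pooled` with
#' `s_pooled = sqrt(((n_x - 1) s_x^2 + (n_y - 1) s_y^2) / (n_x + n_y - 2))`.
#' No small-sample (Hedges) correction is applied.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return Cohen's d_s for the x - y contrast.
#' @export
cohens_ds <- function(x, y) {
  check_group_vector(x, "x"); check_group_vector(y, "y")
  nx <- length(x); ny <- length(y)
  s_pooled <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
                     (nx + ny - 2))
  if (s_pooled == 0) stop("pooled standard deviation is zero: d undefined")
  (mean(x) - mean(y)) / s_pooled
}

## ---- cohort-level analyses ------------------------------------------------

validate_cohort <- function(cohort, contrast = NULL) {
  required <- c("subject_id", "group", "roi", "metric", "mean_tf",
                "conventional_mean", "tissue_weighted_mean", "bias")
  missing <- setdiff(required, names(cohort))
  if (length(missing))
    stop(sprintf("cohort table lacks column(s): %s",
                 paste(missing, collapse = ", ")))
  key <- paste(cohort$subject_id, cohort$roi, cohort$metric)
  if (anyDuplicated(key))
    stop("duplicate (subject, roi, metric) rows in cohort table")
  groups <- unique(cohort$group)
  if (is.null(contrast)) contrast <- groups
  if (length(contrast) != 2L || !all(contrast %in% groups))
    stop(sprintf("need exactly two groups; table has: %s",
                 paste(groups, collapse = ", ")))
  contrast
}

group_column <- function(cohort, roi, metric, group, column) {
  v <- cohort[cohort$roi == roi & cohort$metric == metric &
                cohort$group == group, column]
  v[is.finite(v)]
}

#' Between-group comparison of mean tissue fraction per ROI
#'
#' For each (ROI, metric) cell: the between-subject mean and standard
#' deviation of the per-subject mean TF in each group, a two-tailed
#' Welch's t-test for a group difference, and Bonferroni correction
#' across ROIs (separately per metric). A lower mean TF in one group
#' indicates greater CSF partial volume there, e.g. through atrophy.
#' Mean TF does not depend on the metric, so with several metrics the
#' per-metric result blocks are identical; they are kept separate so
#' the output aligns with the other per-ROI analyses.
#'
#' @param cohort long-format cohort table (rows as written by
#'   [summarise_subject()], one per subject x ROI x metric).
#' @param contrast character vector of the two group labels, ordered as
#'   reference minus comparison; defaults to order of appearance.
#' @param alpha family-wise significance level.
#' @return a data frame with one row per ROI x metric: group means and
#'   SDs of mean TF, Welch `statistic`, `dof`, `p_value`,
#'   `p_bonferroni`, `significant`.
#' @export
mean_tf_group_comparison <- function(cohort, contrast = NULL, alpha = 0.05) {
  per_roi_welch(cohort, "mean_tf", contrast, alpha)
}

per_roi_welch <- function(cohort, column, contrast = NULL, alpha = 0.05) {
  contrast <- validate_cohort(cohort, contrast)
  out <- list()
  for (metric in unique(cohort$metric)) {
    rois <- unique(cohort$roi[cohort$metric == metric])
    rows <- lapply(rois, function(roi) {
      x <- group_column(cohort, roi, metric, contrast[1], column)
      y <- group_column(cohort, roi, metric, contrast[2], column)
      w <- welch_t_test(x, y)
      data.frame(roi = roi, metric = metric,
                 mean_1 = w$group_means[1], sd_1 = w$group_sds[1],
                 mean_2 = w$group_means[2], sd_2 = w$group_sds[2],
                 statistic = w$statistic, dof = w$dof,
                 p_value = w$p_value, stringsAsFactors = FALSE)
    })
    block <- do.call(rbind, rows)
    adj <- bonferroni(block$p_value, alpha)
    block$p_bonferroni <- adj$p_adjusted
    block$significant <- adj$significant
    out[[metric]] <- block
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "contrast") <- contrast
  attr(res, "family") <- "ROIs within metric"
  attr(res, "alpha") <- alpha
  res
}

#' Bias analysis: non-zero bias per group and group differences
#'
#' The per-ROI bias analysis of the conventional mean: within each
#' group, a two-tailed one-sample t-test of the per-subject bias
#' (conventional minus tissue-weighted mean) against zero; between
#' groups, a two-tailed Welch's t-test on the same column. Both are
#' Bonferroni-corrected across ROIs within each metric.
#'
#' @inheritParams mean_tf_group_comparison
#' @return a list with `one_sample` (one row per ROI x metric x group)
#'   and `between_group` (one row per ROI x metric) data frames.
#' @export
bias_analysis <- function(cohort, contrast = NULL, alpha = 0.05) {
  contrast <- validate_cohort(cohort, contrast)
  one <- list()
  for (metric in unique(cohort$metric)) {
    for (grp in contrast) {
      rois <- unique(cohort$roi[cohort$metric == metric])
      rows <- lapply(rois, function(roi) {
        b <- group_column(cohort, roi, metric, grp, "bias")
        r <- one_sample_t_test(b, 0)
        data.frame(roi = roi, metric = metric, group = grp,
                   mean_bias = r$mean, sd_bias = r$sd, n = r$n,
                   statistic = r$statistic, dof = r$dof,
                   p_value = r$p_value, stringsAsFactors = FALSE)
      })
      block <- do.call(rbind, rows)
      adj <- bonferroni(block$p_value, alpha)
      block$p_bonferroni <- adj$p_adjusted
      block$significant <- adj$significant
      one[[paste(metric, grp)]] <- block
    }
  }
  one_sample <- do.call(rbind, one)
  rownames(one_sample) <- NULL
  between <- per_roi_welch(cohort, "bias", contrast, alpha)
  list(one_sample = one_sample, between_group = between)
}

per_roi_group_means <- function(cohort, metric, grp) {
  sub <- cohort[cohort$metric == metric & cohort$group == grp, ]
  rois <- unique(sub$roi)
  data.frame(
    roi = rois,
    abs_bias = vapply(rois, function(r)
      mean(abs(sub$bias[sub$roi == r])), numeric(1)),
    inv_mean_tf = vapply(rois, function(r)
      mean(1 / sub$mean_tf[sub$roi == r]), numeric(1)),
    stringsAsFactors = FALSE)
}

#' Correlation of bias magnitude with inverse mean tissue fraction
#'
#' The closed-form bias `-Cov(m, t) / mean(t)` predicts that, for
#' comparable covariances, bias magnitude scales with the inverse of
#' the mean TF. This computes, per metric and group, the Pearson
#' correlation across ROIs between the group-mean |bias| and the
#' group mean of 1 / (per-subject mean TF); each ROI contributes one
#' point (its between-subject means).
#'
#' @inheritParams mean_tf_group_comparison
#' @return a data frame with one row per metric x group: `r`,
#'   `p_value`, `n` (number of ROIs).
#' @export
bias_tf_correlation <- function(cohort, contrast = NULL) {
  contrast <- validate_cohort(cohort, contrast)
  rows <- list()
  for (metric in unique(cohort$metric)) {
    for (grp in contrast) {
      pts <- per_roi_group_means(cohort, metric, grp)
      if (nrow(pts) < 3L)
        stop("need at least 3 ROIs for a correlation")
      if (stats::sd(pts$abs_bias) == 0 || stats::sd(pts$inv_mean_tf) == 0)
        stop("constant input: correlation undefined")
      ct <- stats::cor.test(pts$abs_bias, pts$inv_mean_tf,
                            method = "pearson")
      rows[[paste(metric, grp)]] <- data.frame(
        metric = metric, group = grp, r = unname(ct$estimate),
        p_value = ct$p.value, n = nrow(pts), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Compare bias magnitude between periventricular and other ROIs
#'
#' Per metric and group, a two-tailed Welch's t-test of the per-ROI
#' group-mean |bias| split by the periventricular flag (one observation
#' per ROI). Periventricular regions border the ventricles and so tend
#' to carry more CSF partial volume and larger bias. The decision is at
#' uncorrected `alpha` (a single test per metric x group, not a
#' per-ROI family).
#'
#' @inheritParams mean_tf_group_comparison
#' @param roidefs ROI definition table with the `periventricular` flag.
#' @return a data frame with one row per metric x group: group sizes,
#'   mean |bias| in each class, Welch `statistic`, `dof`, `p_value`,
#'   `significant`.
#' @export
periventricular_bias_comparison <- function(cohort,
                                            roidefs = roi_definitions(),
                                            contrast = NULL, alpha = 0.05) {
  contrast <- validate_cohort(cohort, contrast)
  flag <- stats::setNames(roidefs$periventricular, roidefs$abbreviation)
  rows <- list()
  for (metric in unique(cohort$metric)) {
    for (grp in contrast) {
      pts <- per_roi_group_means(cohort, metric, grp)
      pv <- flag[pts$roi]
      if (any(is.na(pv)))
        stop(sprintf("ROI(s) missing from definition table: %s",
                     paste(pts$roi[is.na(pv)], collapse = ", ")))
      if (all(pv) || all(!pv))
        stop("all ROIs fall in one periventricular class: test undefined")
      w <- welch_t_test(pts$abs_bias[pv], pts$abs_bias[!pv])
      rows[[paste(metric, grp)]] <- data.frame(
        metric = metric, group = grp,
        n_periventricular = sum(pv), n_other = sum(!pv),
        mean_abs_bias_periventricular = w$group_means[1],
        mean_abs_bias_other = w$group_means[2],
        statistic = w$statistic, dof = w$dof, p_value = w$p_value,
        significant = w$p_value < alpha, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Effect sizes from conventional vs tissue-weighted means
#'
#' Per ROI and metric, Cohen's d_s for the group contrast computed
#' twice: once from the per-subject conventional means and once from
#' the per-subject tissue-weighted means, together with Welch-test
#' significance of the group difference for each estimator
#' (Bonferroni-corrected across ROIs within metric). When the two
#' groups carry different amounts of CSF partial-volume bias, the
#' conventional-mean effect size is distorted relative to the
#' tissue-weighted one; the `difference` column quantifies this.
#'
#' @inheritParams mean_tf_group_comparison
#' @return a data frame with one row per ROI x metric:
#'   `d_conventional`, `d_tissue_weighted`, `difference`
#'   (= d_conventional - d_tissue_weighted), `p_conventional`,
#'   `p_tissue_weighted` (Bonferroni-adjusted), `sig_conventional`,
#'   `sig_tissue_weighted`.
#' @export
effect_size_comparison <- function(cohort, contrast = NULL, alpha = 0.05) {
  contrast <- validate_cohort(cohort, contrast)
  out <- list()
  for (metric in unique(cohort$metric)) {
    rois <- unique(cohort$roi[cohort$metric == metric])
    rows <- lapply(rois, function(roi) {
      res <- lapply(c("conventional_mean", "tissue_weighted_mean"),
                    function(col) {
        x <- group_column(cohort, roi, metric, contrast[1], col)
        y <- group_column(cohort, roi, metric, contrast[2], col)
        list(d = cohens_ds(x, y), p = welch_t_test(x, y)$p_value)
      })
      data.frame(roi = roi, metric = metric,
                 d_conventional = res[[1]]$d,
                 d_tissue_weighted = res[[2]]$d,
                 difference = res[[1]]$d - res[[2]]$d,
                 p_conventional = res[[1]]$p,
                 p_tissue_weighted = res[[2]]$p,
                 stringsAsFactors = FALSE)
    })
    block <- do.call(rbind, rows)
    adj_c <- bonferroni(block$p_conventional, alpha)
    adj_t <- bonferroni(block$p_tissue_weighted, alpha)
    block$p_conventional <- adj_c$p_adjusted
    block$p_tissue_weighted <- adj_t$p_adjusted
    block$sig_conventional <- adj_c$significant
    block$sig_tissue_weighted <- adj_t$significant
    out[[metric]] <- block
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "contrast") <- contrast
  res
}
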