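#' Construct a per-ROI sample of metric values and tissue fractions
#'
#' An `roi_sample` holds, for one region of interest in one subject, the
#' voxelwise values of a tissue microstructure metric (e.g. NODDI NDI or
#' ODI) together with the voxelwise tissue fraction (TF) used as the
#' weight by the tissue-weighted mean. Multi-compartment models such as
#' NODDI estimate the metric as a property of the tissue compartment
#' only, so a voxel contaminated by CSF still reports the metric of its
#' tissue portion; the TF records how much tissue that is.
#'
#' Non-finite metric or TF voxels are removed before any statistic is
#' computed, and the removal applies identically to every estimator so
#' that the algebraic identity between the two means and the covariance
#' term remains exact. TF values slightly outside `[0, 1]` (a common
#' artefact of imperfect model fits) are clipped to the unit interval
#' when `clip_tf = TRUE` (the default), with a warning; with
#' `clip_tf = FALSE` they are an error.
#'
#' @param metric_values numeric vector, the per-voxel metric values m_i.
#' @param tissue_fractions numeric vector of the same length, the
#'   per-voxel tissue fractions t_i in `[0, 1]`.
#' @param metric_name optional metric tag, e.g. `"NDI"` or `"ODI"`.
#' @param roi_label optional ROI identifier (integer label or
#'   abbreviation string).
#' @param clip_tf clip tissue fractions to `[0, 1]` (with a warning)
#'   instead of erroring when values fall outside the unit interval.
#' @return an object of class `roi_sample` with elements
#'   `metric_values`, `tissue_fractions`, `n_voxels`, `n_excluded`
#'   (non-finite voxels dropped), `metric_name` and `roi_label`.
#' @examples
#' s <- roi_sample(c(0.55, 0.60), c(0.5, 1.0))
#' conventional_mean(s)
#' tissue_weighted_mean(s)
#' @export
roi_sample <- function(metric_values, tissue_fractions,
                       metric_name = NA_character_, roi_label = NA,
                       clip_tf = TRUE) {
  if (!is.numeric(metric_values) || !is.numeric(tissue_fractions))
    stop("'metric_values' and 'tissue_fractions' must be numeric vectors")
  if (length(metric_values) != length(tissue_fractions))
    stop(sprintf(
      "length mismatch: %d metric values vs %d tissue fractions",
      length(metric_values), length(tissue_fractions)))
  if (length(metric_values) == 0L)
    stop("degenerate ROI: sample contains no voxels")

  keep <- is.finite(metric_values) & is.finite(tissue_fractions)
  n_excluded <- sum(!keep)
  m <- as.numeric(metric_values[keep])
  t <- as.numeric(tissue_fractions[keep])
  if (length(m) == 0L)
    stop("degenerate ROI: all voxels excluded as non-finite")

  out_of_range <- t < 0 | t > 1
  if (any(out_of_range)) {
    if (!clip_tf)
      stop(sprintf(
        "%d tissue fraction(s) outside [0, 1] (range %.4g to %.4g)",
        sum(out_of_range), min(t), max(t)))
    warning(sprintf(
      "clipped %d tissue fraction(s) to [0, 1]", sum(out_of_range)))
    t <- pmin(pmax(t, 0), 1)
  }

  structure(
    list(metric_values = m, tissue_fractions = t,
         n_voxels = length(m), n_excluded = n_excluded,
         metric_name = metric_name, roi_label = roi_label),
    class = "roi_sample")
}

#' @export
print.roi_sample <- function(x, ...) {
  cat(sprintf("<roi_sample> %s / %s: %d voxels (%d excluded), mean TF %.3f\n",
              as.character(x$roi_label), x$metric_name, x$n_voxels,
              x$n_excluded, mean(x$tissue_fractions)))
  invisible(x)
}

as_roi_sample <- function(x) {
  if (inherits(x, "roi_sample")) return(x)
  stop("expected an 'roi_sample' object")
}

#' Conventional (arithmetic) ROI mean
#'
#' Equal-weight arithmetic mean of the metric over the ROI voxels. Under
#' CSF partial volume this estimator is biased for the mean metric of
#' the ROI's tissue, by `-Cov(m, t) / mean(t)`; see [predicted_bias()].
#'
#' @param sample an [roi_sample()].
#' @return the arithmetic mean of the metric values.
#' @export
conventional_mean <- function(sample) {
  sample <- as_roi_sample(sample)
  mean(sample$metric_values)
}

#' Tissue-weighted ROI mean
#'
#' Mean of the metric over the tissue within the ROI: each voxel's
#' metric value is weighted by its tissue fraction,
#' `sum(t_i * m_i) / sum(t_i)`. Because voxelwise metrics from
#' multi-compartment models describe the tissue portion of the voxel,
#' this weighted average is an unbiased estimate of the mean metric
#' across the ROI's tissue, regardless of how CSF partial volume is
#' distributed over voxels.
#'
#' The `"ratio"` form divides the mean of the products `t_i * m_i` by
#' the mean TF; it is algebraically identical (both numerator and
#' denominator divided by the voxel count) and is the formulation that
#' maps directly onto voxelwise image arithmetic followed by ordinary
#' ROI means.
#'
#' @param sample an [roi_sample()].
#' @param form `"direct"` for `sum(t*m)/sum(t)`, `"ratio"` for
#'   `mean(t*m)/mean(t)`. The two agree to floating-point rounding.
#' @return the tissue-weighted mean, a value within the range of the
#'   metric values.
#' @export
tissue_weighted_mean <- function(sample, form = c("direct", "ratio")) {
  sample <- as_roi_sample(sample)
  form <- match.arg(form)
  t <- sample$tissue_fractions
  m <- sample$metric_values
  if (sum(t) <= 0)
    stop("all-CSF ROI: tissue fractions sum to zero, tissue mean undefined")
  switch(form,
    direct = sum(t * m) / sum(t),
    ratio  = mean(t * m) / mean(t))
}

#' Population covariance of metric and tissue fraction within an ROI
#'
#' Covariance between the metric values and the tissue fractions across
#' the ROI voxels, computed without Bessel's correction (denominator N,
#' not N - 1). The population form is what makes the bias identity
#' `conventional - tissue_weighted = -Cov(m, t) / mean(t)` hold exactly
#' for finite samples. For a single voxel the covariance is 0.
#'
#' @param sample an [roi_sample()].
#' @return the population covariance `Cov(m, t)`.
#' @export
population_covariance <- function(sample) {
  sample <- as_roi_sample(sample)
  m <- sample$metric_values
  t <- sample$tissue_fractions
  mean((m - mean(m)) * (t - mean(t)))
}

#' Closed-form bias of the conventional ROI mean
#'
#' Bias of the equal-weight arithmetic mean relative to the
#' tissue-weighted mean: `-Cov(m, t) / mean(t)`, with the population
#' covariance of [population_covariance()]. This equals
#' `conventional_mean(sample) - tissue_weighted_mean(sample)` exactly
#' (to floating-point rounding). The bias is positive when metric and
#' tissue fraction are negatively correlated and vice versa, and for a
#' fixed covariance it grows as the mean TF shrinks, i.e. as CSF
#' partial volume increases.
#'
#' @param sample an [roi_sample()].
#' @return the predicted bias of the conventional mean.
#' @export
predicted_bias <- function(sample) {
  sample <- as_roi_sample(sample)
  t_bar <- mean(sample$tissue_fractions)
  if (t_bar <= 0)
    stop("all-CSF ROI: mean tissue fraction is zero, bias undefined")
  -population_covariance(sample) / t_bar
}

#' Median of the metric over ROI voxels
#'
#' Ordinary sample median of the voxelwise metric values (midpoint of
#' the middle two for an even voxel count). Like the conventional mean
#' it weights voxels equally and so remains susceptible to CSF
#' partial-volume bias of comparable magnitude; it is provided for
#' comparison with the tissue-weighted mean.
#'
#' @param sample an [roi_sample()].
#' @return the sample median of the metric values.
#' @export
roi_median <- function(sample) {
  sample <- as_roi_sample(sample)
  stats::median(sample$metric_values)
}

#' Summarise an ROI sample
#'
#' Computes every per-ROI statistic in one pass: both means, the bias
#' (their difference, identically `-Cov(m, t) / mean TF`), the mean
#' tissue fraction, the mean voxelwise product `t * m`, the population
#' covariance, the median and the voxel count.
#'
#' @param sample an [roi_sample()].
#' @return an object of class `roi_summary`: a named list with elements
#'   `conventional_mean`, `tissue_weighted_mean`, `bias`, `mean_tf`,
#'   `mean_product`, `covariance`, `median`, `n_voxels`, `n_excluded`,
#'   `metric_name`, `roi_label`.
#' @export
summarise_roi <- function(sample) {
  sample <- as_roi_sample(sample)
  conv <- conventional_mean(sample)
  tw <- tissue_weighted_mean(sample)
  structure(
    list(conventional_mean = conv,
         tissue_weighted_mean = tw,
         bias = conv - tw,
         mean_tf = mean(sample$tissue_fractions),
         mean_product = mean(sample$tissue_fractions * sample$metric_values),
         covariance = population_covariance(sample),
         median = roi_median(sample),
         n_voxels = sample$n_voxels,
         n_excluded = sample$n_excluded,
         metric_name = sample$metric_name,
         roi_label = sample$roi_label),
    class = "roi_summary")
}

#' @export
print.roi_summary <- function(x, ...) {
  cat(sprintf(
    paste0("<roi_summary> %s / %s (N = %d)\n",
           "  conventional mean    %.6f\n",
           "  tissue-weighted mean %.6f\n",
           "  bias                 %+.6f\n",
           "  mean tissue fraction %.4f\n"),
    as.character(x$roi_label), x$metric_name, x$n_voxels,
    x$conventional_mean, x$tissue_weighted_mean, x$bias, x$mean_tf))
  invisible(x)
}

#' @export
as.data.frame.roi_summary <- function(x, ...) {
  data.frame(roi = as.character(x$roi_label), metric = x$metric_name,
             n_voxels = x$n_voxels, mean_tf = x$mean_tf,
             conventional_mean = x$conventional_mean,
             tissue_weighted_mean = x$tissue_weighted_mean,
             bias = x$bias, covariance = x$covariance,
             median = x$median, stringsAsFactors = FALSE)
}
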