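#' Fine-grid phantom with known sub-voxel structure
#'
#' A phantom defined on a grid finer than the imaging resolution: each
#' element carries a local neurite density in `[0, 1]` or is marked as
#' CSF. Block-averaging the phantom to the imaging grid emulates what a
#' multi-compartment model observes: per voxel, the metric is the mean
#' density of the tissue sub-elements the voxel covers, and the tissue
#' fraction is the proportion of non-CSF sub-elements. Because the
#' exact mean density over all tissue sub-elements is known, the
#' phantom provides an analytic ground truth for the ROI tissue mean.
#'
#' @param density_field 2-D or 3-D numeric array of local densities in
#'   `[0, 1]`; values under the CSF mask are ignored.
#' @param csf_mask logical array of the same shape marking CSF
#'   sub-elements.
#' @param block_factor integer >= 1; the downsampling factor, which
#'   must divide every dimension of the grid.
#' @return an object of class `fine_grid_phantom`.
#' @seealso [downsample_phantom()]
#' @export
fine_grid_phantom <- function(density_field, csf_mask, block_factor) {
  if (is.null(dim(density_field)))
    stop("'density_field' must be a 2-D or 3-D array")
  nd <- length(dim(density_field))
  if (!nd %in% c(2L, 3L))
    stop("'density_field' must be a 2-D or 3-D array")
  if (!identical(dim(density_field), dim(csf_mask)))
    stop("'csf_mask' must have the same shape as 'density_field'")
  if (!is.logical(csf_mask)) stop("'csf_mask' must be logical")
  block_factor <- as.integer(block_factor)
  if (block_factor < 1L) stop("'block_factor' must be >= 1")
  if (any(dim(density_field) %% block_factor != 0L))
    stop(sprintf("block_factor %d does not divide dims %s", block_factor,
                 paste(dim(density_field), collapse = "x")))
  if (all(csf_mask)) stop("fully-CSF phantom: no tissue to summarise")
  if (any(!is.finite(density_field[!csf_mask])))
    stop("non-finite density in tissue sub-elements")
  structure(list(density_field = density_field, csf_mask = csf_mask,
                 block_factor = block_factor),
            class = "fine_grid_phantom")
}

block_index <- function(dims, bf) {
  idx <- arrayInd(seq_len(prod(dims)), dims)
  blk <- (idx - 1L) %/% bf
  out_dims <- dims %/% bf
  strides <- cumprod(c(1L, out_dims[-length(out_dims)]))
  as.vector(blk %*% strides) + 1L
}

#' Downsample a fine-grid phantom to imaging resolution
#'
#' Averages the phantom over `block_factor`-sized blocks: per output
#' voxel the tissue fraction is the fraction of non-CSF sub-elements
#' and the metric is the mean density over the non-CSF sub-elements
#' (undefined, `NaN`, for a fully-CSF voxel, which downstream ROI
#' extraction excludes). The exact tissue mean — the mean density over
#' all non-CSF sub-elements of the whole phantom — is returned
#' alongside, and equals the tissue-weighted mean of the downsampled
#' voxels by construction, whereas the conventional voxel mean deviates
#' whenever the tissue fraction varies and co-varies with the metric.
#'
#' @param phantom a [fine_grid_phantom()].
#' @return a list with `tf` (array of tissue fractions), `metric`
#'   (array of voxel metrics, `NaN` where fully CSF), and
#'   `tissue_mean` (the exact fine-grid tissue mean).
#' @export
downsample_phantom <- function(phantom) {
  stopifnot(inherits(phantom, "fine_grid_phantom"))
  dims <- dim(phantom$density_field)
  bf <- phantom$block_factor
  blk <- block_index(dims, bf)
  out_dims <- dims %/% bf
  n_blocks <- prod(out_dims)
  tissue <- !phantom$csf_mask
  d <- phantom$density_field
  d[!tissue] <- 0

  n_tissue <- as.vector(rowsum(as.numeric(tissue), blk,
                               reorder = TRUE))
  sum_density <- as.vector(rowsum(as.vector(d), blk, reorder = TRUE))
  stopifnot(length(n_tissue) == n_blocks)

  tf <- array(n_tissue / bf^length(dims), out_dims)
  metric <- array(ifelse(n_tissue > 0, sum_density / n_tissue, NaN),
                  out_dims)
  list(tf = tf, metric = metric,
       tissue_mean = sum(d) / sum(tissue))
}

#' Random fine-grid phantom
#'
#' Generates a phantom with a smooth-ish density field (independent
#' Gaussian densities around `density_mean`, truncated to `[0, 1]`)
#' and CSF sub-elements placed either at random or concentrated toward
#' one face of the grid. The `gradient` layout couples tissue fraction
#' to position, which (combined with a density trend along the same
#' axis via `density_slope`) induces a controllable covariance between
#' voxel metric and tissue fraction after downsampling — the condition
#' under which the conventional ROI mean is biased.
#'
#' @param dims integer vector (length 2 or 3) of fine-grid dimensions.
#' @param block_factor downsampling factor dividing every dimension.
#' @param csf_fraction overall fraction of CSF sub-elements.
#' @param csf_layout `"random"` for spatially uniform CSF,
#'   `"gradient"` for CSF probability increasing along the first axis.
#' @param density_mean,density_sd mean and SD of the local density.
#' @param density_slope linear density trend along the first axis
#'   (total change across the grid), creating metric-TF covariance
#'   under the `"gradient"` layout.
#' @return a [fine_grid_phantom()].
#' @export
random_phantom <- function(dims, block_factor = 4, csf_fraction = 0.2,
                           csf_layout = c("gradient", "random"),
                           density_mean = 0.55, density_sd = 0.05,
                           density_slope = 0) {
  csf_layout <- match.arg(csf_layout)
  n <- prod(dims)
  pos <- (arrayInd(seq_len(n), dims)[, 1] - 0.5) / dims[1]  # in (0,1)
  dens <- stats::rnorm(n, density_mean + density_slope * (pos - 0.5),
                       density_sd)
  dens <- pmin(pmax(dens, 0), 1)
  p_csf <- switch(csf_layout,
    random = rep(csf_fraction, n),
    gradient = {
      p <- 2 * csf_fraction * pos
      pmin(p, 1)
    })
  csf <- stats::runif(n) < p_csf
  if (all(csf)) csf[1] <- FALSE
  fine_grid_phantom(array(dens, dims), array(csf, dims), block_factor)
}

## ---- ROI-level simulation -------------------------------------------------

beta_shapes <- function(mean, sd) {
  v <- sd^2
  vmax <- mean * (1 - mean)
  if (v >= vmax)
    stop(sprintf("tf_spread %.3g too large for tf_mean %.3g", sd, mean))
  nu <- vmax / v - 1
  c(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Simulate one ROI sample with analytic ground truth
#'
#' Draws voxelwise tissue fractions from a Beta distribution with the
#' requested mean and spread, then generates metric values that depend
#' linearly on tissue fraction: `m_i = mu + kappa (t_i - mean(t)) +
#' noise`, truncated to `[0, 1]`. The slope `kappa` sets the
#' metric-TF covariance (population covariance of the noiseless
#' component is exactly `kappa * Var(t)`), so the closed-form bias
#' `-kappa * Var(t) / mean(t)` of the conventional mean is known
#' analytically. With `sigma = 0` the tissue-weighted mean recovers the
#' recorded ground-truth tissue mean exactly.
#'
#' @param n number of voxels (>= 2).
#' @param tf_mean,tf_spread mean and SD of the tissue-fraction
#'   distribution; `tf_mean` in (0, 1], `tf_spread = 0` gives a
#'   constant TF.
#' @param kappa linear dependence of the metric on tissue fraction
#'   (metric units per unit TF); negative `kappa` produces positive
#'   conventional-mean bias.
#' @param mu metric level at the mean tissue fraction, in `[0, 1]`.
#' @param sigma SD of additive voxelwise noise.
#' @param metric_name,roi_label tags stored in the sample.
#' @return a list with `sample` (an [roi_sample()]) and `truth`
#'   (a one-row data frame: `true_tissue_mean` — the tissue-weighted
#'   mean of the noiseless component, `true_cov` — the population
#'   covariance of the noiseless component with TF, `true_mean_tf`,
#'   `n_clipped`).
#' @export
simulate_roi_sample <- function(n, tf_mean, tf_spread, kappa, mu,
                                sigma = 0, metric_name = NA_character_,
                                roi_label = NA) {
  if (n < 2) stop("'n' must be >= 2")
  if (tf_mean <= 0 || tf_mean > 1) stop("'tf_mean' must be in (0, 1]")
  if (sigma < 0) stop("'sigma' must be >= 0")
  if (tf_spread == 0) {
    t <- rep(tf_mean, n)
  } else {
    sh <- beta_shapes(tf_mean, tf_spread)
    t <- stats::rbeta(n, sh["alpha"], sh["beta"])
    t[t == 0] <- .Machine$double.eps  # Beta support is open; guard exact 0
  }
  m0 <- mu + kappa * (t - mean(t))
  m <- m0 + if (sigma > 0) stats::rnorm(n, 0, sigma) else 0
  clipped <- m < 0 | m > 1
  if (mean(clipped) > 0.05)
    warning(sprintf("%.1f%% of voxels clipped to [0, 1]; ground truth %s",
                    100 * mean(clipped),
                    "no longer matches the generative parameters"))
  m <- pmin(pmax(m, 0), 1)
  tbar <- mean(t)
  truth <- data.frame(
    true_tissue_mean = sum(t * m0) / sum(t),
    true_cov = mean((m0 - mean(m0)) * (t - tbar)),
    true_mean_tf = tbar,
    n_clipped = sum(clipped))
  list(sample = roi_sample(m, t, metric_name = metric_name,
                           roi_label = roi_label),
       truth = truth)
}

## ---- cohort simulation ----------------------------------------------------

#' Default configuration for a synthetic two-group cohort
#'
#' Builds a simulation configuration emulating a case-control
#' microstructure study: two groups of unequal size (21 controls vs 30
#' patients by default), 48 white-matter regions from the packaged
#' atlas table, and two tissue metrics (NDI, ODI). Patients have lower
#' tissue fractions (atrophy increases CSF partial volume), the
#' reduction and the TF spread being larger in periventricular
#' regions, and a stronger negative metric-TF covariance, so the
#' conventional ROI mean is more biased in patients — the regime in
#' which conventional-mean effect sizes are distorted.
#'
#' Per-region voxel counts are log-spaced over `n_voxel_range` so
#' small structures (fornix, tapetum) and large ones coexist, matching
#' the spread of real parcellations at this grid size.
#'
#' @param n_per_group integer pair: subjects in the reference and
#'   comparison group.
#' @param groups labels of the two groups (reference first; the
#'   default contrast is reference minus comparison).
#' @param roidefs ROI definition table; defaults to the packaged one.
#' @param n_voxel_range range of per-ROI voxel counts.
#' @param tf_base,tf_pv_drop mean TF in the reference group for
#'   non-periventricular ROIs, and the additional reduction in
#'   periventricular ROIs.
#' @param tf_group_drop TF reduction in the comparison group, given as
#'   `c(periventricular, other)`.
#' @param tf_spread TF standard deviation across voxels,
#'   `c(periventricular, other)`.
#' @param metrics named list of per-metric generative parameters, each
#'   a list with `mu` (length-2, per group), `kappa_pv` and
#'   `kappa_other` (length-2, per group: metric-TF slope in
#'   periventricular / other ROIs) and `sigma` (voxel noise SD).
#' @param subject_sd between-subject SD of the metric level (random
#'   intercept giving realistic between-subject variance).
#' @param tf_subject_sd between-subject SD of the TF level.
#' @param grid_dim 3-D image dimensions for the written volumes.
#' @param seed integer seed making the cohort fully reproducible.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = c(21, 30),
                          groups = c("control", "patient"),
                          roidefs = roi_definitions(),
                          n_voxel_range = c(100, 600),
                          tf_base = 0.92, tf_pv_drop = 0.12,
                          tf_group_drop = c(0.05, 0.015),
                          tf_spread = c(0.12, 0.06),
                          metrics = list(
                            NDI = list(mu = c(0.60, 0.55),
                                       kappa_pv = c(0.05, -0.15),
                                       kappa_other = c(-0.10, -0.15),
                                       sigma = 0.05),
                            ODI = list(mu = c(0.45, 0.42),
                                       kappa_pv = c(-0.25, -0.45),
                                       kappa_other = c(-0.10, -0.15),
                                       sigma = 0.05)),
                          subject_sd = 0.02, tf_subject_sd = 0.02,
                          grid_dim = c(24, 24, 24), seed = 1L) {
  stopifnot(length(n_per_group) == 2, all(n_per_group >= 2),
            length(groups) == 2, !anyDuplicated(groups))
  nroi <- nrow(roidefs)
  n_vox <- round(exp(seq(log(n_voxel_range[1]), log(n_voxel_range[2]),
                         length.out = nroi)))
  # interleave sizes so neither periventricular class gets only the
  # small or only the large regions
  ord <- order(rank(roidefs$label_id * ((roidefs$label_id %% 2) * 2 - 1)))
  n_vox <- n_vox[ord]
  if (sum(n_vox) > prod(grid_dim))
    stop(sprintf("grid %s too small for %d ROI voxels",
                 paste(grid_dim, collapse = "x"), sum(n_vox)))
  pv <- roidefs$periventricular
  # deterministic within-class TF gradient so mean TF varies across ROIs
  spread_pos <- stats::ave(seq_len(nroi), pv,
                           FUN = function(i) seq(-0.5, 0.5,
                                                 length.out = length(i)))
  tf_ref <- tf_base - tf_pv_drop * pv + 0.06 * spread_pos
  rois <- data.frame(
    abbreviation = roidefs$abbreviation,
    label_id = roidefs$label_id,
    periventricular = pv,
    n_voxels = n_vox,
    tf_mean_1 = tf_ref,
    tf_mean_2 = tf_ref - ifelse(pv, tf_group_drop[1], tf_group_drop[2]),
    tf_spread = ifelse(pv, tf_spread[1], tf_spread[2]),
    stringsAsFactors = FALSE)
  structure(list(n_per_group = as.integer(n_per_group), groups = groups,
                 rois = rois, metrics = metrics,
                 subject_sd = subject_sd, tf_subject_sd = tf_subject_sd,
                 grid_dim = as.integer(grid_dim), seed = as.integer(seed)),
            class = "cohort_config")
}

#' Read a cohort configuration from YAML or JSON
#'
#' Reads the scalar fields of [cohort_config()] from a YAML file (JSON
#' is a YAML subset, so both parse) and builds the configuration with
#' the remaining defaults. Recognised keys: `n_per_group`, `groups`,
#' `seed`, `grid_dim`, `n_voxel_range`, `tf_base`, `tf_pv_drop`,
#' `tf_group_drop`, `tf_spread`, `subject_sd`, `tf_subject_sd`, and a
#' `metrics` block mirroring the `metrics` argument.
#'
#' @param path path to the YAML/JSON configuration file.
#' @return a `cohort_config` object.
#' @export
read_cohort_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: %s", path))
  raw <- yaml::read_yaml(path)
  allowed <- c("n_per_group", "groups", "seed", "grid_dim",
               "n_voxel_range", "tf_base", "tf_pv_drop", "tf_group_drop",
               "tf_spread", "subject_sd", "tf_subject_sd", "metrics")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown))
    stop(sprintf("unknown config field(s): %s",
                 paste(unknown, collapse = ", ")))
  if (!is.null(raw$metrics))
    raw$metrics <- lapply(raw$metrics, function(m)
      lapply(m, as.numeric))
  do.call(cohort_config, raw)
}

subject_roi_params <- function(config, group_idx, subject_tf_shift,
                               subject_mu_shift) {
  rois <- config$rois
  # keep strictly inside (0, 1) so a Beta with the requested spread exists
  tf_mean <- pmin(pmax(
    rois[[paste0("tf_mean_", group_idx)]] + subject_tf_shift, 0.05), 0.97)
  params <- list()
  for (metric in names(config$metrics)) {
    mp <- config$metrics[[metric]]
    params[[metric]] <- list(
      mu = pmin(pmax(mp$mu[group_idx] + subject_mu_shift[[metric]], 0), 1),
      kappa = ifelse(rois$periventricular, mp$kappa_pv[group_idx],
                     mp$kappa_other[group_idx]),
      sigma = mp$sigma)
  }
  list(tf_mean = tf_mean, metrics = params)
}

#' Simulate a full two-group cohort with images and ground truth
#'
#' Generates per-subject tissue-fraction and metric volumes on a
#' shared grid, a shared integer label image (regions occupy fixed
#' voxel blocks), the long-format cohort table obtained by running the
#' ROI extraction on those volumes, and the generative ground truth
#' per subject, region and metric. Everything derives from
#' `config$seed`, so a rerun reproduces the outputs bit for bit.
#'
#' Each subject receives a random TF level shift and per-metric level
#' shifts (between-subject variability); each region then draws
#' voxelwise tissue fractions and metrics via [simulate_roi_sample()].
#'
#' @param config a [cohort_config()].
#' @param outdir optional directory; if given, per-subject NIfTI
#'   volumes (`<id>_<metric>.nii.gz`, `<id>_tf.nii.gz`), the shared
#'   `labels.nii.gz`, `cohort.csv` and `ground_truth.csv` are written
#'   there.
#' @return a list with `cohort` (the cohort table), `truth` (ground
#'   truth rows), `labels` (label array), `subjects` (per-subject
#'   named list of metric and TF arrays), `subject_table` (id, group)
#'   and `config`.
#' @export
simulate_cohort <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  rois <- config$rois
  grid_n <- prod(config$grid_dim)
  # fixed voxel allocation: consecutive flattened blocks per region
  stops <- cumsum(rois$n_voxels)
  starts <- stops - rois$n_voxels + 1L
  labels <- integer(grid_n)
  for (j in seq_len(nrow(rois)))
    labels[starts[j]:stops[j]] <- rois$label_id[j]
  label_img <- array(labels, config$grid_dim)

  subject_ids <- sprintf("sub-%03d", seq_len(sum(config$n_per_group)))
  group_of <- rep(config$groups, config$n_per_group)
  metric_names <- names(config$metrics)

  subjects <- list()
  cohort_rows <- list()
  truth_rows <- list()
  for (s in seq_along(subject_ids)) {
    gi <- match(group_of[s], config$groups)
    tf_shift <- stats::rnorm(1, 0, config$tf_subject_sd)
    mu_shift <- stats::setNames(
      as.list(stats::rnorm(length(metric_names), 0, config$subject_sd)),
      metric_names)
    par <- subject_roi_params(config, gi, tf_shift, mu_shift)

    vols <- c(list(tf = array(0, config$grid_dim)),
              stats::setNames(
                replicate(length(metric_names),
                          array(0, config$grid_dim), simplify = FALSE),
                metric_names))
    for (j in seq_len(nrow(rois))) {
      idx <- starts[j]:stops[j]
      # one TF field per region per subject, shared by every metric
      sh <- beta_shapes(par$tf_mean[j], rois$tf_spread[j])
      t_vec <- stats::rbeta(rois$n_voxels[j], sh["alpha"], sh["beta"])
      t_vec[t_vec == 0] <- .Machine$double.eps
      vols$tf[idx] <- t_vec
      for (metric in metric_names) {
        mp <- par$metrics[[metric]]
        m0 <- mp$mu + mp$kappa[j] * (t_vec - mean(t_vec))
        m <- m0 + stats::rnorm(length(t_vec), 0, mp$sigma)
        clipped <- m < 0 | m > 1
        m <- pmin(pmax(m, 0), 1)
        sample <- roi_sample(m, t_vec, metric_name = metric,
                             roi_label = rois$abbreviation[j])
        vols[[metric]][idx] <- m
        cohort_rows[[length(cohort_rows) + 1L]] <- cbind(
          subject_id = subject_ids[s], group = group_of[s],
          as.data.frame(summarise_roi(sample)),
          stringsAsFactors = FALSE)
        truth_rows[[length(truth_rows) + 1L]] <- cbind(
          subject_id = subject_ids[s], group = group_of[s],
          roi = rois$abbreviation[j], metric = metric,
          data.frame(
            true_tissue_mean = sum(t_vec * m0) / sum(t_vec),
            true_cov = mean((m0 - mean(m0)) * (t_vec - mean(t_vec))),
            true_mean_tf = mean(t_vec),
            n_clipped = sum(clipped)),
          stringsAsFactors = FALSE)
      }
    }
    subjects[[subject_ids[s]]] <- vols
  }
  cohort <- do.call(rbind, cohort_rows)
  rownames(cohort) <- NULL
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  subject_table <- data.frame(subject_id = subject_ids, group = group_of,
                              stringsAsFactors = FALSE)

  if (!is.null(outdir)) {
    if (!dir.exists(outdir))
      dir.create(outdir, recursive = TRUE)
    RNifti::writeNifti(RNifti::asNifti(label_img),
                       file.path(outdir, "labels.nii.gz"))
    for (id in subject_ids) {
      for (v in names(subjects[[id]]))
        RNifti::writeNifti(RNifti::asNifti(subjects[[id]][[v]]),
                           file.path(outdir,
                                     sprintf("%s_%s.nii.gz", id, v)))
    }
    write_roi_table(cohort, file.path(outdir, "cohort.csv"))
    utils::write.csv(truth, file.path(outdir, "ground_truth.csv"),
                     row.names = FALSE)
    utils::write.csv(subject_table, file.path(outdir, "subjects.csv"),
                     row.names = FALSE)
  }
  list(cohort = cohort, truth = truth, labels = label_img,
       subjects = subjects, subject_table = subject_table,
       config = config)
}
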