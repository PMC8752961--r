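test_that("a CSF-free phantom downsamples to uniform TF and exact means", {
  set.seed(1)
  dens <- array(runif(8^3, 0.3, 0.7), c(8, 8, 8))
  ph <- fine_grid_phantom(dens, array(FALSE, c(8, 8, 8)), 2)
  ds <- downsample_phantom(ph)
  expect_true(all(ds$tf == 1))
  expect_equal(ds$tissue_mean, mean(dens), tolerance = 1e-14)
  s <- roi_sample(as.vector(ds$metric), as.vector(ds$tf))
  expect_equal(tissue_weighted_mean(s), ds$tissue_mean, tolerance = 1e-13)
  expect_equal(conventional_mean(s), ds$tissue_mean, tolerance = 1e-13)
})

test_that("two-voxel half-CSF phantom shows the partial-volume mechanism", {
  # voxel 1: half CSF, tissue denser; voxel 2: all tissue
  # (two identical columns so 2x2 blocks reduce to the 1-D case)
  dens <- array(rep(c(0.62, 0.60, 0.55, 0.50), 2), c(4, 2))
  csf <- array(rep(c(FALSE, TRUE, FALSE, FALSE), 2), c(4, 2))
  ph <- fine_grid_phantom(dens, csf, 2)
  ds <- downsample_phantom(ph)
  expect_equal(as.vector(ds$tf), c(0.5, 1))
  expect_equal(as.vector(ds$metric), c(0.62, 0.525))
  truth <- mean(c(0.62, 0.55, 0.50))
  expect_equal(ds$tissue_mean, truth)
  s <- roi_sample(as.vector(ds$metric), as.vector(ds$tf))
  expect_equal(tissue_weighted_mean(s), truth, tolerance = 1e-14)
  expect_false(isTRUE(all.equal(conventional_mean(s), truth)))
})

test_that("uniform 50% CSF gives constant TF and hence zero bias", {
  dims <- c(8, 8)
  csf <- array(rep(c(TRUE, FALSE), length.out = prod(dims)), dims)
  dens <- array(runif(prod(dims), 0.4, 0.6), dims)
  ph <- fine_grid_phantom(dens, csf, 2)
  ds <- downsample_phantom(ph)
  expect_true(all(ds$tf == 0.5))
  s <- roi_sample(as.vector(ds$metric), as.vector(ds$tf))
  expect_equal(predicted_bias(s), 0, tolerance = 1e-14)
})

test_that("tissue-weighted mean of downsampled voxels is exact on random phantoms", {
  set.seed(23)
  for (i in 1:20) {
    bf <- sample(c(2, 4), 1)
    ph <- random_phantom(c(16, 16, 8), bf, csf_fraction = runif(1, 0.1, 0.4),
                         density_slope = runif(1, -0.3, 0.3))
    ds <- downsample_phantom(ph)
    keep <- is.finite(as.vector(ds$metric))
    s <- roi_sample(as.vector(ds$metric)[keep], as.vector(ds$tf)[keep])
    expect_lt(abs(tissue_weighted_mean(s) - ds$tissue_mean), 1e-12)
  }
})

test_that("phantom constructor rejects invalid geometry", {
  dens <- array(0.5, c(6, 6))
  expect_error(fine_grid_phantom(dens, array(FALSE, c(6, 6)), 4),
               "does not divide")
  expect_error(fine_grid_phantom(dens, array(TRUE, c(6, 6)), 2),
               "fully-CSF")
  expect_error(fine_grid_phantom(0.5, FALSE, 1), "2-D or 3-D")
})

test_that("simulated ROI samples honour their generative parameters", {
  set.seed(5)
  # no slope, no noise: both estimators return mu exactly
  flat <- simulate_roi_sample(200, 0.8, 0.05, kappa = 0, mu = 0.6,
                              sigma = 0)
  expect_equal(conventional_mean(flat$sample), 0.6, tolerance = 1e-12)
  expect_equal(tissue_weighted_mean(flat$sample), 0.6, tolerance = 1e-12)

  # negative slope, no noise: bias equals -kappa * Var(t) / mean(t)
  neg <- simulate_roi_sample(500, 0.7, 0.1, kappa = -0.5, mu = 0.5,
                             sigma = 0)
  s <- neg$sample
  t <- s$tissue_fractions
  analytic <- 0.5 * mean((t - mean(t))^2) / mean(t)
  observed <- conventional_mean(s) - tissue_weighted_mean(s)
  expect_equal(observed, analytic, tolerance = 1e-12)
  expect_gt(observed, 0)
  expect_equal(neg$truth$true_cov, -0.5 * mean((t - mean(t))^2),
               tolerance = 1e-12)
  expect_equal(tissue_weighted_mean(s), neg$truth$true_tissue_mean,
               tolerance = 1e-12)

  # same seed, same draw
  set.seed(99); a <- simulate_roi_sample(50, 0.8, 0.08, -0.3, 0.5, 0.02)
  set.seed(99); b <- simulate_roi_sample(50, 0.8, 0.08, -0.3, 0.5, 0.02)
  expect_identical(a$sample$metric_values, b$sample$metric_values)
  expect_identical(a$truth, b$truth)

  expect_error(simulate_roi_sample(1, 0.8, 0.05, 0, 0.5), ">= 2")
  expect_error(simulate_roi_sample(10, 0.5, 0.6, 0, 0.5), "too large")
  expect_warning(simulate_roi_sample(500, 0.8, 0.05, 0, 0.99, 0.2),
                 "clipped")
})

test_that("tissue-weighted means track ground truth where conventional means drift", {
  set.seed(61)
  n <- 500; sigma <- 0.02
  tw_err <- conv_err <- analytic_bias <- numeric(200)
  for (i in 1:200) {
    kappa <- runif(1, -0.6, -0.2)
    tf_mean <- runif(1, 0.6, 0.9)
    sim <- simulate_roi_sample(n, tf_mean, 0.1, kappa, 0.5, sigma)
    t <- sim$sample$tissue_fractions
    tw_err[i] <- tissue_weighted_mean(sim$sample) -
      sim$truth$true_tissue_mean
    conv_err[i] <- conventional_mean(sim$sample) -
      sim$truth$true_tissue_mean
    analytic_bias[i] <- -kappa * mean((t - mean(t))^2) / mean(t)
  }
  expect_lt(mean(abs(tw_err)), 3 * sigma / sqrt(n * 0.6))
  # conventional error tracks the closed-form bias, not zero
  expect_gt(mean(conv_err), 5 * mean(abs(tw_err)))
  expect_gt(cor(conv_err, analytic_bias), 0.9)
  expect_lt(mean(abs(conv_err - analytic_bias)), 3 * mean(abs(tw_err)))
})

test_that("simulated cohorts are reproducible and internally consistent", {
  cfg <- cohort_config(n_per_group = c(3, 3),
                       roidefs = roi_definitions()[c(1, 6, 20, 47), ],
                       grid_dim = c(12, 12, 12), seed = 404)
  sim1 <- simulate_cohort(cfg)
  sim2 <- simulate_cohort(cfg)
  expect_identical(sim1$cohort, sim2$cohort)
  expect_identical(sim1$subjects, sim2$subjects)

  # different seed changes the data
  cfg2 <- cfg; cfg2$seed <- 405L
  expect_false(identical(simulate_cohort(cfg2)$cohort, sim1$cohort))

  expect_equal(nrow(sim1$cohort), 6 * 4 * 2)  # subjects x ROIs x metrics
  expect_equal(nrow(sim1$truth), nrow(sim1$cohort))
  # estimator output close to recorded ground truth
  merged <- merge(sim1$cohort, sim1$truth,
                  by = c("subject_id", "roi", "metric"))
  expect_lt(max(abs(merged$tissue_weighted_mean -
                      merged$true_tissue_mean)), 0.02)
  expect_lt(max(abs(merged$mean_tf - merged$true_mean_tf)), 1e-12)
})

test_that("extracting ROIs from written volumes reproduces the cohort table", {
  cfg <- cohort_config(n_per_group = c(2, 2),
                       roidefs = roi_definitions()[c(3, 19), ],
                       grid_dim = c(10, 10, 10), seed = 11)
  outdir <- tempfile()
  sim <- simulate_cohort(cfg, outdir = outdir)
  expect_true(file.exists(file.path(outdir, "labels.nii.gz")))
  labels <- read_label_image(file.path(outdir, "labels.nii.gz"))
  id <- sim$subject_table$subject_id[1]
  metrics <- list(
    NDI = read_metric_image(file.path(outdir, paste0(id, "_NDI.nii.gz"))),
    ODI = read_metric_image(file.path(outdir, paste0(id, "_ODI.nii.gz"))))
  tf <- read_metric_image(file.path(outdir, paste0(id, "_tf.nii.gz")))
  tab <- summarise_subject(metrics, tf, labels,
                           roi_definitions()[c(3, 19), ],
                           subject_id = id, group = "control")
  ref <- sim$cohort[sim$cohort$subject_id == id, ]
  merged <- merge(tab, ref, by = c("roi", "metric"),
                  suffixes = c("_file", "_mem"))
  expect_equal(nrow(merged), 4L)
  expect_equal(merged$tissue_weighted_mean_file,
               merged$tissue_weighted_mean_mem, tolerance = 1e-12)
  expect_equal(merged$bias_file, merged$bias_mem, tolerance = 1e-12)
  # the cohort CSV on disk matches too
  disk <- read_roi_table(file.path(outdir, "cohort.csv"))
  expect_equal(disk$tissue_weighted_mean, sim$cohort$tissue_weighted_mean,
               tolerance = 1e-12)
  unlink(outdir, recursive = TRUE)
})

test_that("cohort configs round trip through YAML with validation", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "n_per_group: [4, 5]",
    "groups: [control, patient]",
    "seed: 12",
    "grid_dim: [14, 14, 14]",
    "n_voxel_range: [20, 60]",
    "metrics:",
    "  NDI:",
    "    mu: [0.6, 0.55]",
    "    kappa_pv: [0.0, -0.3]",
    "    kappa_other: [-0.1, -0.1]",
    "    sigma: 0.03"), path)
  cfg <- read_cohort_config(path)
  expect_s3_class(cfg, "cohort_config")
  expect_equal(cfg$n_per_group, c(4L, 5L))
  expect_equal(cfg$seed, 12L)
  expect_equal(names(cfg$metrics), "NDI")

  writeLines("bogus_field: 3", path)
  expect_error(read_cohort_config(path), "bogus_field")
  unlink(path)
})
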