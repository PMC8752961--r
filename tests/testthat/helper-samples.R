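# Shared fixture builders for the test suite. Everything is generated
# in code; no binary fixtures.

random_sample <- function(n = NULL) {
  if (is.null(n)) n <- sample(2:60, 1)
  roi_sample(runif(n), runif(n, min = 0.05, max = 1))
}

# brute-force elementwise oracle for the tissue-weighted mean
loop_weighted_mean <- function(m, t) {
  num <- 0; den <- 0
  for (i in seq_along(m)) {
    num <- num + t[i] * m[i]
    den <- den + t[i]
  }
  num / den
}

# hand-formula oracles for the statistical machinery, independent of
# stats::t.test
oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  dof <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, dof = dof, p = 2 * pt(-abs(t), dof))
}

oracle_one_sample <- function(x, mu0) {
  n <- length(x)
  s <- sqrt(sum((x - mean(x))^2) / (n - 1))
  t <- (mean(x) - mu0) / (s / sqrt(n))
  list(t = t, dof = n - 1, p = 2 * pt(-abs(t), n - 1))
}

oracle_cohens_ds <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  (mean(x) - mean(y)) /
    sqrt(((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2))
}

# small toy images for extraction tests: two ROIs in a 4x3x2 grid
toy_images <- function() {
  dims <- c(4, 3, 2)
  labels <- array(0L, dims)
  labels[1:8] <- 1L
  labels[9:20] <- 2L
  set.seed(11)
  metric <- array(runif(prod(dims), 0.3, 0.7), dims)
  tf <- array(runif(prod(dims), 0.4, 1), dims)
  list(metric = metric, tf = tf, labels = labels, dims = dims)
}

toy_roidefs <- function() {
  data.frame(label_id = c(1L, 2L, 3L),
             abbreviation = c("R1", "R2", "R3"),
             full_name = c("region one", "region two", "region three"),
             periventricular = c(TRUE, FALSE, TRUE),
             stringsAsFactors = FALSE)
}

# tiny cohort table built directly (no images) for group-analysis tests
toy_cohort <- function(n_a = 8, n_b = 8, rois = c("R1", "R2", "R3"),
                       seed = 5, bias_shift_b = 0,
                       metric = "NDI") {
  set.seed(seed)
  rows <- list()
  for (grp in c("A", "B")) {
    n <- if (grp == "A") n_a else n_b
    for (s in seq_len(n)) {
      for (k in seq_along(rois)) {
        tw <- rnorm(1, 0.55, 0.02)
        bias <- rnorm(1, 0, 0.005) +
          if (grp == "B") bias_shift_b else 0
        rows[[length(rows) + 1]] <- data.frame(
          subject_id = sprintf("%s%02d", grp, s), group = grp,
          roi = rois[k], metric = metric, n_voxels = 100L,
          mean_tf = rnorm(1, 0.8, 0.02),
          conventional_mean = tw + bias, tissue_weighted_mean = tw,
          bias = bias, covariance = -bias * 0.8, median = tw,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
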