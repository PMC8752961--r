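#' Read a scalar parameter map from NIfTI
#'
#' Thin wrapper around [RNifti::readNifti()] that checks the image is a
#' 3-D scalar volume as expected for a fitted parameter map (NDI, ODI,
#' FWF or TF).
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return an `RNifti` image (numeric 3-D array with xform attributes).
#' @export
read_metric_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("image not found: %s", path))
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop(sprintf("%s: expected a 3-D scalar volume, got %s dims",
                 path, length(dim(img))))
  img
}

#' Read an integer ROI label image from NIfTI
#'
#' Reads a parcellation volume and checks that it is integer-valued
#' (background voxels are 0). Label images must already be resampled to
#' the metric grid; no registration or interpolation is performed.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return an `RNifti` image whose data are non-negative integers.
#' @export
read_label_image <- function(path) {
  img <- read_metric_image(path)
  v <- as.vector(img)
  if (any(!is.finite(v)) || any(v < 0) || any(v != round(v)))
    stop(sprintf("%s: label image must contain non-negative integers", path))
  img
}

image_affine <- function(img) {
  if (inherits(img, "niftiImage") || !is.null(attr(img, ".nifti_image_ptr")))
    return(structure(RNifti::xform(img), class = "matrix"))
  a <- attr(img, "affine")
  if (!is.null(a)) return(a)
  diag(4)
}

#' Convert a free-water-fraction map to a tissue-fraction map
#'
#' Multi-compartment models report the free water (CSF) volume fraction
#' FWF per voxel; the tissue fraction is its complement, TF = 1 - FWF.
#' FWF values within `tol` outside `[0, 1]` are clipped (with a
#' warning) before conversion; values further out are an error, since
#' they indicate the image is not a volume-fraction map. Non-finite
#' voxels propagate as non-finite and are excluded downstream.
#'
#' @param fwf a 3-D FWF image (array or `RNifti` image).
#' @param tol tolerance outside `[0, 1]` within which values are
#'   clipped rather than rejected.
#' @return a TF image of the same class, geometry preserved.
#' @export
tf_from_fwf <- function(fwf, tol = 0.01) {
  v <- as.vector(fwf)
  finite <- is.finite(v)
  bad <- finite & (v < -tol | v > 1 + tol)
  if (any(bad))
    stop(sprintf(
      "%d FWF voxel(s) outside [-%g, 1 + %g]: not a volume-fraction map",
      sum(bad), tol, tol))
  clip <- finite & (v < 0 | v > 1)
  if (any(clip)) {
    warning(sprintf("clipped %d FWF voxel(s) to [0, 1]", sum(clip)))
    v[finite] <- pmin(pmax(v[finite], 0), 1)
  }
  tf <- fwf
  tf[] <- 1 - v
  tf
}

#' Check that images share one voxel grid
#'
#' All per-subject inputs (metric maps, TF map, label image) must live
#' on the same grid: identical array dimensions and element-wise equal
#' affines to within `tol`. Fails with a message naming the first
#' offending pair.
#'
#' @param images a named list of 3-D images (arrays or `RNifti`
#'   images); at least two.
#' @param tol absolute tolerance for affine element comparison.
#' @return invisibly `TRUE` on success.
#' @export
validate_grid <- function(images, tol = 1e-4) {
  if (!is.list(images) || length(images) < 2L)
    stop("'images' must be a list of at least two images")
  nms <- names(images)
  if (is.null(nms)) nms <- paste0("image", seq_along(images))
  ref_dim <- dim(images[[1]])
  ref_aff <- image_affine(images[[1]])
  for (k in seq_along(images)[-1]) {
    d <- dim(images[[k]])
    if (!identical(as.integer(ref_dim), as.integer(d)))
      stop(sprintf("grid mismatch between '%s' and '%s': dims %s vs %s",
                   nms[1], nms[k], paste(ref_dim, collapse = "x"),
                   paste(d, collapse = "x")))
    a <- image_affine(images[[k]])
    if (max(abs(ref_aff - a)) > tol)
      stop(sprintf(
        "affine mismatch between '%s' and '%s': max |difference| = %.3g",
        nms[1], nms[k], max(abs(ref_aff - a))))
  }
  invisible(TRUE)
}

#' Extract the ROI sample for one label
#'
#' Collects the metric and TF values at every voxel carrying the given
#' label, drops voxels where either value is non-finite, and returns an
#' [roi_sample()]. The voxel traversal order has no effect on any
#' downstream statistic.
#'
#' @param metric 3-D metric image (array or `RNifti` image).
#' @param tf 3-D tissue-fraction image on the same grid.
#' @param labels 3-D integer label image on the same grid.
#' @param label_id the integer label to extract.
#' @param metric_name optional tag stored in the sample.
#' @param roi_name optional ROI identifier stored in the sample
#'   (defaults to the label id).
#' @param clip_tf passed to [roi_sample()].
#' @return an [roi_sample()].
#' @export
extract_roi_sample <- function(metric, tf, labels, label_id,
                               metric_name = NA_character_,
                               roi_name = NULL, clip_tf = TRUE) {
  validate_grid(list(metric = metric, tf = tf, labels = labels))
  lab <- as.vector(labels)
  idx <- which(lab == label_id)
  if (length(idx) == 0L) {
    present <- sort(unique(lab[lab != 0]))
    stop(sprintf("label %s absent from label image; available labels: %s",
                 label_id, paste(present, collapse = ", ")))
  }
  roi_sample(as.vector(metric)[idx], as.vector(tf)[idx],
             metric_name = metric_name,
             roi_label = if (is.null(roi_name)) label_id else roi_name,
             clip_tf = clip_tf)
}

#' Bundled white-matter ROI definition table
#'
#' Loads the packaged table of 48 white-matter regions following the
#' JHU ICBM-DTI-81 integer labelling (label ids 1-48) with their
#' abbreviations, full names, and a periventricular flag (29
#' periventricular, 19 non-periventricular; a periventricular region
#' shares a border with the ventricles and is therefore prone to CSF
#' partial volume). Users with a different parcellation supply their
#' own table in the same format.
#'
#' @param path optional path to a user-supplied tab-separated table
#'   with columns `label_id`, `abbreviation`, `full_name`,
#'   `periventricular`; defaults to the packaged JHU table.
#' @return a data frame with those four columns.
#' @export
roi_definitions <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "jhu_roi_definitions.tsv",
                        package = "twroi", mustWork = TRUE)
  defs <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("label_id", "abbreviation", "full_name", "periventricular")
  missing <- setdiff(required, names(defs))
  if (length(missing))
    stop(sprintf("ROI definition table lacks column(s): %s",
                 paste(missing, collapse = ", ")))
  if (anyDuplicated(defs$abbreviation))
    stop("ROI abbreviations must be unique")
  if (anyDuplicated(defs$label_id))
    stop("ROI label ids must be unique")
  defs$periventricular <- as.logical(defs$periventricular)
  defs
}

#' Per-subject ROI summary table
#'
#' Computes both ROI means and all companion statistics for every
#' (ROI x metric) combination in one subject: for each region defined
#' in `roidefs` and present in the label image, and each supplied
#' metric map, the conventional mean, tissue-weighted mean, bias, mean
#' TF, covariance, median and voxel count. Regions listed in `roidefs`
#' but absent from the label image are reported in the `missing_rois`
#' attribute (with a warning), not silently dropped.
#'
#' @param metrics named list of 3-D metric images (names become the
#'   `metric` column, e.g. `list(NDI = ..., ODI = ...)`).
#' @param tf 3-D tissue-fraction image on the same grid.
#' @param labels 3-D integer label image on the same grid.
#' @param roidefs ROI definition table from [roi_definitions()].
#' @param subject_id subject identifier written into every row.
#' @param group optional group label written into every row.
#' @param clip_tf passed to [roi_sample()].
#' @return a data frame with columns `subject_id`, `group`, `roi`,
#'   `metric`, `n_voxels`, `mean_tf`, `conventional_mean`,
#'   `tissue_weighted_mean`, `bias`, `covariance`, `median`; attribute
#'   `missing_rois` lists defined regions absent from the label image.
#' @export
summarise_subject <- function(metrics, tf, labels, roidefs = roi_definitions(),
                              subject_id = "subject", group = NA_character_,
                              clip_tf = TRUE) {
  if (!is.list(metrics) || is.null(names(metrics)) ||
      any(!nzchar(names(metrics))))
    stop("'metrics' must be a named list of metric images")
  validate_grid(c(metrics, list(tf = tf, labels = labels)))
  lab <- as.vector(labels)
  present <- roidefs$label_id %in% unique(lab)
  missing_rois <- roidefs$abbreviation[!present]
  if (length(missing_rois))
    warning(sprintf("%d ROI(s) absent from label image: %s",
                    length(missing_rois),
                    paste(missing_rois, collapse = ", ")))
  if (!any(present)) {
    out <- empty_subject_table()
    attr(out, "missing_rois") <- missing_rois
    return(out)
  }
  defs <- roidefs[present, , drop = FALSE]
  rows <- vector("list", nrow(defs) * length(metrics))
  k <- 0L
  for (j in seq_len(nrow(defs))) {
    for (metric_name in names(metrics)) {
      s <- extract_roi_sample(metrics[[metric_name]], tf, labels,
                              defs$label_id[j], metric_name = metric_name,
                              roi_name = defs$abbreviation[j],
                              clip_tf = clip_tf)
      k <- k + 1L
      rows[[k]] <- as.data.frame(summarise_roi(s))
    }
  }
  out <- do.call(rbind, rows)
  out <- cbind(subject_id = subject_id, group = group, out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "missing_rois") <- missing_rois
  out
}

empty_subject_table <- function() {
  data.frame(subject_id = character(), group = character(),
             roi = character(), metric = character(),
             n_voxels = integer(), mean_tf = numeric(),
             conventional_mean = numeric(), tissue_weighted_mean = numeric(),
             bias = numeric(), covariance = numeric(), median = numeric(),
             stringsAsFactors = FALSE)
}

subject_table_columns <- c(
  "subject_id", "group", "roi", "metric", "n_voxels", "mean_tf",
  "conventional_mean", "tissue_weighted_mean", "bias", "covariance",
  "median")

#' Write / read per-subject or cohort ROI tables
#'
#' Fixed-column CSV round trip for the tables produced by
#' [summarise_subject()] (and concatenations of them forming a cohort
#' table). Full double precision is preserved.
#'
#' @param table a subject or cohort ROI table.
#' @param path output CSV path.
#' @return `write_roi_table` invisibly returns `path`;
#'   `read_roi_table` returns the data frame.
#' @export
write_roi_table <- function(table, path) {
  missing <- setdiff(subject_table_columns, names(table))
  if (length(missing))
    stop(sprintf("table lacks column(s): %s", paste(missing, collapse = ", ")))
  utils::write.csv(table[, subject_table_columns], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_roi_table
#' @export
read_roi_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("table not found: %s", path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(subject_id = "character",
                                        group = "character",
                                        roi = "character",
                                        metric = "character"))
  missing <- setdiff(subject_table_columns, names(tab))
  if (length(missing))
    stop(sprintf("%s lacks column(s): %s", path,
                 paste(missing, collapse = ", ")))
  tab
}

#' Voxels contained in a reference volume at a given resolution
#'
#' Number of isotropic voxels of edge `voxel_mm` that fit in a volume
#' of `volume_mm3` cubic millimetres. Useful for comparing how many
#' voxels ROIs contain across acquisitions: 2 mm isotropic data packs
#' 125 voxels per 1000 mm^3 where 2.5 mm data packs 64, so the
#' higher-resolution image has roughly twice as many voxels per region
#' and proportionally fewer voxels straddling a CSF border.
#'
#' @param voxel_mm isotropic voxel edge length in millimetres.
#' @param volume_mm3 reference volume in cubic millimetres.
#' @return voxels per reference volume (a real number).
#' @examples
#' voxels_per_volume(2)    # 125
#' voxels_per_volume(2.5)  # 64
#' @export
voxels_per_volume <- function(voxel_mm, volume_mm3 = 1000) {
  if (voxel_mm <= 0) stop("'voxel_mm' must be positive")
  volume_mm3 / voxel_mm^3
}
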