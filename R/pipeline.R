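# Two-stage patient-level inference: segmentation -> patch extraction from
# the predicted tumor -> patch-wise genotype prediction -> crop-and-stitch
# probability map -> P_mean and majority vote.

#' Segment one patient
#'
#' Runs the segmentation network on the full image and takes the per-pixel
#' argmax of the 2-class probability map; an exact 0.5/0.5 tie goes to
#' background. Optional largest-component post-filtering is off by default.
#'
#' @param volume A [cest_volume()].
#' @param model A `cest_network` or `cest_fit` trained for segmentation.
#' @param largest_component_only Keep only the largest connected component.
#' @return Logical `H x W` mask. An all-background prediction is returned
#'   with a warning (the genotype stage then skips the patient).
#' @export
segment_patient <- function(volume, model, largest_component_only = FALSE) {
  prob <- predict(model, volume)
  mask <- prob[, , 2] > 0.5
  if (!any(mask)) {
    warning("segmentation predicted an empty mask", call. = FALSE)
    return(mask)
  }
  if (largest_component_only) mask <- largest_component(mask)
  mask
}

#' Restrict a probability map to a region of interest
#'
#' @param map A `prob_map` from [aggregate_patches()].
#' @param roi Logical `H x W` mask; must be covered by valid pixels.
#' @return The map with its `roi` field set.
#' @export
restrict_roi <- function(map, roi) {
  stopifnot(inherits(map, "prob_map"))
  roi <- roi & map$valid
  map$roi <- roi
  map
}

#' Patient-level mean class probability
#'
#' The arithmetic mean of the per-pixel predicted probability of class
#' `class` over the N pixels of the ROI.
#'
#' @param map A `prob_map` with a non-empty ROI (or a plain probability
#'   array plus `roi`).
#' @param class Class index (1-based; class 2 = positive/mutant analogue).
#' @param roi Optional ROI override.
#' @return Scalar in `[0, 1]`.
#' @export
p_mean <- function(map, class = 2L, roi = NULL) {
  if (inherits(map, "prob_map")) {
    if (is.null(roi)) roi <- map$roi
    data <- map$data
  } else data <- map
  if (is.null(roi) || !any(roi)) {
    stop("P_mean is undefined on an empty ROI", call. = FALSE)
  }
  plane <- data[, , class]
  mean(plane[roi])
}

#' Patient-level majority vote
#'
#' Each ROI pixel votes for the positive class when its probability is at
#' least `threshold`; the patient is labelled 1 when the voting fraction
#' strictly exceeds one half (an exact half ties to 0).
#'
#' @param map A `prob_map` with ROI (or array).
#' @param threshold Per-pixel vote threshold (default 0.5).
#' @param roi Optional ROI override.
#' @return Integer label 0 or 1.
#' @export
majority_vote <- function(map, threshold = 0.5, roi = NULL) {
  if (inherits(map, "prob_map")) {
    if (is.null(roi)) roi <- map$roi
    data <- map$data
  } else data <- map
  if (is.null(roi) || !any(roi)) {
    stop("majority vote is undefined on an empty ROI", call. = FALSE)
  }
  votes <- data[, , 2][roi] >= threshold
  as.integer(mean(votes) > 0.5)
}

#' Patch-wise genotype prediction for one patient
#'
#' Builds the 48/12 shift-window grid over the (predicted or true) tumor
#' mask, runs the genotype network on every patch, stitches the patch
#' probabilities with crop = stride, restricts the map to the mask, and
#' aggregates to `P_mean` and the majority-vote label.
#'
#' @param volume A [cest_volume()].
#' @param mask Logical tumor mask (typically from [segment_patient()]).
#' @param model Genotype `cest_network` or `cest_fit`.
#' @param patch_size,patch_stride Patch geometry (defaults 48 / 12).
#' @param crop Aggregation crop (default = stride).
#' @return Object of class `patient_prediction`: list(p_mean (per class),
#'   vote, n_roi, map, grid, status). When the mask is empty, `status` is
#'   `"empty_mask"` and the probability fields are NA.
#' @export
predict_genotype_patient <- function(volume, mask, model, patch_size = 48L,
                                     patch_stride = 12L,
                                     crop = patch_stride) {
  if (!any(mask)) {
    return(structure(list(p_mean = c(NA_real_, NA_real_), vote = NA_integer_,
                          n_roi = 0L, map = NULL, grid = NULL,
                          status = "empty_mask"),
                     class = "patient_prediction"))
  }
  net <- if (inherits(model, "cest_fit")) model$model else model
  grid <- build_grid(mask, dim(mask), patch_size, patch_stride)
  ps <- extract_patches(volume, grid)
  preds <- lapply(ps$patches, function(p) predict(net, p))
  map <- aggregate_patches(preds, grid, crop = crop)
  map <- restrict_roi(map, mask)
  pm <- vapply(seq_len(dim(map$data)[3]), function(k) p_mean(map, k),
               numeric(1))
  structure(list(p_mean = pm, vote = majority_vote(map), n_roi = sum(map$roi),
                 map = map, grid = grid, status = "ok"),
            class = "patient_prediction")
}

#' @export
print.patient_prediction <- function(x, ...) {
  if (x$status != "ok") {
    cat(sprintf("<patient_prediction> status = %s\n", x$status))
  } else {
    cat(sprintf(
      "<patient_prediction> vote = %d, P_mean(class 1) = %.4f over %d ROI px\n",
      x$vote, x$p_mean[2], x$n_roi))
  }
  invisible(x)
}

#' Run the full two-stage pipeline over a cohort
#'
#' Segmentation -> genotype prediction per patient. Patients whose predicted
#' mask is empty are excluded from genotype metrics and tallied.
#'
#' @param records List of [patient_record()]s.
#' @param seg_model Segmentation fit/network (NULL to use ground-truth
#'   masks).
#' @param geno_model Genotype fit/network.
#' @param patch_size,patch_stride Patch geometry.
#' @return data.frame with one row per patient: id, truth label, n_roi,
#'   p_mean (positive class), vote, dice (vs. true mask; NA if no
#'   segmentation model), status.
#' @export
run_pipeline <- function(records, seg_model, geno_model, patch_size = 48L,
                         patch_stride = 12L) {
  rows <- lapply(records, function(r) {
    if (is.null(seg_model)) {
      mask <- r$mask
      dsc <- NA_real_
    } else {
      mask <- suppressWarnings(segment_patient(r$volume, seg_model))
      dsc <- dice(mask, r$mask)
    }
    if (!any(mask)) {
      return(data.frame(patient_id = r$patient_id, truth = r$genotype,
                        n_roi = 0L, p_mean = NA_real_, vote = NA_integer_,
                        dice = dsc, status = "empty_mask",
                        stringsAsFactors = FALSE))
    }
    pp <- predict_genotype_patient(r$volume, mask, geno_model,
                                   patch_size, patch_stride)
    data.frame(patient_id = r$patient_id, truth = r$genotype,
               n_roi = pp$n_roi, p_mean = pp$p_mean[2], vote = pp$vote,
               dice = dsc, status = pp$status, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
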