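# Model visualisation: Grad-CAM heatmaps, integrated-gradients
# attributions, cohort-level mean saliency maps with a gradient-magnitude
# distribution summary, and the discordant-case selector.

#' Resize an array by linear interpolation
#'
#' Half-pixel-centre resampling of a 2D/3D array to new extents; used for
#' upsampling Grad-CAM maps and for preprocessing resizes.
#'
#' @param img 2D or 3D array.
#' @param new_dims Target extents.
#' @param order `"linear"` or `"nearest"`.
#' @return Array with dimensions `new_dims`.
#' @export
resize_array <- function(img, new_dims, order = "linear") {
  d <- check_image(img)
  if (length(new_dims) != length(d)) {
    abort("`new_dims` must match the input dimensionality.")
  }
  out <- coord_grid(new_dims)
  in_coords <- out
  for (k in seq_along(d)) {
    in_coords[, k] <- (out[, k] - 0.5) * d[k] / new_dims[k] + 0.5
    in_coords[, k] <- pmin(pmax(in_coords[, k], 1), d[k])
  }
  array(interp_at(img, in_coords, order = order), new_dims)
}

#' Grad-CAM attribution map
#'
#' Gradient-weighted class activation map at the adapter's last
#' convolutional block: per-channel weights are the global-average-pooled
#' gradients of the target score, the weighted activation sum is rectified,
#' upsampled to the input's spatial shape, and rescaled to \[0, 1\].
#'
#' @param adapter An adapter exposing activations and gradients at a
#'   convolutional layer (the reference CNN does; see details).
#' @param image A single 2D/3D array.
#' @param target Output index or name to explain.
#' @return Attribution array with the input's spatial shape, values in
#'   \[0, 1\]; attribute `"target"` records the explained output, and
#'   `"scale"` the pre-normalisation maximum.
#' @details Custom adapters participate by providing a
#'   `gradcam_ingredients()` method returning `activations` and `gradients`
#'   matrices (pixels x channels) plus the `spatial_shape` of that layer.
#' @export
gradcam <- function(adapter, image, target = 1) {
  ing <- tryCatch(gradcam_ingredients(adapter, image, target),
                  error = function(e) {
                    abort(paste("Adapter does not expose convolutional",
                                "activations/gradients for Grad-CAM."))
                  })
  A <- as.matrix(ing$activations)
  G <- as.matrix(ing$gradients)
  w <- colMeans(G)
  cam <- pmax(as.vector(A %*% w), 0)
  cam_arr <- array(cam, ing$spatial_shape)
  up <- resize_array(cam_arr, dim(image))
  mx <- max(up)
  if (mx > 0) up <- up / mx
  attr(up, "target") <- target
  attr(up, "scale") <- mx
  up
}

#' Integrated-gradients attribution map
#'
#' Midpoint Riemann approximation of the path integral of the input
#' gradients from `baseline` to `image`:
#' `(x - x0) * mean_i grad(score)(x0 + (i - 1/2)/steps * (x - x0))`. The
#' completeness property (attributions summing to the score difference)
#' holds in the limit of many steps.
#'
#' @param adapter A model adapter implementing [input_gradients()].
#' @param image A single 2D/3D array.
#' @param target Output index or name.
#' @param steps Number of integration steps (>= 2, default 50).
#' @param baseline Baseline image (default all zeros).
#' @return Attribution array shaped like the input, with attribute
#'   `"target"`.
#' @export
integrated_gradients <- function(adapter, image, target = 1, steps = 50,
                                 baseline = NULL) {
  if (steps < 2) abort("`steps` must be >= 2.")
  d <- check_image(image)
  baseline <- baseline %||% array(0, d)
  if (!identical(dim(baseline), dim(image))) {
    abort("`baseline` must match the image dimensions.")
  }
  diff_img <- image - baseline
  alphas <- (seq_len(steps) - 0.5) / steps
  path <- lapply(alphas, function(a) baseline + a * diff_img)
  grads <- input_gradients(adapter, path, target = target)
  avg <- Reduce(`+`, grads) / steps
  out <- diff_img * avg
  attr(out, "target") <- target
  out
}

#' Cohort-level mean saliency map
#'
#' Pixelwise mean of per-image absolute integrated-gradients attributions
#' for a set of images, with a density-histogram summary of the per-pixel
#' mean magnitudes (the "gradient distribution" panel).
#'
#' @inheritParams integrated_gradients
#' @param images List of arrays (>= 1).
#' @param n_bins Histogram bins for the magnitude distribution.
#' @return List with `map` (mean |IG| array) and `distribution` (tibble
#'   `mid`, `density`, `width`; densities integrate to 1).
#' @export
mean_saliency <- function(adapter, images, target = 1, steps = 50,
                          n_bins = 30) {
  images <- as_image_list(images)
  if (length(images) == 0) abort("Need at least one image.")
  acc <- NULL
  for (im in images) {
    ig <- abs(integrated_gradients(adapter, im, target = target,
                                   steps = steps))
    acc <- if (is.null(acc)) ig else acc + ig
  }
  map <- acc / length(images)
  h <- graphics::hist(as.vector(map), breaks = n_bins, plot = FALSE)
  list(map = map,
       distribution = tibble::tibble(mid = h$mids, density = h$density,
                                     width = diff(h$breaks)))
}

demo_correct <- function(pred_scores, truth_levels) {
  pred_scores <- as.matrix(pred_scores)
  if (ncol(pred_scores) == 1) {
    pred <- as.integer(pred_scores[, 1] >= 0.5)
    pred == as.integer(truth_levels)
  } else {
    lv <- colnames(pred_scores)
    lv[max.col(pred_scores, ties.method = "first")] ==
      as.character(truth_levels)
  }
}

#' Select discordant cases between an original and a debiased model
#'
#' Returns (sorted) the sample ids where the original model identified the
#' demographic attribute correctly, the proposed model did not, and both
#' models' label predictions are correct at the given thresholds — the
#' cases whose saliency is most informative about removed shortcuts.
#' Multi-class demographic correctness is argmax agreement; binary is
#' thresholded at 0.5.
#'
#' @param labels_original,labels_proposed [score_set()]s of label scores
#'   (with truths) from the two models, covering identical samples.
#' @param demo_original,demo_proposed Demographic score matrices
#'   (samples x classes, class-named columns; or a single column for a
#'   binary attribute), rows aligned with the score sets' samples.
#' @param demo_truth Per-sample true demographic class.
#' @param thresholds Named per-label thresholds (see
#'   [select_thresholds()]).
#' @return Character vector of sample ids, sorted.
#' @export
select_discordant_cases <- function(labels_original, labels_proposed,
                                    demo_original, demo_proposed,
                                    demo_truth, thresholds = 0.5) {
  ids <- unique(labels_original$sample_id)
  if (!identical(sort(ids), sort(unique(labels_proposed$sample_id)))) {
    abort("The two score sets must cover identical samples.")
  }
  if (nrow(as.matrix(demo_original)) != length(ids) ||
      nrow(as.matrix(demo_proposed)) != length(ids)) {
    abort("Demographic predictions must have one row per sample.")
  }
  labels <- ss_labels(labels_original)
  thresholds <- resolve_thresholds(thresholds, labels)
  label_correct <- function(ss) {
    ss |>
      dplyr::mutate(ok = (.data$score >= thresholds[.data$label]) ==
                      (.data$truth == 1)) |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::summarise(ok = all(.data$ok), .groups = "drop")
  }
  lo <- label_correct(labels_original)
  lp <- label_correct(labels_proposed)
  ok_orig <- setNames(lo$ok, lo$sample_id)[ids]
  ok_prop <- setNames(lp$ok, lp$sample_id)[ids]
  d_orig <- demo_correct(demo_original, demo_truth)
  d_prop <- demo_correct(demo_proposed, demo_truth)
  sort(ids[d_orig & !d_prop & ok_orig & ok_prop])
}
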