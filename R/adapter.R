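# ModelAdapter contract and the reference small CNN.
#
# Any trainable classifier can be plugged into the harness by implementing
# the four generics below (plus freeze_backbone()). The package ships a
# desk-scale reference model: a small convolutional network (four 3^nd conv
# blocks with ReLU and 2x average pooling, global average pooling, linear
# head) whose forward/backward passes run in compiled code and train on a
# CPU in minutes at 64 x 64.

#' Predict per-output probability scores
#'
#' @param adapter A model adapter (e.g. [reference_small_cnn()]).
#' @param images List of image arrays (or an `image_cohort`).
#' @param ... Method-specific arguments.
#' @return Numeric matrix (samples x outputs) of scores in \[0, 1\].
#' @export
predict_scores <- function(adapter, images, ...) UseMethod("predict_scores")

#' Extract penultimate-layer feature vectors
#'
#' @inheritParams predict_scores
#' @return Numeric matrix (samples x feature dimension).
#' @export
penultimate_features <- function(adapter, images, ...) {
  UseMethod("penultimate_features")
}

#' Gradients of a target output score with respect to the input pixels
#'
#' @inheritParams predict_scores
#' @param target Index (or name) of the output whose score is differentiated.
#' @return List of arrays, one per image, each shaped like its input.
#' @export
input_gradients <- function(adapter, images, target = 1, ...) {
  UseMethod("input_gradients")
}

#' Freeze the feature extractor of an adapter
#'
#' Returns an adapter whose backbone (everything below the final linear
#' layer) is immutable: subsequent fitting updates only the head, so
#' [penultimate_features()] are unchanged by further training.
#'
#' @param adapter A model adapter.
#' @return The frozen adapter.
#' @export
freeze_backbone <- function(adapter) UseMethod("freeze_backbone")

default_channels <- function(nd) if (nd == 2) c(8L, 16L, 32L, 32L) else
  c(4L, 8L, 16L, 16L)

init_cnn_weights <- function(nd, channels, n_outputs) {
  ntaps <- 3^nd
  w <- list()
  cin <- 1L
  for (b in seq_along(channels)) {
    fan_in <- ntaps * cin
    w[[2 * b - 1]] <- matrix(rnorm(fan_in * channels[b], sd = sqrt(2 / fan_in)),
                             fan_in, channels[b])
    w[[2 * b]] <- matrix(0, 1, channels[b])
    cin <- channels[b]
  }
  Fdim <- channels[length(channels)]
  w[[2 * length(channels) + 1]] <- matrix(rnorm(Fdim * n_outputs,
                                                sd = sqrt(1 / Fdim)),
                                          Fdim, n_outputs)
  w[[2 * length(channels) + 2]] <- matrix(0, 1, n_outputs)
  w
}

#' Reference small convolutional classifier
#'
#' A compact convolutional network satisfying the full ModelAdapter
#' contract for 2D images or 3D volumes: four convolution blocks (3^nd
#' kernels, ReLU, 2x average pooling), global average pooling (the
#' penultimate features) and a linear head with a softmax (mutually
#' exclusive classes) or sigmoid (independent binary outputs) activation.
#' Image extents must be divisible by 16. Weights are initialised from the
#' current RNG state; fitting re-initialises them from the training seed
#' unless the backbone is frozen.
#'
#' @param image_shape 2D `c(H, W)` or 3D `c(D1, D2, D3)` extents.
#' @param n_outputs Number of output nodes.
#' @param head `"softmax"` or `"sigmoid"`.
#' @param channels Optional per-block channel counts (default
#'   `c(8, 16, 32, 32)` in 2D, `c(4, 8, 16, 16)` in 3D).
#' @param output_names Optional names for the outputs.
#' @return An object of class `small_cnn`.
#' @examples
#' m <- reference_small_cnn(c(32, 32), 3, head = "softmax")
#' x <- list(matrix(runif(32 * 32), 32, 32))
#' rowSums(predict_scores(m, x))  # sums to 1
#' @export
reference_small_cnn <- function(image_shape, n_outputs,
                                head = c("softmax", "sigmoid"),
                                channels = NULL, output_names = NULL) {
  head <- match.arg(head)
  nd <- length(image_shape)
  if (!nd %in% c(2, 3)) abort("`image_shape` must be 2D or 3D.")
  channels <- as.integer(channels %||% default_channels(nd))
  if (any(image_shape %% 2^length(channels) != 0)) {
    abort(sprintf("`image_shape` extents must be divisible by %d (%d pooling halvings).",
                  2^length(channels), length(channels)))
  }
  structure(
    list(image_shape = as.integer(image_shape), nd = nd,
         channels = channels, n_outputs = as.integer(n_outputs),
         head = head,
         output_names = output_names %||% paste0("out", seq_len(n_outputs)),
         weights = init_cnn_weights(nd, channels, n_outputs),
         frozen = FALSE, fitted = FALSE, log = NULL),
    class = "small_cnn")
}

#' @export
print.small_cnn <- function(x, ...) {
  cat(sprintf("<small_cnn> %s -> %d blocks (%s) -> %d-dim features -> %s(%d)%s%s\n",
              paste(x$image_shape, collapse = "x"), length(x$channels),
              paste(x$channels, collapse = ","),
              x$channels[length(x$channels)], x$head, x$n_outputs,
              if (x$fitted) " [fitted]" else "",
              if (x$frozen) " [frozen backbone]" else ""))
  invisible(x)
}

as_image_list <- function(images) {
  if (inherits(images, "image_cohort")) return(images$images)
  if (is.array(images) && !is.list(images)) return(list(images))
  images
}

images_to_matrix <- function(images, shape) {
  npix <- prod(shape)
  vapply(images, function(im) {
    if (!identical(dim(im), as.integer(shape)) &&
        !identical(as.integer(dim(im)), as.integer(shape))) {
      abort("Image dimensions do not match the adapter's image_shape.")
    }
    as.vector(im)
  }, numeric(npix))
}

cnn_pass <- function(adapter, X, ...) {
  cnn_pass_cpp(adapter$weights, X, adapter$image_shape, adapter$channels,
               adapter$head, ...)
}

chunk_indices <- function(n, size) split(seq_len(n), ceiling(seq_len(n) / size))

#' @rdname predict_scores
#' @param batch_size Prediction chunk size.
#' @export
predict_scores.small_cnn <- function(adapter, images, batch_size = 256, ...) {
  images <- as_image_list(images)
  out <- matrix(NA_real_, length(images), adapter$n_outputs)
  for (idx in chunk_indices(length(images), batch_size)) {
    X <- images_to_matrix(images[idx], adapter$image_shape)
    out[idx, ] <- cnn_pass(adapter, X)$scores
  }
  colnames(out) <- adapter$output_names
  out
}

#' @rdname penultimate_features
#' @param batch_size Prediction chunk size.
#' @export
penultimate_features.small_cnn <- function(adapter, images,
                                           batch_size = 256, ...) {
  images <- as_image_list(images)
  Fdim <- adapter$channels[length(adapter$channels)]
  out <- matrix(NA_real_, length(images), Fdim)
  for (idx in chunk_indices(length(images), batch_size)) {
    X <- images_to_matrix(images[idx], adapter$image_shape)
    out[idx, ] <- cnn_pass(adapter, X)$features
  }
  out
}

#' @rdname input_gradients
#' @param batch_size Prediction chunk size.
#' @export
input_gradients.small_cnn <- function(adapter, images, target = 1,
                                      batch_size = 128, ...) {
  images <- as_image_list(images)
  if (is.character(target)) target <- match(target, adapter$output_names)
  K <- adapter$n_outputs
  grads <- vector("list", length(images))
  for (idx in chunk_indices(length(images), batch_size)) {
    X <- images_to_matrix(images[idx], adapter$image_shape)
    sc <- cnn_pass(adapter, X)$scores
    # d score_target / d logits (head Jacobian row)
    dlg <- matrix(0, length(idx), K)
    if (adapter$head == "sigmoid") {
      dlg[, target] <- sc[, target] * (1 - sc[, target])
    } else {
      for (k in seq_len(K)) {
        dlg[, k] <- sc[, target] * ((k == target) - sc[, k])
      }
    }
    res <- cnn_pass(adapter, X, d_logits_in = dlg, want_input_grad = TRUE)
    for (j in seq_along(idx)) {
      grads[[idx[j]]] <- array(res$d_input[, j], adapter$image_shape)
    }
  }
  grads
}

#' @export
freeze_backbone.small_cnn <- function(adapter) {
  adapter$frozen <- TRUE
  adapter
}

#' Grad-CAM ingredients of an adapter
#'
#' Activations and target-score gradients at a convolutional layer (the
#' reference CNN uses its last block, post-ReLU, pre-pool). Custom adapters
#' implement this method to participate in [gradcam()].
#'
#' @inheritParams input_gradients
#' @param image A single image array.
#' @return List with `activations` and `gradients` (pixels x channels
#'   matrices) and `spatial_shape`.
#' @export
gradcam_ingredients <- function(adapter, image, target = 1, ...) {
  UseMethod("gradcam_ingredients")
}

#' @export
gradcam_ingredients.small_cnn <- function(adapter, image, target = 1, ...) {
  if (is.character(target)) target <- match(target, adapter$output_names)
  X <- images_to_matrix(list(image), adapter$image_shape)
  sc <- cnn_pass(adapter, X)$scores
  K <- adapter$n_outputs
  dlg <- matrix(0, 1, K)
  if (adapter$head == "sigmoid") {
    dlg[, target] <- sc[, target] * (1 - sc[, target])
  } else {
    for (k in seq_len(K)) dlg[, k] <- sc[, target] * ((k == target) - sc[, k])
  }
  res <- cnn_pass(adapter, X, d_logits_in = dlg, want_conv = TRUE,
                  want_conv_grad = TRUE)
  conv_shape <- adapter$image_shape %/% 2^(length(adapter$channels) - 1)
  list(activations = res$conv_act[, , 1],
       gradients = res$conv_grad[, , 1],
       spatial_shape = conv_shape)
}

#' @export
glance.small_cnn <- function(x, ...) {
  lg <- x$log
  if (is.null(lg)) return(tibble::tibble(fitted = FALSE))
  tibble::tibble(fitted = TRUE, epochs_run = nrow(lg),
                 best_epoch = x$best_epoch,
                 best_val_loss = min(lg$val_loss))
}

#' @export
tidy.small_cnn <- function(x, ...) {
  x$log %||% tibble::tibble()
}
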