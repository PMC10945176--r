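# Stochastic distortion family: rotation, shear, scaling and fisheye warps
# for 2D images and 3D volumes, plus the augmentation policy sampler and the
# test-time-augmentation ensemble.
#
# All operators use inverse mapping with linear (bilinear/trilinear)
# interpolation for intensities and nearest-neighbour for masks, preserve the
# input shape, fill out-of-bounds regions with `fill`, and clamp intensities
# to [0, 1]. Coordinates are (row, column[, slice]), 1-based; the rotation /
# shear / scale anchor is the image centre (d + 1) / 2.

# integer coordinate grid in column-major (R array) order
coord_grid <- function(d) {
  g <- as.matrix(do.call(expand.grid, lapply(d, seq_len)))
  dimnames(g) <- NULL
  storage.mode(g) <- "double"
  g
}

# sample `img` at fractional 1-based `coords` (npix x nd); out-of-bounds -> fill
interp_at <- function(img, coords, order = "linear", fill = 0) {
  d <- dim(img)
  nd <- length(d)
  n <- nrow(coords)
  if (order == "nearest") {
    idx <- round(coords)
    valid <- rep(TRUE, n)
    for (k in seq_len(nd)) valid <- valid & idx[, k] >= 1 & idx[, k] <= d[k]
    out <- rep(fill, n)
    if (any(valid)) {
      lin <- idx[valid, 1]
      mult <- 1
      for (k in seq_len(nd)[-1]) {
        mult <- mult * d[k - 1]
        lin <- lin + (idx[valid, k] - 1) * mult
      }
      out[valid] <- img[lin]
    }
    return(out)
  }
  lo <- floor(coords)
  fr <- coords - lo
  out <- numeric(n)
  for (corner in 0:(2^nd - 1)) {
    w <- rep(1, n)
    idx <- lo
    for (k in seq_len(nd)) {
      delta <- bitwAnd(bitwShiftR(corner, k - 1), 1L)
      if (delta == 1L) {
        idx[, k] <- lo[, k] + 1
        w <- w * fr[, k]
      } else {
        w <- w * (1 - fr[, k])
      }
    }
    valid <- rep(TRUE, n)
    for (k in seq_len(nd)) valid <- valid & idx[, k] >= 1 & idx[, k] <= d[k]
    v <- rep(fill, n)
    if (any(valid)) {
      lin <- idx[valid, 1]
      mult <- 1
      for (k in seq_len(nd)[-1]) {
        mult <- mult * d[k - 1]
        lin <- lin + (idx[valid, k] - 1) * mult
      }
      v[valid] <- img[lin]
    }
    out <- out + w * v
  }
  out
}

warp_by_coords <- function(img, in_coords, order, fill, clamp = TRUE) {
  vals <- interp_at(img, in_coords, order = order, fill = fill)
  if (clamp) vals <- pmin(pmax(vals, 0), 1)
  array(vals, dim(img))
}

check_image <- function(img, arg = "image") {
  if (!is.array(img) || !(length(dim(img)) %in% c(2L, 3L))) {
    abort(sprintf("`%s` must be a 2D or 3D numeric array.", arg))
  }
  invisible(dim(img))
}

#' Rotate an image about its centre
#'
#' Rotates the image content by `angle` degrees about the image centre; for 3D
#' volumes the rotation acts in the axial (row-column) plane. The output keeps
#' the input shape; regions rotated in from outside the frame take `fill`.
#'
#' @param img 2D or 3D numeric array with intensities in \[0, 1\].
#' @param angle Rotation angle in degrees (finite).
#' @param order Interpolation: `"linear"` (images) or `"nearest"` (masks).
#' @param fill Value for out-of-bounds samples.
#' @return Array with the same dimensions as `img`.
#' @examples
#' x <- matrix(runif(16 * 16), 16, 16)
#' stopifnot(identical(img_rotate(x, 0), x))
#' @export
img_rotate <- function(img, angle, order = "linear", fill = 0) {
  d <- check_image(img)
  if (!is.finite(angle)) abort("`angle` must be finite.")
  nd <- length(d)
  ctr <- (d + 1) / 2
  th <- angle * pi / 180
  out <- coord_grid(d)
  u <- out[, 2] - ctr[2]  # column offset
  v <- out[, 1] - ctr[1]  # row offset
  in_coords <- out
  in_coords[, 1] <- -sin(th) * u + cos(th) * v + ctr[1]
  in_coords[, 2] <- cos(th) * u + sin(th) * v + ctr[2]
  warp_by_coords(img, in_coords, order, fill)
}

#' Shear an image horizontally about its centre
#'
#' Centre-anchored horizontal shear: column positions are displaced in
#' proportion to the row offset from centre, with displacement factor
#' `tan(radian)`. The centre row is fixed. For 3D volumes the shear acts in
#' the axial plane.
#'
#' @inheritParams img_rotate
#' @param radian Shear angle in radians, `|radian| < pi/2`.
#' @return Array with the same dimensions as `img`.
#' @export
img_shear <- function(img, radian, order = "linear", fill = 0) {
  d <- check_image(img)
  if (!is.finite(radian) || abs(radian) >= pi / 2) {
    abort("`radian` must satisfy |radian| < pi/2.")
  }
  ctr <- (d + 1) / 2
  t_ <- tan(radian)
  out <- coord_grid(d)
  in_coords <- out
  in_coords[, 2] <- out[, 2] - t_ * (out[, 1] - ctr[1])
  warp_by_coords(img, in_coords, order, fill)
}

#' Scale (shrink) an image about its centre
#'
#' Shrinks the content by `factor` (in (0, 1\]) about the image centre and
#' pads the surround with `fill`, keeping the original shape.
#'
#' @inheritParams img_rotate
#' @param factor Scale factor in (0, 1\].
#' @return Array with the same dimensions as `img`.
#' @export
img_scale <- function(img, factor, order = "linear", fill = 0) {
  d <- check_image(img)
  if (!is.finite(factor) || factor <= 0 || factor > 1) {
    abort("`factor` must lie in (0, 1].")
  }
  ctr <- (d + 1) / 2
  out <- coord_grid(d)
  in_coords <- sweep(sweep(out, 2, ctr), 2, rep(factor, length(d)), "/")
  in_coords <- sweep(in_coords, 2, ctr, "+")
  warp_by_coords(img, in_coords, order, fill)
}

#' Fisheye (barrel) distortion about an arbitrary centre
#'
#' Radial barrel warp: with radii normalised so the image corner farthest
#' from `center` lies at radius 1, the output location at radius r samples
#' the input at radius r (1 + k r^2) / (1 + k) along the same ray. The pixel
#' at `center` is a fixed point and k = 0 is the identity.
#'
#' @inheritParams img_rotate
#' @param k Distortion coefficient, `k >= 0`.
#' @param center Numeric vector (row, column\[, slice\]) inside the image;
#'   default image centre.
#' @return Array with the same dimensions as `img`.
#' @export
img_fisheye <- function(img, k, center = NULL, order = "linear", fill = 0) {
  d <- check_image(img)
  if (!is.finite(k) || k < 0) abort("`k` must be a non-negative number.")
  nd <- length(d)
  if (is.null(center)) center <- (d + 1) / 2
  if (length(center) != nd || any(center < 1) || any(center > d)) {
    abort("`center` must be a point inside the image bounds.")
  }
  corners <- as.matrix(do.call(expand.grid, lapply(d, function(n) c(1, n))))
  rmax <- sqrt(max(rowSums(sweep(corners, 2, center)^2)))
  out <- coord_grid(d)
  off <- sweep(out, 2, center)
  r_out <- sqrt(rowSums(off^2)) / rmax
  s <- (1 + k * r_out^2) / (1 + k)
  in_coords <- sweep(off * s, 2, center, "+")
  warp_by_coords(img, in_coords, order, fill)
}

aug_methods <- c("rotate", "shear", "scale", "fisheye")

#' Augmentation policy: parameter ranges for the four distortions
#'
#' Describes the stochastic distortion family applied at train time and in
#' test-time augmentation: per-method parameter ranges, the fisheye
#' coefficient (its centre is drawn uniformly within the image bounds), the
#' composition mode (`"single_random"` draws one of the four methods per
#' image; `"compose_all"` chains rotate, shear, scale, fisheye in that
#' order), the interpolation order and the fill value.
#'
#' @param rotation_range Angle interval in degrees.
#' @param shear_range Interval in radians, inside (-pi/2, pi/2).
#' @param scale_range Interval of factors, subset of (0, 1].
#' @param fisheye_k Fisheye coefficient, `k >= 0`.
#' @param composition_mode `"single_random"` or `"compose_all"`.
#' @param interpolation `"linear"` or `"nearest"`.
#' @param fill_value Fill for out-of-bounds regions.
#' @return An object of class `aug_policy`.
#' @seealso [preset_policy()] for the chest-radiograph and brain-MRI presets.
#' @export
aug_policy <- function(rotation_range = c(-90, 90),
                       shear_range = c(-pi / 4, pi / 4),
                       scale_range = c(0.4, 1),
                       fisheye_k = 0.4,
                       composition_mode = c("single_random", "compose_all"),
                       interpolation = c("linear", "nearest"),
                       fill_value = 0) {
  composition_mode <- match.arg(composition_mode)
  interpolation <- match.arg(interpolation)
  chk_range <- function(x, nm) {
    if (length(x) != 2 || !all(is.finite(x)) || x[1] > x[2]) {
      abort(sprintf("`%s` must be a non-empty finite interval c(lo, hi).", nm))
    }
  }
  chk_range(rotation_range, "rotation_range")
  chk_range(shear_range, "shear_range")
  chk_range(scale_range, "scale_range")
  if (scale_range[1] <= 0 || scale_range[2] > 1) {
    abort("`scale_range` must be a subset of (0, 1].")
  }
  if (abs(shear_range[1]) >= pi / 2 || abs(shear_range[2]) >= pi / 2) {
    abort("`shear_range` must lie inside (-pi/2, pi/2).")
  }
  if (!is.finite(fisheye_k) || fisheye_k < 0) abort("`fisheye_k` must be >= 0.")
  structure(
    list(rotation_range = as.numeric(rotation_range),
         shear_range = as.numeric(shear_range),
         scale_range = as.numeric(scale_range),
         fisheye_k = as.numeric(fisheye_k),
         composition_mode = composition_mode,
         interpolation = interpolation,
         fill_value = fill_value),
    class = "aug_policy")
}

#' Modality presets for the augmentation policy
#'
#' `"cxr_2d"`: rotation \[-90, 90\] degrees, shear \[-pi/4, pi/4\] radians,
#' scale \[0.4, 1\], fisheye k = 0.4. `"mri_3d"`: rotation \[-10, 10\]
#' degrees, shear \[-pi/6, pi/6\] radians, scale \[0.8, 1\], fisheye k = 0.4.
#'
#' @param modality `"cxr_2d"` or `"mri_3d"` (case-insensitive).
#' @param ... Overrides passed on to [aug_policy()].
#' @return An `aug_policy`.
#' @export
preset_policy <- function(modality = c("cxr_2d", "mri_3d"), ...) {
  modality <- tolower(modality[1])
  dots <- list(...)
  base <- switch(modality,
    cxr_2d = list(rotation_range = c(-90, 90), shear_range = c(-pi / 4, pi / 4),
                  scale_range = c(0.4, 1), fisheye_k = 0.4),
    mri_3d = list(rotation_range = c(-10, 10), shear_range = c(-pi / 6, pi / 6),
                  scale_range = c(0.8, 1), fisheye_k = 0.4),
    abort(sprintf("Unknown modality '%s'; use 'cxr_2d' or 'mri_3d'.", modality))
  )
  base[names(dots)] <- dots
  do.call(aug_policy, base)
}

#' @export
print.aug_policy <- function(x, ...) {
  cat("<aug_policy>\n")
  cat(sprintf("  rotation: [%g, %g] deg; shear: [%g, %g] rad\n",
              x$rotation_range[1], x$rotation_range[2],
              x$shear_range[1], x$shear_range[2]))
  cat(sprintf("  scale: [%g, %g]; fisheye k = %g; mode = %s\n",
              x$scale_range[1], x$scale_range[2], x$fisheye_k,
              x$composition_mode))
  invisible(x)
}

# draw one concrete transform spec for `method` using the current RNG
sample_aug_spec <- function(method, policy, d) {
  switch(method,
    rotate = tibble::tibble(method = "rotate",
                            param = runif(1, policy$rotation_range[1],
                                          policy$rotation_range[2]),
                            center = list(NULL)),
    shear = tibble::tibble(method = "shear",
                           param = runif(1, policy$shear_range[1],
                                         policy$shear_range[2]),
                           center = list(NULL)),
    scale = tibble::tibble(method = "scale",
                           param = runif(1, policy$scale_range[1],
                                         policy$scale_range[2]),
                           center = list(NULL)),
    fisheye = tibble::tibble(method = "fisheye",
                             param = policy$fisheye_k,
                             center = list(vapply(d, function(n)
                               runif(1, 1, n), numeric(1))))
  )
}

#' Apply a recorded transform specification to an image
#'
#' Replays the rows of an `AugSpec` tibble (columns `method`, `param`,
#' `center`) in order; useful for applying the identical geometric transform
#' to an image and its truth masks (with `order = "nearest"`).
#'
#' @param img 2D or 3D array.
#' @param spec Tibble of transform rows as produced by [apply_policy()].
#' @param order,fill Interpolation order and fill value.
#' @return Transformed array.
#' @export
apply_aug_spec <- function(img, spec, order = "linear", fill = 0) {
  for (i in seq_len(nrow(spec))) {
    img <- switch(spec$method[i],
      identity = img,
      rotate = img_rotate(img, spec$param[i], order = order, fill = fill),
      shear = img_shear(img, spec$param[i], order = order, fill = fill),
      scale = img_scale(img, spec$param[i], order = order, fill = fill),
      fisheye = img_fisheye(img, spec$param[i], center = spec$center[[i]],
                            order = order, fill = fill),
      abort(sprintf("Unknown method '%s' in AugSpec.", spec$method[i]))
    )
  }
  img
}

#' Sample and apply one stochastic augmentation
#'
#' In `single_random` mode one of the four methods is drawn uniformly and
#' applied with a parameter drawn uniformly from its range; in `compose_all`
#' mode all four are applied in the fixed order rotate, shear, scale,
#' fisheye. Uses R's global random number generator; call [set.seed()] for
#' reproducibility.
#'
#' @param img 2D or 3D array.
#' @param policy An [aug_policy()].
#' @return List with `image` (the distorted array) and `spec` (tibble of the
#'   sampled transform(s)).
#' @export
apply_policy <- function(img, policy) {
  d <- check_image(img)
  methods <- if (policy$composition_mode == "single_random") {
    sample(aug_methods, 1)
  } else {
    aug_methods
  }
  spec <- dplyr::bind_rows(lapply(methods, sample_aug_spec,
                                  policy = policy, d = d))
  list(image = apply_aug_spec(img, spec, order = policy$interpolation,
                              fill = policy$fill_value),
       spec = spec)
}

#' Test-time augmentation ensemble
#'
#' Generates `reps_per_method` independently distorted copies of the input
#' per method (rotate, shear, scale, fisheye), `4 * reps_per_method` images
#' in total (12 at the default), grouped by method.
#'
#' @param img 2D or 3D array.
#' @param policy An [aug_policy()].
#' @param reps_per_method Copies per method, `>= 1` (default 3).
#' @return List of distorted arrays with attribute `"specs"` (tibble of the
#'   sampled transforms, one row per ensemble member).
#' @export
make_tta_ensemble <- function(img, policy, reps_per_method = 3) {
  d <- check_image(img)
  if (reps_per_method < 1) abort("`reps_per_method` must be >= 1.")
  specs <- list()
  out <- list()
  i <- 0
  for (method in aug_methods) {
    for (r in seq_len(reps_per_method)) {
      i <- i + 1
      sp <- sample_aug_spec(method, policy, d)
      out[[i]] <- apply_aug_spec(img, sp, order = policy$interpolation,
                                 fill = policy$fill_value)
      specs[[i]] <- sp
    }
  }
  attr(out, "specs") <- dplyr::bind_rows(specs)
  out
}
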