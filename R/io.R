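# Cohort readers/writers and image preprocessing.
#
# 2D cohorts are written as 16-bit TIFF (intensities are already quantised
# to the 16-bit grid at render time, so save -> load round trips are
# bit-exact); 3D cohorts as NIfTI with an identity affine and double
# datatype. The sample table travels as `cohort.csv`, the generating spec
# as `spec.json`.

#' Save a cohort to a directory
#'
#' Writes one image file per sample (`images/<sample_id>.tiff` for 2D,
#' `.nii.gz` for 3D), truth masks under `masks/`, the sample table as
#' `cohort.csv` and the generating specification (when present) as
#' `spec.json`.
#'
#' @param cohort An `image_cohort`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
save_cohort <- function(cohort, dir) {
  nd <- length(dim(cohort$images[[1]]))
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  ext <- if (nd == 2) ".tiff" else ".nii.gz"
  info <- cohort$info
  info$file <- file.path("images", paste0(info$sample_id, ext))
  write_img <- function(img, path) {
    if (nd == 2) {
      tiff::writeTIFF(img, path, bits.per.sample = 16L)
    } else {
      RNifti::writeNifti(RNifti::asNifti(img, datatype = "double"), path)
    }
  }
  for (i in seq_len(nrow(info))) {
    write_img(cohort$images[[i]], file.path(dir, info$file[i]))
    write_img(cohort$masks$shortcut[[i]] * 1,
              file.path(dir, "masks", paste0(info$sample_id[i], "_shortcut", ext)))
    write_img(cohort$masks$disease[[i]] * 1,
              file.path(dir, "masks", paste0(info$sample_id[i], "_disease", ext)))
  }
  readr::write_csv(info, file.path(dir, "cohort.csv"))
  if (!is.null(cohort$spec)) {
    sp <- cohort$spec
    jsonlite::write_json(
      list(n_subjects = sp$n_subjects,
           images_per_subject = sp$images_per_subject,
           image_shape = sp$image_shape,
           groups = as.list(sp$groups), labels = sp$labels,
           prevalence = sp$prevalence,
           shortcut = unclass(sp$shortcut), signal = unclass(sp$signal),
           noise_sigma = sp$noise_sigma, background = sp$background,
           seed = sp$seed),
      file.path(dir, "spec.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

read_img_file <- function(path) {
  if (grepl("\\.(tif|tiff)$", path, ignore.case = TRUE)) {
    as.matrix(tiff::readTIFF(path))
  } else if (grepl("\\.png$", path, ignore.case = TRUE)) {
    as.matrix(png::readPNG(path))
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    arr <- as.array(RNifti::readNifti(path))
    array(as.numeric(arr), dim(arr))
  } else {
    abort(sprintf("Unsupported image format: %s", path))
  }
}

#' Load a cohort from a directory
#'
#' Reads `cohort.csv` plus the referenced images (TIFF/PNG for 2D, NIfTI
#' for 3D) and masks; save/load round trips reproduce the arrays and the
#' table exactly. Errors on duplicate sample ids, missing image files, or
#' a mix of 2D and 3D images.
#'
#' @param dir Directory produced by [save_cohort()].
#' @return An `image_cohort`.
#' @export
load_cohort <- function(dir) {
  csv <- file.path(dir, "cohort.csv")
  if (!file.exists(csv)) abort(sprintf("No cohort.csv under '%s'.", dir))
  info <- readr::read_csv(csv, show_col_types = FALSE)
  if (anyDuplicated(info$sample_id)) {
    abort(sprintf("Duplicate sample_id(s): %s",
                  paste(unique(info$sample_id[duplicated(info$sample_id)]),
                        collapse = ", ")))
  }
  paths <- file.path(dir, info$file)
  missing <- !file.exists(paths)
  if (any(missing)) {
    abort(sprintf("Missing image file(s) for: %s",
                  paste(info$sample_id[missing], collapse = ", ")))
  }
  is3d <- grepl("\\.nii(\\.gz)?$", info$file)
  if (length(unique(is3d)) > 1) {
    abort("Cohort mixes 2D and 3D images; load them separately.")
  }
  images <- lapply(paths, read_img_file)
  ext <- if (is3d[1]) ".nii.gz" else ".tiff"
  read_mask <- function(kind) {
    lapply(info$sample_id, function(id) {
      p <- file.path(dir, "masks", paste0(id, "_", kind, ext))
      if (file.exists(p)) read_img_file(p) >= 0.5 else NULL
    })
  }
  spec <- NULL
  spec_path <- file.path(dir, "spec.json")
  if (file.exists(spec_path)) {
    sj <- jsonlite::read_json(spec_path, simplifyVector = TRUE)
    spec <- cohort_spec(
      n_subjects = sj$n_subjects, images_per_subject = sj$images_per_subject,
      image_shape = sj$image_shape, groups = unlist(sj$groups),
      labels = sj$labels, prevalence = matrix(unlist(sj$prevalence),
                                              nrow = length(sj$groups)),
      shortcut = do.call(shortcut_spec, sj$shortcut),
      signal = do.call(signal_spec, sj$signal),
      noise_sigma = sj$noise_sigma, background = sj$background,
      seed = sj$seed)
  }
  info$file <- NULL
  structure(list(images = images, info = info,
                 masks = list(shortcut = read_mask("shortcut"),
                              disease = read_mask("disease")),
                 spec = spec),
            class = "image_cohort")
}

#' Histogram equalisation
#'
#' Maps intensities to their empirical CDF values, flattening the
#' histogram; a constant image stays constant.
#'
#' @param img Numeric array.
#' @return Array of the same shape with values in (0, 1\].
#' @export
hist_equalize <- function(img) {
  array(rank(img, ties.method = "max") / length(img), dim(img))
}

#' Preprocess an image for training
#'
#' `"cxr"` mode: histogram equalisation then resize to `target_shape`.
#' `"mri"` mode: centre crop to the tight bounding box of above-threshold
#' voxels (falling back to the full volume with a warning when the
#' foreground is empty) then resize. Output intensities lie in \[0, 1\].
#'
#' @param img 2D or 3D grayscale array.
#' @param target_shape Output extents.
#' @param mode `"cxr"` or `"mri"`.
#' @param threshold Foreground threshold for `"mri"` cropping.
#' @return Array with dimensions `target_shape`.
#' @export
preprocess <- function(img, target_shape, mode = c("cxr", "mri"),
                       threshold = 0.05) {
  mode <- match.arg(mode)
  d <- check_image(img)
  if (mode == "cxr") {
    return(resize_array(hist_equalize(img), target_shape))
  }
  fg <- which(img > threshold, arr.ind = TRUE)
  if (nrow(fg) == 0) {
    warn("Empty foreground in MRI preprocessing; resizing the full volume.")
    cropped <- img
  } else {
    ranges <- lapply(seq_along(d), function(k) seq(min(fg[, k]), max(fg[, k])))
    cropped <- do.call(`[`, c(list(img), ranges, list(drop = FALSE)))
    cropped <- array(cropped, vapply(ranges, length, integer(1)))
  }
  out <- resize_array(cropped, target_shape)
  pmin(pmax(out, 0), 1)
}
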