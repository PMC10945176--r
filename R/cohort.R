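# Synthetic subject-grouped image cohorts with a geometry-robust "disease"
# signal and a demographic-correlated shortcut feature. The generator
# emulates the statistical structure of subject-grouped radiology cohorts:
# each subject belongs to one categorical group (a race / age-bin / sex
# stand-in), carries one or more images, binary multi-label targets whose
# prevalence depends on the group, and — with probability `leak_rate` — a
# group-determined shortcut feature painted into the image.

#' Shortcut feature specification
#'
#' Describes the planted image feature correlated with the demographic group:
#' * `corner_token` — a bright square (2D) or cube (3D) whose corner is a
#'   deterministic function of the group; destroyed by rotation/shear/fisheye
#'   while a central disease blob is not (the "metal marker" hypothesis);
#' * `border_marker` — a bright stripe along a group-determined border;
#' * `global_offset` — a group-dependent uniform intensity shift.
#'
#' @param kind One of `"corner_token"`, `"border_marker"`, `"global_offset"`.
#' @param strength Contrast amplitude in intensity units (images live in
#'   \[0, 1\]).
#' @param size Token side / stripe width in pixels.
#' @param margin Distance of a corner token from the image border.
#' @param leak_rate Probability in \[0, 1\] that a subject carries its
#'   group's shortcut (1 = deterministic shortcut).
#' @return An object of class `shortcut_spec`.
#' @export
shortcut_spec <- function(kind = c("corner_token", "border_marker",
                                   "global_offset"),
                          strength = 0.35, size = 6, margin = 2,
                          leak_rate = 1) {
  kind <- match.arg(kind)
  if (!is.finite(leak_rate) || leak_rate < 0 || leak_rate > 1) {
    abort("`leak_rate` must lie in [0, 1].")
  }
  if (!is.finite(strength) || strength < 0) abort("`strength` must be >= 0.")
  if (size < 1) abort("`size` must be >= 1 pixel.")
  structure(list(kind = kind, strength = strength, size = size,
                 margin = margin, leak_rate = leak_rate),
            class = "shortcut_spec")
}

#' Disease signal specification
#'
#' The label-linked image signal: a round blob of positive contrast placed in
#' the central field (with small per-sample jitter), chosen to survive the
#' whole distortion family — rotations, shears, shrinking and fisheye warps
#' leave a central blob detectable, unlike a corner token.
#'
#' @param radius Blob radius in pixels.
#' @param contrast Blob contrast in intensity units (> 0 whenever any label
#'   prevalence is positive).
#' @param jitter Maximum per-sample displacement of the blob centre from the
#'   image centre, per axis.
#' @return An object of class `signal_spec`.
#' @export
signal_spec <- function(radius = 6, contrast = 0.045, jitter = 4) {
  if (!is.finite(contrast) || contrast < 0) abort("`contrast` must be >= 0.")
  if (radius < 1) abort("`radius` must be >= 1 pixel.")
  structure(list(radius = radius, contrast = contrast, jitter = jitter),
            class = "signal_spec")
}

#' Cohort specification
#'
#' Generative description of a subject-grouped, multi-label,
#' shortcut-planted synthetic image cohort. Group proportions must sum to 1;
#' `prevalence` is the matrix of Bernoulli parameters pi\[g, l\] giving the
#' per-group prevalence of each binary label, which is what couples the
#' demographic attribute to the targets (and thereby makes the shortcut
#' exploitable by a label detector).
#'
#' @param n_subjects Number of subjects (positive integer).
#' @param images_per_subject Images per subject: a single count or a
#'   length-2 range sampled uniformly per subject.
#' @param image_shape 2D `c(H, W)` or 3D `c(D1, D2, D3)` extents, each
#'   `>= 16` and divisible by 16 (four halvings in the reference network).
#' @param groups Named numeric vector of group proportions summing to 1.
#' @param labels Character vector of binary label names.
#' @param prevalence Numeric matrix (groups x labels) of Bernoulli
#'   parameters in \[0, 1\]; defaults to a graded prevalence across groups.
#' @param shortcut A [shortcut_spec()].
#' @param signal A [signal_spec()].
#' @param noise_sigma Gaussian pixel-noise standard deviation (>= 0).
#' @param background Constant background intensity.
#' @param seed Integer seed making generation deterministic.
#' @return An object of class `cohort_spec`.
#' @examples
#' spec <- cohort_spec(n_subjects = 30, seed = 1)
#' cohort <- generate_cohort(spec)
#' @export
cohort_spec <- function(n_subjects = 300,
                        images_per_subject = 1,
                        image_shape = c(64, 64),
                        groups = c(A = 0.2, B = 0.3, C = 0.5),
                        labels = "finding",
                        prevalence = NULL,
                        shortcut = shortcut_spec(),
                        signal = signal_spec(),
                        noise_sigma = 0.08,
                        background = 0.3,
                        seed = 2021) {
  if (!is.numeric(n_subjects) || n_subjects < 1) {
    abort("`n_subjects` must be a positive integer.")
  }
  if (!length(images_per_subject) %in% c(1, 2) || any(images_per_subject < 1)) {
    abort("`images_per_subject` must be a positive count or range.")
  }
  if (!length(image_shape) %in% c(2, 3) || any(image_shape < 16)) {
    abort("`image_shape` must be 2D or 3D with every extent >= 16.")
  }
  if (any(image_shape %% 16 != 0)) {
    abort("`image_shape` extents must be divisible by 16.")
  }
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    abort("`groups` must be a named vector of proportions.")
  }
  if (abs(sum(groups) - 1) > 1e-9) {
    abort("`groups` proportions must sum to 1 (within 1e-9).")
  }
  if (any(groups < 0)) abort("`groups` proportions must be non-negative.")
  G <- length(groups)
  L <- length(labels)
  if (is.null(prevalence)) {
    prevalence <- matrix(rep(seq(0.2, 0.8, length.out = G), L), G, L,
                         dimnames = list(names(groups), labels))
  }
  prevalence <- as.matrix(prevalence)
  if (!all(dim(prevalence) == c(G, L))) {
    abort("`prevalence` must be a groups x labels matrix.")
  }
  if (any(prevalence < 0 | prevalence > 1)) {
    abort("`prevalence` entries must lie in [0, 1].")
  }
  dimnames(prevalence) <- list(names(groups), labels)
  if (!inherits(shortcut, "shortcut_spec")) abort("`shortcut` must be a shortcut_spec.")
  if (!inherits(signal, "signal_spec")) abort("`signal` must be a signal_spec.")
  if (shortcut$kind != "global_offset") {
    if (shortcut$size + shortcut$margin > min(image_shape)) {
      abort("shortcut token does not fit inside the image.")
    }
  }
  if (any(prevalence > 0) && signal$contrast <= 0) {
    abort("`signal` contrast must be > 0 when any label prevalence is > 0.")
  }
  if (!is.finite(noise_sigma) || noise_sigma < 0) {
    abort("`noise_sigma` must be >= 0.")
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         images_per_subject = as.integer(images_per_subject),
         image_shape = as.integer(image_shape),
         groups = groups, labels = labels, prevalence = prevalence,
         shortcut = shortcut, signal = signal,
         noise_sigma = noise_sigma, background = background,
         seed = as.integer(seed)),
    class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>\n")
  cat(sprintf("  %d subjects, shape %s, %d group(s), %d label(s)\n",
              x$n_subjects, paste(x$image_shape, collapse = "x"),
              length(x$groups), length(x$labels)))
  cat(sprintf("  shortcut: %s (strength %g, leak_rate %g); noise sigma %g\n",
              x$shortcut$kind, x$shortcut$strength, x$shortcut$leak_rate,
              x$noise_sigma))
  invisible(x)
}

# group index -> corner (2D: 4 corners, 3D: 8), cycling when G > corners
corner_for_group <- function(gi, d) {
  nd <- length(d)
  ci <- (gi - 1) %% (2^nd)
  vapply(seq_len(nd), function(k) bitwAnd(bitwShiftR(ci, k - 1), 1L),
         integer(1))  # 0 = low side, 1 = high side
}

# paint the shortcut for group index gi; returns list(img, mask)
paint_shortcut <- function(img, gi, spec) {
  d <- dim(img)
  nd <- length(d)
  sc <- spec$shortcut
  mask <- array(FALSE, d)
  if (sc$kind == "corner_token") {
    side <- corner_for_group(gi, d)
    rng <- lapply(seq_len(nd), function(k) {
      if (side[k] == 0) seq(sc$margin + 1, sc$margin + sc$size)
      else seq(d[k] - sc$margin - sc$size + 1, d[k] - sc$margin)
    })
    idx <- as.matrix(do.call(expand.grid, rng))
    mask[idx] <- TRUE
    img[idx] <- img[idx] + sc$strength
  } else if (sc$kind == "border_marker") {
    nb <- 2 * nd
    bi <- (gi - 1) %% nb
    axis <- bi %/% 2 + 1
    hi <- bi %% 2
    rng <- lapply(seq_len(nd), function(k) {
      if (k != axis) seq_len(d[k])
      else if (hi == 0) seq_len(sc$size)
      else seq(d[k] - sc$size + 1, d[k])
    })
    idx <- as.matrix(do.call(expand.grid, rng))
    mask[idx] <- TRUE
    img[idx] <- img[idx] + sc$strength
  } else {  # global_offset
    G <- length(spec$groups)
    offset <- sc$strength * ((gi - 1) / max(G - 1, 1) - 0.5)
    img <- img + offset
    mask[] <- TRUE
  }
  list(img = img, mask = mask)
}

# squared-distance field from a centre point (reused for blobs)
dist2_field <- function(d, ctr) {
  g <- coord_grid(d)
  array(rowSums(sweep(g, 2, ctr)^2), d)
}

#' Render a single cohort sample
#'
#' Renders one image for a given group and label vector: constant
#' background, one central blob per active label (at a label-specific offset
#' plus per-sample jitter), the group's shortcut (if `carry_shortcut`),
#' Gaussian noise, then clamping to \[0, 1\] and quantisation to the 16-bit
#' intensity grid (so that PNG round trips are exact). Uses the current RNG
#' state for jitter and noise.
#'
#' @param spec A [cohort_spec()].
#' @param group Group name (must be one of `names(spec$groups)`).
#' @param labels Binary vector over `spec$labels`.
#' @param carry_shortcut Whether this sample's subject carries the shortcut;
#'   by default drawn as Bernoulli(`leak_rate`).
#' @return List with `image`, `shortcut_mask`, `disease_mask`.
#' @export
render_sample <- function(spec, group, labels,
                          carry_shortcut = NULL) {
  gi <- match(group, names(spec$groups))
  if (is.na(gi)) abort(sprintf("Unknown group '%s'.", group))
  if (length(labels) != length(spec$labels)) {
    abort("`labels` must have one entry per label in the spec.")
  }
  if (!all(labels %in% c(0, 1))) abort("`labels` must be 0/1.")
  d <- spec$image_shape
  nd <- length(d)
  img <- array(spec$background, d)
  disease_mask <- array(FALSE, d)
  sig <- spec$signal
  for (l in seq_along(spec$labels)) {
    if (labels[l] != 1) next
    # deterministic per-label offset on a small ring + per-sample jitter
    ang <- 2 * pi * (l - 1) / max(length(spec$labels), 1)
    base_off <- c(cos(ang), sin(ang), rep(0, nd - 2))[seq_len(nd)] *
      min(d) / 10
    jit <- runif(nd, -sig$jitter, sig$jitter)
    ctr <- (d + 1) / 2 + base_off + jit
    blob <- dist2_field(d, ctr) <= sig$radius^2
    img[blob] <- img[blob] + sig$contrast
    disease_mask <- disease_mask | blob
  }
  if (is.null(carry_shortcut)) {
    carry_shortcut <- runif(1) < spec$shortcut$leak_rate
  }
  shortcut_mask <- array(FALSE, d)
  if (isTRUE(carry_shortcut) && spec$shortcut$strength > 0) {
    ps <- paint_shortcut(img, gi, spec)
    img <- ps$img
    shortcut_mask <- ps$mask
  }
  if (spec$noise_sigma > 0) {
    img <- img + rnorm(length(img), sd = spec$noise_sigma)
  }
  img <- round(pmin(pmax(img, 0), 1) * 65535) / 65535
  list(image = img, shortcut_mask = shortcut_mask,
       disease_mask = disease_mask)
}

#' Generate a synthetic cohort
#'
#' Realises a [cohort_spec()]: draws each subject's group from the spec's
#' proportions, a subject-level shortcut carrier flag (Bernoulli
#' `leak_rate`), per-sample binary labels from the group's prevalence row,
#' and renders every image. Per-subject images share the group and the
#' shortcut realisation but redraw jitter and noise, which is what makes
#' subject-wise splitting consequential. Deterministic given `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `image_cohort`: list with `images` (list of
#'   arrays), `info` (tibble: `sample_id`, `subject_id`, `group`, one
#'   `label_*` column per label), `masks` (lists `shortcut`, `disease`) and
#'   `spec`.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) abort("`spec` must be a cohort_spec.")
  set.seed(spec$seed)
  G <- length(spec$groups)
  subj_group <- sample(names(spec$groups), spec$n_subjects, replace = TRUE,
                       prob = spec$groups)
  subj_carry <- runif(spec$n_subjects) < spec$shortcut$leak_rate
  n_img <- if (length(spec$images_per_subject) == 1) {
    rep(spec$images_per_subject, spec$n_subjects)
  } else {
    sample(seq(spec$images_per_subject[1], spec$images_per_subject[2]),
           spec$n_subjects, replace = TRUE)
  }
  images <- list()
  m_short <- list()
  m_dis <- list()
  rows <- vector("list", sum(n_img))
  k <- 0
  for (s in seq_len(spec$n_subjects)) {
    g <- subj_group[s]
    gi <- match(g, names(spec$groups))
    for (i in seq_len(n_img[s])) {
      k <- k + 1
      labs <- rbinom(length(spec$labels), 1, spec$prevalence[gi, ])
      r <- render_sample(spec, g, labs, carry_shortcut = subj_carry[s])
      images[[k]] <- r$image
      m_short[[k]] <- r$shortcut_mask
      m_dis[[k]] <- r$disease_mask
      row <- tibble::tibble(sample_id = sprintf("S%05d_I%02d", s, i),
                            subject_id = sprintf("S%05d", s),
                            group = g)
      for (l in seq_along(spec$labels)) {
        row[[paste0("label_", spec$labels[l])]] <- as.integer(labs[l])
      }
      rows[[k]] <- row
    }
  }
  structure(list(images = images,
                 info = dplyr::bind_rows(rows),
                 masks = list(shortcut = m_short, disease = m_dis),
                 spec = spec),
            class = "image_cohort")
}

#' @export
print.image_cohort <- function(x, ...) {
  cat("<image_cohort>\n")
  cat(sprintf("  %d samples from %d subjects, shape %s\n",
              nrow(x$info), dplyr::n_distinct(x$info$subject_id),
              paste(dim(x$images[[1]]), collapse = "x")))
  print(dplyr::count(x$info, .data$group))
  invisible(x)
}

#' @export
as_tibble.image_cohort <- function(x, ...) x$info

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Subset a cohort by sample index
#'
#' @param cohort An `image_cohort`.
#' @param idx Integer row indices into `cohort$info`.
#' @return A new `image_cohort` with the selected samples.
#' @export
subset_cohort <- function(cohort, idx) {
  structure(list(images = cohort$images[idx],
                 info = cohort$info[idx, , drop = FALSE],
                 masks = list(shortcut = cohort$masks$shortcut[idx],
                              disease = cohort$masks$disease[idx]),
                 spec = cohort$spec),
            class = "image_cohort")
}

#' Binary label matrix of a cohort
#'
#' @param cohort An `image_cohort`.
#' @return Integer matrix (samples x labels), label names as columns.
#' @export
label_matrix <- function(cohort) {
  cols <- grep("^label_", names(cohort$info), value = TRUE)
  m <- as.matrix(cohort$info[cols])
  colnames(m) <- sub("^label_", "", cols)
  m
}

#' Split a cohort by subject
#'
#' Partitions subjects (never individual images) into train / validation /
#' test so that no subject appears in more than one split; subject counts
#' follow the fractions by largest-remainder rounding. Deterministic given
#' `seed`.
#'
#' @param cohort An `image_cohort`.
#' @param fractions Positive fractions `c(train, val, test)` summing to 1.
#' @param seed Integer seed for the subject shuffle.
#' @return Named list of three `image_cohort`s: `train`, `val`, `test`.
#' @export
split_by_subject <- function(cohort, fractions = c(0.6, 0.2, 0.2),
                             seed = 2021) {
  if (length(fractions) != 3 || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    abort("`fractions` must be three positive numbers summing to 1.")
  }
  subjects <- unique(cohort$info$subject_id)
  n <- length(subjects)
  if (n < 3) abort("Fewer subjects than splits.")
  base <- floor(fractions * n)
  rem <- fractions * n - base
  extra <- n - sum(base)
  if (extra > 0) {
    give <- order(rem, decreasing = TRUE)[seq_len(extra)]
    base[give] <- base[give] + 1
  }
  set.seed(seed)
  shuffled <- sample(subjects)
  assignment <- rep(c("train", "val", "test"), times = base)
  out <- lapply(c(train = "train", val = "val", test = "test"), function(s) {
    keep <- shuffled[assignment == s]
    subset_cohort(cohort, which(cohort$info$subject_id %in% keep))
  })
  out
}
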