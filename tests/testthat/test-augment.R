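test_that("identity-parameter limits are bit-exact for all four operators", {
  set.seed(1)
  for (img in list(matrix(runif(32 * 32), 32, 32),
                   array(runif(16^3), c(16, 16, 16)))) {
    expect_identical(img_rotate(img, 0), img)
    expect_identical(img_shear(img, 0), img)
    expect_identical(img_scale(img, 1), img)
    expect_identical(img_fisheye(img, 0), img)
  }
})

test_that("90-degree rotation equals the array quarter-turn", {
  set.seed(2)
  n <- 32
  x <- matrix(runif(n * n), n, n)
  expect_equal(img_rotate(x, 90, order = "nearest"), t(x)[, n:1])
})

test_that("rotation composes approximately to identity on smooth images", {
  sm <- outer(seq(0, 1, length.out = 64), seq(0, 1, length.out = 64),
              function(a, b) 0.5 + 0.3 * sin(4 * a) * cos(3 * b))
  rb <- img_rotate(img_rotate(sm, 37), -37)
  interior <- abs(rb - sm)[17:48, 17:48]
  expect_lt(mean(interior), 0.02)
})

test_that("shear fixes the anchor point and inverts by negation", {
  x <- matrix(0, 33, 33)
  x[17, 17] <- 1
  for (r in c(0.3, -0.7, pi / 6)) {
    expect_equal(img_shear(x, r)[17, 17], 1)
  }
  sm <- outer(seq(0, 1, length.out = 64), seq(0, 1, length.out = 64),
              function(a, b) 0.5 + 0.3 * sin(5 * a + 2 * b))
  back <- img_shear(img_shear(sm, pi / 6), -pi / 6)
  expect_lt(mean(abs(back - sm)[17:48, 17:48]), 0.02)
  expect_error(img_shear(sm, pi / 2), "radian")
})

test_that("scaling shrinks a disk by the squared factor and fill grows as factor drops", {
  d2 <- (row(diag(64)) - 32.5)^2 + (col(diag(64)) - 32.5)^2
  disk <- array(as.numeric(d2 <= 20^2), c(64, 64))
  sc <- img_scale(disk, 0.5)
  expect_equal(sum(sc > 0.5) / sum(disk), 0.25, tolerance = 0.05 / 0.25)
  ones <- array(1, c(64, 64))
  fill_area <- vapply(c(0.4, 0.6, 0.8, 1), function(f)
    sum(img_scale(ones, f) < 0.5), numeric(1))
  expect_true(all(diff(fill_area) <= 0))
  expect_error(img_scale(disk, 0), "factor")
  expect_error(img_scale(disk, 1.2), "factor")
})

test_that("fisheye fixes its centre and maps radii monotonically", {
  set.seed(3)
  x <- matrix(runif(64 * 64), 64, 64)
  ctr <- c(20, 41)
  y <- img_fisheye(x, 0.4, center = ctr)
  expect_equal(y[20, 41], x[20, 41])
  # radial map r_in = r (1 + k r^2) / (1 + k): strictly monotone, with
  # displacement magnitude increasing on [0, 1/sqrt(3)]
  k <- 0.4
  r <- seq(0, 1, length.out = 201)
  rin <- r * (1 + k * r^2) / (1 + k)
  expect_true(all(diff(rin) > 0))
  disp <- abs(rin - r)
  rising <- r <= 1 / sqrt(3)
  expect_true(all(diff(disp[rising]) > 0))
  expect_equal(rin[length(r)], 1)
  expect_error(img_fisheye(x, 0.4, center = c(100, 2)), "bounds")
  expect_error(img_fisheye(x, -1), "k")
})

test_that("modality presets carry the published parameter ranges", {
  cxr <- preset_policy("cxr_2d")
  expect_equal(cxr$rotation_range, c(-90, 90))
  expect_equal(cxr$shear_range, c(-pi / 4, pi / 4))
  expect_equal(cxr$scale_range, c(0.4, 1))
  expect_equal(cxr$fisheye_k, 0.4)
  mri <- preset_policy("mri_3d")
  expect_equal(mri$rotation_range, c(-10, 10))
  expect_equal(mri$shear_range, c(-pi / 6, pi / 6))
  expect_equal(mri$scale_range, c(0.8, 1))
  expect_equal(mri$fisheye_k, 0.4)
  expect_error(preset_policy("pet"), "modality")
})

test_that("apply_policy draws methods uniformly and parameters within range", {
  set.seed(4)
  p <- preset_policy("cxr_2d")
  img <- matrix(0.5, 16, 16)
  specs <- dplyr::bind_rows(
    replicate(4000, apply_policy(img, p)$spec, simplify = FALSE))
  freq <- table(specs$method) / nrow(specs)
  expect_true(all(freq >= 0.23 & freq <= 0.27))
  rot <- specs$param[specs$method == "rotate"]
  expect_true(all(rot >= -90 & rot <= 90))
  she <- specs$param[specs$method == "shear"]
  expect_true(all(abs(she) <= pi / 4))
  sca <- specs$param[specs$method == "scale"]
  expect_true(all(sca >= 0.4 & sca <= 1))
})

test_that("degenerate-identity policy reproduces the input", {
  p <- aug_policy(rotation_range = c(0, 0), shear_range = c(0, 0),
                  scale_range = c(1, 1), fisheye_k = 0)
  set.seed(5)
  x <- matrix(runif(32 * 32), 32, 32)
  expect_identical(apply_policy(x, p)$image, x)
  p2 <- aug_policy(rotation_range = c(0, 0), shear_range = c(0, 0),
                   scale_range = c(1, 1), fisheye_k = 0,
                   composition_mode = "compose_all")
  expect_identical(apply_policy(x, p2)$image, x)
})

test_that("TTA ensemble has reps_per_method x 4 members of the input shape", {
  set.seed(6)
  x <- matrix(runif(32 * 32), 32, 32)
  p <- preset_policy("cxr_2d")
  ens <- make_tta_ensemble(x, p, reps_per_method = 3)
  expect_length(ens, 12)
  expect_true(all(vapply(ens, function(e) identical(dim(e), dim(x)),
                         logical(1))))
  ident <- aug_policy(rotation_range = c(0, 0), shear_range = c(0, 0),
                      scale_range = c(1, 1), fisheye_k = 0)
  ens1 <- make_tta_ensemble(x, ident, reps_per_method = 1)
  expect_length(ens1, 4)
  for (e in ens1) expect_identical(e, x)
})

test_that("operators preserve shape and the [0, 1] intensity range", {
  set.seed(7)
  p <- preset_policy("cxr_2d")
  x <- matrix(runif(32 * 32), 32, 32)
  for (i in 1:25) {
    out <- apply_policy(x, p)$image
    expect_identical(dim(out), dim(x))
    expect_true(all(out >= 0 & out <= 1))
  }
})

test_that("a composed random augmentation usually expels a corner token from its quadrant", {
  spec <- tiny_spec(image_shape = c(64, 64),
                    shortcut = shortcut_spec(size = 6, strength = 0.4,
                                             leak_rate = 1))
  r <- local({set.seed(8); render_sample(spec, "A", 1)})
  mask <- r$shortcut_mask
  centroid_quadrant <- function(m) {
    idx <- which(m, arr.ind = TRUE)
    ctr <- colMeans(idx)
    c(ctr[1] <= 32.5, ctr[2] <= 32.5)
  }
  orig_q <- centroid_quadrant(mask)
  p <- preset_policy("cxr_2d", composition_mode = "compose_all",
                     interpolation = "nearest")
  set.seed(9)
  moved <- 0
  n_draws <- 300
  for (i in seq_len(n_draws)) {
    res <- apply_policy(mask * 1, p)
    warped <- res$image >= 0.5
    if (!any(warped)) {
      moved <- moved + 1  # token pushed out of frame entirely
    } else if (!identical(centroid_quadrant(warped), orig_q)) {
      moved <- moved + 1
    }
  }
  expect_gt(moved / n_draws, 0.5)
})
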