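test_that("the reference CNN satisfies the adapter output contracts", {
  set.seed(30)
  m_soft <- reference_small_cnn(c(32, 32), 3, head = "softmax")
  imgs <- lapply(1:7, function(i) matrix(runif(32 * 32), 32, 32))
  sc <- predict_scores(m_soft, imgs)
  expect_equal(rowSums(sc), rep(1, 7), tolerance = 1e-6)
  m_sig <- reference_small_cnn(c(32, 32), 10, head = "sigmoid")
  sc2 <- predict_scores(m_sig, imgs)
  expect_true(all(sc2 >= 0 & sc2 <= 1))
  expect_equal(dim(sc2), c(7, 10))
  # penultimate dimensionality constant across batch sizes
  f1 <- penultimate_features(m_soft, imgs[1])
  f7 <- penultimate_features(m_soft, imgs)
  expect_equal(ncol(f1), ncol(f7))
  expect_equal(f7[1, ], f1[1, ], tolerance = 1e-12)
  expect_error(reference_small_cnn(c(30, 30), 2), "divisible")
})

test_that("training is seed-deterministic with the documented LR schedule and early stopping", {
  spec <- tiny_spec(n_subjects = 40, seed = 31)
  co <- generate_cohort(spec)
  sp <- split_by_subject(co, c(0.6, 0.2, 0.2), seed = 31)
  sched <- fast_schedule(seed = 31, max_epochs = 6, patience = 2)
  m1 <- train_demographic_classifier(sp$train, sp$val, schedule = sched)
  m2 <- train_demographic_classifier(sp$train, sp$val, schedule = sched)
  lg1 <- tidy(m1)
  expect_identical(lg1$train_loss[1], tidy(m2)$train_loss[1])
  expect_identical(m1$weights, m2$weights)
  # lr(epoch) = 0.001 * 0.95^floor(epoch / 2), read back from the log
  expect_equal(lg1$lr, 0.001 * 0.95^(lg1$epoch %/% 2), tolerance = 1e-12)
  # early stopping: no more than patience non-improving epochs after the best
  best_ep <- m1$best_epoch
  expect_lte(nrow(lg1), best_ep + 1 + sched$patience)
  expect_lte(nrow(lg1), sched$max_epochs)
})

test_that("subject leakage between splits is rejected before fitting", {
  spec <- tiny_spec(n_subjects = 20, seed = 32)
  co <- generate_cohort(spec)
  sp <- split_by_subject(co, c(0.6, 0.2, 0.2), seed = 32)
  leaky <- subset_cohort(co, 1:10)
  expect_error(train_demographic_classifier(leaky, co, schedule =
                                              fast_schedule()), "leakage")
  expect_error(check_subject_disjoint(sp$train, sp$train), "leakage")
  expect_silent(check_subject_disjoint(sp$train, sp$val, sp$test))
})

test_that("constant labels and single-class targets are refused", {
  spec <- cohort_spec(n_subjects = 24, image_shape = c(16, 16),
                      prevalence = matrix(0, 3, 1),
                      signal = signal_spec(radius = 3, contrast = 0.2,
                                           jitter = 1),
                      shortcut = shortcut_spec(size = 3, margin = 1),
                      seed = 33)
  co <- generate_cohort(spec)
  sp <- split_by_subject(co, c(0.6, 0.2, 0.2), seed = 33)
  expect_error(train_label_detector(sp$train, sp$val,
                                    schedule = fast_schedule()), "constant")
  one_group <- subset_cohort(co, which(co$info$group == co$info$group[1]))
  sp1 <- split_by_subject(one_group, c(0.5, 0.25, 0.25), seed = 1)
  expect_error(train_demographic_classifier(sp1$train, sp1$val,
                                            schedule = fast_schedule()),
               "single class")
})

test_that("threshold selection attains the exhaustive weighted-F1 grid maximum", {
  ss <- score_set(matrix(c(0.1, 0.2, 0.8, 0.9), ncol = 1,
                         dimnames = list(NULL, "l")),
                  matrix(c(0, 0, 1, 1), ncol = 1))
  thr <- select_thresholds(ss)
  # exhaustive oracle over the same grid
  grid <- seq(0, 1, by = 0.01)
  oracle <- vapply(grid, function(t) {
    pred <- as.integer(c(0.1, 0.2, 0.8, 0.9) >= t)
    y <- c(0, 0, 1, 1)
    f1 <- function(cls) {
      tp <- sum(pred == cls & y == cls)
      fp <- sum(pred == cls & y != cls)
      fn <- sum(pred != cls & y == cls)
      if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    }
    (2 * f1(1) + 2 * f1(0)) / 4
  }, numeric(1))
  expect_equal(attr(thr, "weighted_f1")[["l"]], max(oracle))
  expect_equal(unname(thr["l"]), grid[which.max(oracle)])
  expect_equal(unname(thr["l"]), 0.21)  # smallest separating grid point
  expect_equal(max(oracle), 1)          # perfectly separable
  # all-identical scores: constant F1, tie broken to the smallest threshold
  ss2 <- score_set(matrix(rep(0.5, 6), ncol = 1),
                   matrix(rep(c(0, 1), 3), ncol = 1))
  expect_equal(unname(select_thresholds(ss2)[1]), 0)
  # no positives -> 0.5 with warning
  ss3 <- score_set(matrix(runif(5), ncol = 1), matrix(rep(0, 5), ncol = 1))
  expect_warning(t3 <- select_thresholds(ss3), "positives")
  expect_equal(unname(t3[1]), 0.5)
})

test_that("TTA averaging reduces to the base scores under an identity policy", {
  set.seed(34)
  m <- reference_small_cnn(c(32, 32), 2, head = "sigmoid")
  imgs <- lapply(1:4, function(i) matrix(runif(32 * 32), 32, 32))
  ident <- aug_policy(rotation_range = c(0, 0), shear_range = c(0, 0),
                      scale_range = c(1, 1), fisheye_k = 0)
  base <- predict_scores(m, imgs)
  tta <- predict_with_tta(m, imgs, ident)
  expect_equal(tta, base, tolerance = 1e-12)
  # the TTA output is exactly the mean of the 12 member scores
  p <- preset_policy("cxr_2d")
  set.seed(35)
  tta1 <- predict_with_tta(m, imgs[1], p)
  set.seed(35)
  ens <- make_tta_ensemble(imgs[[1]], p, 3)
  expect_equal(unname(tta1[1, ]), unname(colMeans(predict_scores(m, ens))),
               tolerance = 1e-12)
})

test_that("TTA scores vary less across RNG states than single augmentations", {
  set.seed(36)
  m <- reference_small_cnn(c(32, 32), 1, head = "sigmoid")
  img <- matrix(runif(32 * 32), 32, 32)
  p <- preset_policy("cxr_2d")
  tta_scores <- single_scores <- numeric(20)
  for (r in 1:20) {
    set.seed(1000 + r)
    tta_scores[r] <- predict_with_tta(m, list(img), p)[1, 1]
    set.seed(1000 + r)
    single_scores[r] <- predict_scores(m, list(apply_policy(img, p)$image))[1, 1]
  }
  expect_lte(stats::var(tta_scores), stats::var(single_scores))
})

test_that("the task-transfer probe is chance-level for random features and freezes the backbone", {
  spec <- cohort_spec(n_subjects = 500, image_shape = c(16, 16),
                      groups = c(A = 0.5, B = 0.5),
                      prevalence = matrix(0.5, 2, 1),
                      signal = signal_spec(radius = 3, contrast = 0.2,
                                           jitter = 1),
                      shortcut = shortcut_spec(size = 3, margin = 1,
                                               leak_rate = 0),
                      seed = 37)
  co <- generate_cohort(spec)
  sp <- split_by_subject(co, c(0.4, 0.2, 0.4), seed = 37)
  set.seed(38)
  m <- reference_small_cnn(c(16, 16), 1, head = "sigmoid")  # untrained
  pr <- task_transfer_probe(m, sp$train, sp$val, sp$test,
                            boot = bootstrap_config(iterations = 50))
  expect_gte(pr$auc, 0.4)
  expect_lte(pr$auc, 0.6)
  expect_true(pr$features_unchanged)
  expect_true(pr$ci$lower <= pr$ci$boot_mean &&
              pr$ci$boot_mean <= pr$ci$upper)
  # frozen backbone: features identical after further head-only fitting
  frozen <- freeze_backbone(m)
  f_before <- penultimate_features(frozen, sp$test$images[1:5])
  refit <- train_demographic_classifier(sp$train, sp$val, adapter = frozen,
                                        schedule = fast_schedule(max_epochs = 2))
  f_after <- penultimate_features(refit, sp$test$images[1:5])
  expect_identical(f_before, f_after)
})
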