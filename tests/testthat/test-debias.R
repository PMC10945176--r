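# explicit O(n^2) double-sum oracle for the unbiased MMD^2
mmd_oracle <- function(a, b, sigma) {
  k <- function(x, y) exp(-(x - y)^2 / (2 * sigma^2))
  m <- length(a)
  n <- length(b)
  saa <- 0
  for (i in 1:m) for (j in 1:m) if (i != j) saa <- saa + k(a[i], a[j])
  sbb <- 0
  for (i in 1:n) for (j in 1:n) if (i != j) sbb <- sbb + k(b[i], b[j])
  sab <- 0
  for (i in 1:m) for (j in 1:n) sab <- sab + k(a[i], b[j])
  saa / (m * (m - 1)) + sbb / (n * (n - 1)) - 2 * sab / (m * n)
}

test_that("mmd_rbf matches the double-sum oracle and separates shifted samples", {
  set.seed(40)
  a <- rnorm(40)
  b <- rnorm(35, mean = 0.5)
  pool <- c(a, b)
  D <- abs(outer(pool, pool, "-"))
  sigma <- max(stats::median(D[lower.tri(D)]), 1e-3)
  expect_equal(mmd_rbf(a, b, bandwidth = sigma),
               max(mmd_oracle(a, b, sigma), 0), tolerance = 1e-12)
  # same draws -> (biased estimator) ~ 0
  expect_warning(v_same <- mmd_rbf(a[1], a[1]), "size 1")
  expect_lt(abs(v_same), 1e-9)
  expect_equal(mmd_rbf(a, a), 0)  # identical samples, clipped at 0
  # well-separated gaussians
  set.seed(41)
  x <- rnorm(200)
  y <- rnorm(200, mean = 3)
  expect_gt(mmd_rbf(x, y), 0.5)
  expect_error(mmd_rbf(numeric(0), y), "non-empty")
})

test_that("mmd analytic gradients agree with finite differences", {
  set.seed(42)
  a <- runif(8)            # well-separated samples: positive MMD^2, so the
  b <- runif(6, 1.5, 2.5)  # clipped estimate is differentiable
  g <- fairaug:::mmd_rbf_grad(a, b)
  # frozen-bandwidth objective for the finite-difference check
  pool <- c(a, b)
  D <- abs(outer(pool, pool, "-"))
  sigma <- max(stats::median(D[lower.tri(D)]), 1e-3)
  f <- function(aa, bb) mmd_oracle(aa, bb, sigma)
  eps <- 1e-6
  for (i in c(1, 5)) {
    ap <- a; ap[i] <- ap[i] + eps
    am <- a; am[i] <- am[i] - eps
    expect_equal(g$da[i], (f(ap, b) - f(am, b)) / (2 * eps),
                 tolerance = 1e-5)
  }
})

test_that("balanced subsampling equalises subject counts without splitting subjects", {
  spec <- cohort_spec(n_subjects = 175, image_shape = c(16, 16),
                      images_per_subject = c(1, 2),
                      groups = c(A = 4 / 7, B = 2 / 7, C = 1 / 7),
                      signal = signal_spec(radius = 3, contrast = 0.2,
                                           jitter = 1),
                      shortcut = shortcut_spec(size = 3, margin = 1),
                      seed = 43)
  co <- generate_cohort(spec)
  bal <- balanced_subsample(co, seed = 1)
  counts <- dplyr::count(dplyr::distinct(bal$info, subject_id,
                                         .keep_all = TRUE), group)
  expect_equal(length(unique(counts$n)), 1)
  # subject integrity: every kept subject keeps all its images
  orig_n <- table(co$info$subject_id)
  kept_n <- table(bal$info$subject_id)
  expect_true(all(kept_n == orig_n[names(kept_n)]))
  # already balanced -> identity up to ordering
  bal2 <- balanced_subsample(bal, seed = 2)
  expect_setequal(bal2$info$sample_id, bal$info$sample_id)
  # the input cohort is untouched
  expect_equal(nrow(co$info), sum(orig_n))
})

test_that("every weighted debias method at weight zero matches the baseline run", {
  spec <- tiny_spec(n_subjects = 40, seed = 44)
  co <- generate_cohort(spec)
  sp <- split_by_subject(co, c(0.6, 0.2, 0.2), seed = 44)
  sched <- fast_schedule(seed = 44, max_epochs = 3, patience = 3)
  base <- train_label_detector(sp$train, sp$val, schedule = sched)
  base_val <- tidy(base)$val_loss
  zero_runs <- list(
    distmatch_train(sp$train, sp$val, schedule = sched, penalty = "mean",
                    gamma = 0),
    distmatch_train(sp$train, sp$val, schedule = sched, penalty = "mmd",
                    gamma = 0),
    adversarial_train(sp$train, sp$val, schedule = sched, lambda = 0),
    fairalm_train(sp$train, sp$val, schedule = sched, eta = 0, rho = 0))
  for (run in zero_runs) {
    expect_equal(tidy(run)$val_loss, base_val, tolerance = 1e-6)
  }
})

test_that("fairalm logs a non-negative-stepped multiplier and its constraint", {
  spec <- tiny_spec(n_subjects = 40, seed = 45,
                    prevalence = matrix(c(0.15, 0.5, 0.85), 3, 1))
  co <- generate_cohort(spec)
  sp <- split_by_subject(co, c(0.6, 0.2, 0.2), seed = 45)
  fm <- fairalm_train(sp$train, sp$val, eta = 0.05,
                      schedule = fast_schedule(seed = 45, max_epochs = 4))
  lg <- tidy(fm)
  expect_true(all(is.finite(lg$constraint)))
  expect_true(all(is.finite(lg$mu)))
  # mu moves by eta * mean constraint each epoch
  expect_equal(diff(lg$mu), 0.05 * lg$constraint[-1], tolerance = 1e-12)
})

test_that("a large mean-matching penalty shrinks the held-out group score difference", {
  spec <- tiny_spec(n_subjects = 80, seed = 46,
                    groups = c(A = 0.5, B = 0.5),
                    prevalence = matrix(c(0.15, 0.85), 2, 1))
  co <- generate_cohort(spec)
  sp <- split_by_subject(co, c(0.6, 0.2, 0.2), seed = 46)
  sched <- fast_schedule(seed = 46, max_epochs = 5, batch_size = 48)
  base <- train_label_detector(sp$train, sp$val, schedule = sched)
  dm <- distmatch_train(sp$train, sp$val, schedule = sched,
                        penalty = "mean", gamma = 50)
  gap_of <- function(m) {
    sc <- predict_scores(m, sp$test)[, 1]
    abs(mean(sc[sp$test$info$group == "A"]) -
        mean(sc[sp$test$info$group == "B"]))
  }
  expect_lt(gap_of(dm), gap_of(base))
  # the logged penalty is never negative
  expect_true(all(tidy(dm)$penalty >= 0))
})

test_that("stratified training reduces to per-group baselines and routes strictly", {
  spec <- tiny_spec(n_subjects = 60, seed = 47,
                    groups = c(A = 0.5, B = 0.5),
                    prevalence = matrix(c(0.4, 0.6), 2, 1))
  co <- generate_cohort(spec)
  sp <- split_by_subject(co, c(0.6, 0.2, 0.2), seed = 47)
  sm <- stratified_train(sp$train, sp$val,
                         schedule = fast_schedule(seed = 47, max_epochs = 2))
  expect_named(sm$adapters, c("A", "B"))
  sc <- predict_scores(sm, sp$test)
  expect_equal(nrow(sc), length(sp$test$images))
  # routing a sample with an unknown group errors
  alien <- sp$test
  alien$info$group[1] <- "Z"
  expect_error(predict_scores(sm, alien), "Z")
  expect_error(predict_scores(sm, sp$test$images), "image_cohort")
  # single group: reduces to one baseline adapter
  one <- subset_cohort(co, which(co$info$group == "A"))
  so <- split_by_subject(one, c(0.5, 0.25, 0.25), seed = 1)
  sm1 <- stratified_train(so$train, so$val,
                          schedule = fast_schedule(seed = 47, max_epochs = 2))
  expect_length(sm1$adapters, 1)
})

test_that("stratified models win when groups have opposite signal polarity", {
  # adversarial construction: for group B the blob means "label 0" (the
  # labels are flipped after rendering), so blob presence predicts the
  # label with opposite polarity in the two groups; a pooled model that
  # cannot see the group is stuck near chance while routed per-group
  # models solve their own polarity
  spec <- cohort_spec(n_subjects = 120, image_shape = c(32, 32),
                      groups = c(A = 0.5, B = 0.5),
                      prevalence = matrix(0.5, 2, 1),
                      signal = signal_spec(radius = 5, contrast = 0.3,
                                           jitter = 1),
                      shortcut = shortcut_spec(leak_rate = 0, size = 4),
                      noise_sigma = 0.03, seed = 48)
  co <- generate_cohort(spec)
  flip <- co$info$group == "B"
  co$info$label_finding[flip] <- 1L - co$info$label_finding[flip]
  sp <- split_by_subject(co, c(0.6, 0.2, 0.2), seed = 48)
  sched <- fast_schedule(seed = 48, max_epochs = 6, batch_size = 36)
  pooled <- train_label_detector(sp$train, sp$val, schedule = sched)
  strat <- stratified_train(sp$train, sp$val, schedule = sched)
  y_te <- label_matrix(sp$test)[, 1]
  auc_pooled <- auc(predict_scores(pooled, sp$test)[, 1], y_te)
  auc_strat <- auc(predict_scores(strat, sp$test)[, 1], y_te)
  expect_gt(auc_strat, auc_pooled)
})

test_that("adversarial training engages the adversary and logs both losses", {
  spec <- tiny_spec(n_subjects = 40, seed = 49)
  co <- generate_cohort(spec)
  sp <- split_by_subject(co, c(0.6, 0.2, 0.2), seed = 49)
  sched <- fast_schedule(seed = 49, max_epochs = 3)
  adv <- adversarial_train(sp$train, sp$val, schedule = sched, lambda = 1)
  lg <- tidy(adv)
  expect_true(all(is.finite(lg$adv_loss)))
  base <- train_label_detector(sp$train, sp$val, schedule = sched)
  # a non-zero lambda changes the learned weights
  expect_false(identical(adv$weights, base$weights))
})
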