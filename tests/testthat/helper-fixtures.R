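# Shared fixtures: small, fast synthetic study conditions for unit tests.
# Images are 32x32 (or 16x16 for statistics-only checks) so the default
# four-block reference network still applies.

tiny_spec <- function(n_subjects = 60, seed = 7, image_shape = c(32, 32),
                      ...) {
  args <- list(n_subjects = n_subjects, seed = seed,
               image_shape = image_shape,
               signal = signal_spec(radius = 4, contrast = 0.3, jitter = 2),
               shortcut = shortcut_spec(size = 4, strength = 0.35))
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(cohort_spec, args)
}

fast_schedule <- function(seed = 11, max_epochs = 4, batch_size = 32,
                          patience = 4, ...) {
  train_schedule(batch_size = batch_size, max_epochs = max_epochs,
                 patience = min(patience, max_epochs), seed = seed, ...)
}

# class-mean-difference linear scorer: an independent, deliberately simple
# linear classifier on raw pixels (used for plant-and-recover checks)
linear_probe_auc <- function(train_imgs, train_y, test_imgs, test_y) {
  Xtr <- t(vapply(train_imgs, as.vector, numeric(length(train_imgs[[1]]))))
  Xte <- t(vapply(test_imgs, as.vector, numeric(length(test_imgs[[1]]))))
  w <- colMeans(Xtr[train_y == 1, , drop = FALSE]) -
    colMeans(Xtr[train_y == 0, , drop = FALSE])
  auc(Xte %*% w, test_y)
}

expect_same_array <- function(a, b, tol = 0) {
  if (tol == 0) expect_identical(a, b) else
    expect_lt(max(abs(a - b)), tol)
}
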