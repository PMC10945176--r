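# Training engine: schedules, the optimisation loop (with optional train-time
# augmentation and pluggable debiasing penalties), demographic and label
# detection tasks, weighted-F1 threshold selection, test-time-augmentation
# inference and the frozen-backbone task-transfer probe.

#' Training schedule
#'
#' Defaults follow the reference recipe: Adam with initial learning rate
#' 0.001 decayed by 5% every 2 epochs, early stopping when the validation
#' loss fails to improve (strict decrease of at least `min_delta`) for
#' `patience` consecutive epochs within `max_epochs`. The weights restored
#' at the end are those of the best validation epoch.
#'
#' @param batch_size Minibatch size (>= 1).
#' @param initial_lr Initial learning rate.
#' @param lr_decay_rate Fractional decay per period (default 0.05).
#' @param lr_decay_every Period in epochs (default 2).
#' @param patience Early-stopping patience in epochs.
#' @param max_epochs Maximum number of epochs.
#' @param min_delta Minimum validation-loss decrease counted as improvement.
#' @param seed Seed controlling weight initialisation, shuffling and
#'   train-time augmentation draws.
#' @return Object of class `train_schedule`.
#' @details The default patience/epoch budget (8 within 40) is sized for
#'   desk-scale cohorts of a few hundred images, where the loss can sit on
#'   a plateau for a dozen epochs before the signal is found; the
#'   full-scale recipes are available through [schedule_preset()].
#' @export
train_schedule <- function(batch_size = 32, initial_lr = 0.001,
                           lr_decay_rate = 0.05, lr_decay_every = 2,
                           patience = 8, max_epochs = 40, min_delta = 1e-5,
                           seed = 2021) {
  if (batch_size < 1) abort("`batch_size` must be >= 1.")
  if (lr_decay_rate < 0 || lr_decay_rate >= 1) {
    abort("`lr_decay_rate` must lie in [0, 1).")
  }
  if (patience > max_epochs) abort("`patience` must be <= `max_epochs`.")
  structure(list(batch_size = as.integer(batch_size),
                 initial_lr = initial_lr, lr_decay_rate = lr_decay_rate,
                 lr_decay_every = as.integer(lr_decay_every),
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 min_delta = min_delta, seed = as.integer(seed)),
            class = "train_schedule")
}

#' Modality presets for the training schedule
#'
#' `"cxr"`: batch 128, patience 4 within 15 epochs. `"mri"`: batch 16,
#' patience 10 within 80 epochs. Both use initial learning rate 0.001
#' decayed by 5% every 2 epochs.
#'
#' @param modality `"cxr"` or `"mri"`.
#' @param ... Overrides passed to [train_schedule()].
#' @return A `train_schedule`.
#' @export
schedule_preset <- function(modality = c("cxr", "mri"), ...) {
  modality <- match.arg(modality)
  base <- switch(modality,
    cxr = list(batch_size = 128, patience = 4, max_epochs = 15),
    mri = list(batch_size = 16, patience = 10, max_epochs = 80))
  dots <- list(...)
  base[names(dots)] <- dots
  do.call(train_schedule, base)
}

adam_init <- function(weights) {
  list(m = lapply(weights, function(w) w * 0),
       v = lapply(weights, function(w) w * 0), t = 0)
}

adam_step <- function(weights, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, skip = integer(0)) {
  state$t <- state$t + 1
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (i in seq_along(weights)) {
    if (i %in% skip) next
    g <- grads[[i]]
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g^2
    weights[[i]] <- weights[[i]] -
      lr * (state$m[[i]] / corr1) / (sqrt(state$v[[i]] / corr2) + eps)
  }
  list(weights = weights, state = state)
}

# task loss on a held-out set, in chunks, no augmentation
cnn_loss_on <- function(adapter, x, y, batch_size = 256) {
  n <- length(x)
  total <- 0
  for (idx in chunk_indices(n, batch_size)) {
    X <- images_to_matrix(x[idx], adapter$image_shape)
    total <- total + cnn_pass(adapter, X,
                              Y_ = y[idx, , drop = FALSE])$loss * length(idx)
  }
  total / n
}

# Core optimisation loop shared by the demographic and label-detection
# tasks; `debias` plugs method-specific penalty gradients into each batch.
cnn_fit <- function(adapter, x_train, y_train, x_val, y_val, schedule,
                    policy = NULL, debias = NULL, groups_train = NULL,
                    groups_val = NULL) {
  n <- length(x_train)
  if (!adapter$frozen) {
    set.seed(schedule$seed)
    adapter$weights <- init_cnn_weights(adapter$nd, adapter$channels,
                                        adapter$n_outputs)
  }
  nblocks <- length(adapter$channels)
  skip <- if (adapter$frozen) seq_len(2 * nblocks) else integer(0)
  opt <- adam_init(adapter$weights)
  dstate <- debias_init(debias, adapter, schedule$seed, groups_train)
  best <- list(loss = Inf, weights = adapter$weights, epoch = NA_integer_)
  wait <- 0
  log <- vector("list", schedule$max_epochs)
  for (epoch in 0:(schedule$max_epochs - 1)) {
    lr <- schedule$initial_lr *
      (1 - schedule$lr_decay_rate)^(epoch %/% schedule$lr_decay_every)
    set.seed(schedule$seed + 7919L * (epoch + 1L))
    ord <- sample(n)
    ep_loss <- 0
    ep_pen <- 0
    ep_con <- numeric(0)
    ep_adv <- numeric(0)
    for (idx in chunk_indices(n, schedule$batch_size)) {
      bi <- ord[idx]
      imgs <- x_train[bi]
      if (!is.null(policy)) {
        imgs <- lapply(imgs, function(im) apply_policy(im, policy)$image)
      }
      X <- images_to_matrix(imgs, adapter$image_shape)
      Yb <- y_train[bi, , drop = FALSE]
      extras <- NULL
      if (!is.null(dstate)) {
        pre <- cnn_pass(adapter, X)
        extras <- debias_batch(debias, dstate, pre$scores, pre$features, Yb,
                               groups_train[bi])
        dstate <- extras$state
        ep_pen <- ep_pen + extras$penalty * length(bi)
        if (!is.null(extras$constraint)) ep_con <- c(ep_con, extras$constraint)
        if (!is.null(extras$adv_loss)) ep_adv <- c(ep_adv, extras$adv_loss)
      }
      res <- cnn_pass(adapter, X, Y_ = Yb,
                      d_scores_extra_ = extras$d_scores,
                      d_feat_extra_ = extras$d_feat, want_grads = TRUE)
      upd <- adam_step(adapter$weights, res$grads, opt, lr, skip = skip)
      adapter$weights <- upd$weights
      opt <- upd$state
      ep_loss <- ep_loss + res$loss * length(bi)
    }
    val_loss <- cnn_loss_on(adapter, x_val, y_val)
    mu <- NA_real_
    if (!is.null(dstate) && debias$method == "fairalm") {
      dstate <- fairalm_epoch_update(debias, dstate, ep_con)
      mu <- dstate$mu
    }
    log[[epoch + 1]] <- tibble::tibble(
      epoch = epoch, lr = lr, train_loss = ep_loss / n, val_loss = val_loss,
      penalty = if (is.null(dstate)) NA_real_ else ep_pen / n,
      constraint = if (length(ep_con)) mean(ep_con) else NA_real_,
      mu = mu,
      adv_loss = if (length(ep_adv)) mean(ep_adv) else NA_real_)
    if (best$loss - val_loss >= schedule$min_delta) {
      best <- list(loss = val_loss, weights = adapter$weights,
                   epoch = epoch)
      wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= schedule$patience) break
    }
  }
  adapter$weights <- best$weights
  adapter$fitted <- TRUE
  adapter$log <- dplyr::bind_rows(log)
  adapter$best_epoch <- best$epoch
  adapter$debias_state <- dstate
  adapter
}

#' Guard against subject leakage between splits
#'
#' Errors when any subject identifier appears in more than one of the given
#' cohorts.
#'
#' @param ... Two or more `image_cohort`s.
#' @return Invisibly `TRUE` when disjoint.
#' @export
check_subject_disjoint <- function(...) {
  cohorts <- list(...)
  ids <- lapply(cohorts, function(co) unique(co$info$subject_id))
  for (i in seq_along(ids)) {
    for (j in seq_len(i - 1)) {
      shared <- intersect(ids[[i]], ids[[j]])
      if (length(shared) > 0) {
        abort(sprintf("Subject leakage between splits: %s",
                      paste(head(shared, 5), collapse = ", ")))
      }
    }
  }
  invisible(TRUE)
}

one_hot <- function(f) {
  if (!is.factor(f)) f <- factor(f)
  m <- matrix(0, length(f), nlevels(f),
              dimnames = list(NULL, levels(f)))
  m[cbind(seq_along(f), as.integer(f))] <- 1
  m
}

#' Train a demographic-attribute classifier
#'
#' Fits an adapter to predict the cohort's group attribute from images (a
#' softmax head with one output per group), optionally passing every
#' training image through the stochastic augmentation policy each epoch.
#' Train and validation cohorts must be subject-disjoint.
#'
#' @param train,val Subject-disjoint `image_cohort`s.
#' @param adapter A model adapter; default a [reference_small_cnn()] sized
#'   to the cohort.
#' @param schedule A [train_schedule()].
#' @param policy Optional [aug_policy()] applied at train time (re-sampled
#'   every epoch).
#' @param attribute Group column of the cohort info table.
#' @param debias Optional [debias_config()].
#' @return The fitted adapter, with a per-epoch training `log` (epoch,
#'   learning rate, train/validation loss) and `target_levels`.
#' @export
train_demographic_classifier <- function(train, val, adapter = NULL,
                                         schedule = train_schedule(),
                                         policy = NULL, attribute = "group",
                                         debias = NULL) {
  check_subject_disjoint(train, val)
  prep <- prepare_debias_cohort(debias, train, attribute)
  train <- prep$train
  debias <- prep$debias
  g_tr <- factor(train$info[[attribute]])
  if (nlevels(g_tr) < 2) {
    abort("Training target has a single class; cannot train a classifier.")
  }
  g_val <- factor(val$info[[attribute]], levels = levels(g_tr))
  y_tr <- one_hot(g_tr)
  y_val <- one_hot(g_val)
  if (is.null(adapter)) {
    adapter <- reference_small_cnn(dim(train$images[[1]]), nlevels(g_tr),
                                   head = "softmax",
                                   output_names = levels(g_tr))
  } else if (adapter$head == "sigmoid" && adapter$n_outputs == 1) {
    # single-node sigmoid head: binary attribute as a positive-class indicator
    if (nlevels(g_tr) != 2) {
      abort("A single-node sigmoid head needs a binary attribute.")
    }
    pos <- levels(g_tr)[2]
    y_tr <- matrix(as.integer(g_tr == pos), ncol = 1,
                   dimnames = list(NULL, pos))
    y_val <- matrix(as.integer(g_val == pos), ncol = 1,
                    dimnames = list(NULL, pos))
  }
  adapter <- cnn_fit(adapter, train$images, y_tr, val$images, y_val,
                     schedule, policy = policy, debias = debias,
                     groups_train = as.character(g_tr))
  adapter$target_levels <- levels(g_tr)
  adapter$attribute <- attribute
  adapter
}

#' Train a multi-label detector
#'
#' Fits an adapter to detect the cohort's binary labels (a sigmoid head,
#' one node per label, binary cross entropy). Labels that are constant in
#' the training cohort are refused.
#'
#' @inheritParams train_demographic_classifier
#' @return The fitted adapter with `label_names`.
#' @export
train_label_detector <- function(train, val, adapter = NULL,
                                 schedule = train_schedule(),
                                 policy = NULL, debias = NULL,
                                 attribute = "group") {
  check_subject_disjoint(train, val)
  prep <- prepare_debias_cohort(debias, train, attribute)
  train <- prep$train
  debias <- prep$debias
  y_tr <- label_matrix(train)
  y_val <- label_matrix(val)
  const <- colnames(y_tr)[apply(y_tr, 2, function(cc) length(unique(cc)) < 2)]
  if (length(const) > 0) {
    abort(sprintf("Label(s) constant in the training cohort: %s",
                  paste(const, collapse = ", ")))
  }
  if (is.null(adapter)) {
    adapter <- reference_small_cnn(dim(train$images[[1]]), ncol(y_tr),
                                   head = "sigmoid",
                                   output_names = colnames(y_tr))
  }
  groups_tr <- if (attribute %in% names(train$info)) {
    as.character(train$info[[attribute]])
  } else NULL
  adapter <- cnn_fit(adapter, train$images, y_tr, val$images, y_val,
                     schedule, policy = policy, debias = debias,
                     groups_train = groups_tr)
  adapter$label_names <- colnames(y_tr)
  adapter
}

weighted_f1 <- function(pred, truths) {
  f1c <- function(cls) {
    tp <- sum(pred == cls & truths == cls)
    fp <- sum(pred == cls & truths != cls)
    fn <- sum(pred != cls & truths == cls)
    if (2 * tp + fp + fn == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }
  (sum(truths == 1) * f1c(1) + sum(truths == 0) * f1c(0)) / length(truths)
}

#' Select per-label decision thresholds by weighted F1
#'
#' For each label, scans the 101-point grid 0.00, 0.01, ..., 1.00 and
#' returns the threshold maximising the support-weighted F1 score over the
#' positive and negative classes on the validation score set (predicted
#' positive means `score >= threshold`); ties break toward the smallest
#' threshold. A label with no positives gets threshold 0.5 with a warning.
#'
#' @param ss Validation [score_set()].
#' @return Named numeric vector of thresholds, one per label, with
#'   attribute `"weighted_f1"` (the achieved maxima).
#' @export
select_thresholds <- function(ss) {
  grid <- seq(0, 1, by = 0.01)
  labels <- ss_labels(ss)
  out <- setNames(numeric(length(labels)), labels)
  achieved <- setNames(numeric(length(labels)), labels)
  for (l in labels) {
    d <- ss[ss$label == l, ]
    if (sum(d$truth == 1) == 0) {
      warn(sprintf("Label '%s' has no positives; defaulting threshold 0.5.", l))
      out[l] <- 0.5
      achieved[l] <- NA_real_
      next
    }
    vals <- vapply(grid, function(t) weighted_f1(as.integer(d$score >= t),
                                                 d$truth), numeric(1))
    out[l] <- grid[which.max(vals)]
    achieved[l] <- max(vals)
  }
  attr(out, "weighted_f1") <- achieved
  out
}

#' Predict with test-time augmentation
#'
#' For each image, builds the test-time ensemble (`reps_per_method`
#' distorted copies per method, 12 at the default) and returns the
#' arithmetic mean of the adapter's scores over the ensemble members.
#'
#' @param adapter A fitted model adapter.
#' @param images List of arrays or an `image_cohort`.
#' @param policy An [aug_policy()].
#' @param reps_per_method Copies per method (default 3).
#' @return Score matrix (samples x outputs).
#' @export
predict_with_tta <- function(adapter, images, policy, reps_per_method = 3) {
  images <- as_image_list(images)
  ens_size <- 4 * reps_per_method
  all_imgs <- vector("list", length(images) * ens_size)
  for (i in seq_along(images)) {
    ens <- make_tta_ensemble(images[[i]], policy, reps_per_method)
    all_imgs[(i - 1) * ens_size + seq_len(ens_size)] <- ens
  }
  sc <- predict_scores(adapter, all_imgs)
  out <- matrix(NA_real_, length(images), ncol(sc))
  for (i in seq_along(images)) {
    rows <- (i - 1) * ens_size + seq_len(ens_size)
    out[i, ] <- colMeans(sc[rows, , drop = FALSE])
  }
  colnames(out) <- colnames(sc)
  out
}

#' Score a cohort with a fitted detector
#'
#' Convenience: runs [predict_scores()] (or [predict_with_tta()] when a
#' policy is supplied) on a cohort and assembles the [score_set()] joining
#' scores to the cohort's labels and group assignment.
#'
#' @param adapter Fitted label-detector adapter.
#' @param cohort An `image_cohort`.
#' @param tta_policy Optional [aug_policy()] for test-time augmentation.
#' @param reps_per_method TTA copies per method.
#' @return A [score_set()].
#' @export
detector_scores <- function(adapter, cohort, tta_policy = NULL,
                            reps_per_method = 3) {
  sc <- if (is.null(tta_policy)) {
    predict_scores(adapter, cohort$images)
  } else {
    predict_with_tta(adapter, cohort$images, tta_policy, reps_per_method)
  }
  y <- label_matrix(cohort)
  colnames(sc) <- colnames(y)
  score_set(sc, y, groups = cohort$info["group"],
            sample_id = cohort$info$sample_id,
            subject_id = cohort$info$subject_id)
}

#' Macro one-versus-rest AUC for a multi-class score matrix
#'
#' @param scores Matrix (samples x classes) with class names as columns.
#' @param groups Per-sample class assignment.
#' @return Mean of the per-class one-vs-rest AUCs (classes missing either
#'   side are skipped).
#' @export
macro_ovr_auc <- function(scores, groups) {
  lv <- colnames(scores)
  vals <- vapply(lv, function(l) {
    y <- as.integer(groups == l)
    if (length(unique(y)) < 2) return(NA_real_)
    auc(scores[, l], y)
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

# full-batch Adam on a linear softmax head over fixed features
fit_linear_head <- function(f_tr, y_tr, f_val, y_val, lr = 0.01,
                            max_epochs = 300, patience = 20,
                            min_delta = 1e-5, seed = 2021) {
  set.seed(seed)
  Fd <- ncol(f_tr)
  K <- ncol(y_tr)
  w <- list(W = matrix(rnorm(Fd * K, sd = sqrt(1 / Fd)), Fd, K),
            b = matrix(0, 1, K))
  opt <- adam_init(w)
  softmax <- function(z) {
    e <- exp(z - apply(z, 1, max))
    e / rowSums(e)
  }
  ce <- function(p, y) -mean(rowSums(y * log(pmax(p, 1e-12))))
  fwd <- function(w, f) softmax(sweep(f %*% w$W, 2, -w$b[1, ], "-"))
  best <- list(loss = Inf, w = w)
  wait <- 0
  for (ep in seq_len(max_epochs)) {
    p <- fwd(w, f_tr)
    dlg <- (p - y_tr) / nrow(f_tr)
    grads <- list(W = t(f_tr) %*% dlg, b = matrix(colSums(dlg), 1, K))
    upd <- adam_step(w, grads, opt, lr)
    w <- upd$weights
    opt <- upd$state
    vloss <- ce(fwd(w, f_val), y_val)
    if (best$loss - vloss >= min_delta) {
      best <- list(loss = vloss, w = w)
      wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= patience) break
    }
  }
  best$w
}

#' Task-transfer probe: what do the detector's features encode?
#'
#' Freezes the adapter's feature extractor, fits a fresh linear softmax
#' layer on the penultimate features to predict a demographic attribute,
#' and reports the held-out macro one-vs-rest AUC with a bootstrap
#' confidence interval. A high probe AUC indicates the backbone embedded
#' demographic information while being trained for something else.
#'
#' @param adapter A model adapter (typically a fitted label detector).
#' @param train,val,test Subject-disjoint `image_cohort`s.
#' @param attribute Group column to probe for.
#' @param boot A [bootstrap_config()] for the AUC interval.
#' @param seed Seed for the probe head initialisation.
#' @return Object of class `task_transfer_probe`: `auc`, `ci` (tibble),
#'   `scores`, `levels`, `features_unchanged` (backbone check).
#' @export
task_transfer_probe <- function(adapter, train, val, test,
                                attribute = "group",
                                boot = bootstrap_config(), seed = 2021) {
  check_subject_disjoint(train, val, test)
  g_tr <- factor(train$info[[attribute]])
  if (nlevels(g_tr) < 2) abort("Probe attribute is constant.")
  g_val <- factor(val$info[[attribute]], levels = levels(g_tr))
  g_te <- factor(test$info[[attribute]], levels = levels(g_tr))
  frozen <- freeze_backbone(adapter)
  feats_before <- penultimate_features(frozen, test$images)
  f_tr <- penultimate_features(frozen, train$images)
  f_val <- penultimate_features(frozen, val$images)
  head_w <- fit_linear_head(f_tr, one_hot(g_tr), f_val, one_hot(g_val),
                            seed = seed)
  feats_after <- penultimate_features(frozen, test$images)
  softmax <- function(z) {
    e <- exp(z - apply(z, 1, max))
    e / rowSums(e)
  }
  sc <- softmax(sweep(feats_after %*% head_w$W, 2, -head_w$b[1, ], "-"))
  colnames(sc) <- levels(g_tr)
  a <- macro_ovr_auc(sc, g_te)
  ss <- score_set(sc, one_hot(g_te), sample_id = test$info$sample_id,
                  subject_id = test$info$subject_id)
  ci <- bootstrap_ci(ss, function(d) {
    d |>
      dplyr::group_by(.data$label) |>
      dplyr::summarise(a = auc(.data$score, .data$truth),
                       .groups = "drop") |>
      dplyr::pull(a) |>
      mean()
  }, boot)
  structure(list(auc = a, ci = ci, scores = sc, levels = levels(g_tr),
                 features_unchanged = identical(feats_before, feats_after)),
            class = "task_transfer_probe")
}

#' @export
print.task_transfer_probe <- function(x, ...) {
  cat(sprintf("<task_transfer_probe> macro OVR AUC = %.3f [%.3f, %.3f]\n",
              x$auc, x$ci$lower, x$ci$upper))
  invisible(x)
}

#' @export
tidy.task_transfer_probe <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(auc = x$auc), x$ci)
}
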