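# Comparison debiasing methods, each pluggable into the training loop so
# the augmentation scheme can be layered on top of any of them:
# balanced subsampling, per-group stratified training, adversarial
# debiasing via gradient reversal, distribution-matching penalties (MMD and
# mean difference on predicted scores) and an augmented-Lagrangian method
# (FairALM) on the group-wise risk difference.

#' Debiasing configuration
#'
#' @param method One of `"baseline"`, `"balanced"`, `"stratified"`,
#'   `"adversarial"`, `"distmatch_mmd"`, `"distmatch_mean"`, `"fairalm"`,
#'   `"augmentation"`.
#' @param attribute Group attribute the method consumes (all methods except
#'   `baseline`/`augmentation` require demographic information).
#' @param lambda Adversary weight (gradient-reversal strength), >= 0.
#' @param gamma Distribution-matching penalty weight, >= 0.
#' @param eta Lagrangian multiplier step size, > 0 for `fairalm`.
#' @param rho Quadratic penalty coefficient for `fairalm`.
#' @param mu0 Initial Lagrange multiplier.
#' @param adversary_hidden Hidden width of the 2-layer adversary perceptron.
#' @param balance_seed Seed for balanced subsampling.
#' @return Object of class `debias_config`.
#' @export
debias_config <- function(method = c("baseline", "balanced", "stratified",
                                     "adversarial", "distmatch_mmd",
                                     "distmatch_mean", "fairalm",
                                     "augmentation"),
                          attribute = "group", lambda = 1, gamma = 1,
                          eta = 0.01, rho = 1, mu0 = 0,
                          adversary_hidden = 16, balance_seed = 2021) {
  method <- match.arg(method)
  if (lambda < 0 || gamma < 0 || rho < 0) {
    abort("Debias weights must be >= 0.")
  }
  if (method == "fairalm" && eta < 0) abort("`eta` must be >= 0 for fairalm.")
  structure(list(method = method, attribute = attribute, lambda = lambda,
                 gamma = gamma, eta = eta, rho = rho, mu0 = mu0,
                 adversary_hidden = as.integer(adversary_hidden),
                 balance_seed = as.integer(balance_seed)),
            class = "debias_config")
}

# balanced subsampling happens before the loop; other methods act per batch
prepare_debias_cohort <- function(debias, train, attribute) {
  if (!is.null(debias) && debias$method == "balanced") {
    train <- balanced_subsample(train, attribute = debias$attribute %||%
                                  attribute, seed = debias$balance_seed)
    debias <- NULL
  }
  if (!is.null(debias) && debias$method %in% c("baseline", "augmentation")) {
    debias <- NULL
  }
  list(train = train, debias = debias)
}

#' Balanced subsampling of the majority groups
#'
#' Downsamples every group, subject-wise and without replacement, to the
#' minority group's subject count, so each group contributes the same
#' number of subjects. A subject is never split between kept and dropped.
#' Returns a new cohort; the input is not modified.
#'
#' @param cohort An `image_cohort`.
#' @param attribute Group column.
#' @param seed Seed for the subject draw.
#' @return A new, balanced `image_cohort`.
#' @export
balanced_subsample <- function(cohort, attribute = "group", seed = 2021) {
  subj <- dplyr::distinct(cohort$info, .data$subject_id,
                          group = .data[[attribute]])
  counts <- dplyr::count(subj, .data$group)
  if (any(counts$n == 0) || nrow(counts) < 2) {
    abort("Need at least two non-empty groups to balance.")
  }
  m <- min(counts$n)
  set.seed(seed)
  keep <- subj |>
    dplyr::group_by(.data$group) |>
    dplyr::slice_sample(n = m) |>
    dplyr::pull(.data$subject_id)
  subset_cohort(cohort, which(cohort$info$subject_id %in% keep))
}

# ---- adversary (2-layer perceptron on penultimate features) ----

adv_init <- function(Fdim, G, hidden, seed) {
  set.seed(seed)
  list(W1 = matrix(rnorm(Fdim * hidden, sd = sqrt(2 / Fdim)), Fdim, hidden),
       b1 = matrix(0, 1, hidden),
       W2 = matrix(rnorm(hidden * G, sd = sqrt(1 / hidden)), hidden, G),
       b2 = matrix(0, 1, G))
}

# trains the adversary one step on (features -> group) and returns the
# gradient of its cross-entropy w.r.t. the features
adv_step <- function(adv, opt, feats, g_onehot, lr = 0.001) {
  B <- nrow(feats)
  H1 <- pmax(sweep(feats %*% adv$W1, 2, -adv$b1[1, ], "-"), 0)
  Z <- sweep(H1 %*% adv$W2, 2, -adv$b2[1, ], "-")
  P <- exp(Z - apply(Z, 1, max))
  P <- P / rowSums(P)
  loss <- -mean(rowSums(g_onehot * log(pmax(P, 1e-12))))
  dZ <- (P - g_onehot) / B
  dW2 <- t(H1) %*% dZ
  db2 <- matrix(colSums(dZ), 1)
  dH1 <- (dZ %*% t(adv$W2)) * (H1 > 0)
  dW1 <- t(feats) %*% dH1
  db1 <- matrix(colSums(dH1), 1)
  d_feats <- dH1 %*% t(adv$W1)
  upd <- adam_step(adv, list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2), opt, lr)
  list(adv = upd$weights, opt = upd$state, d_feats = d_feats, loss = loss)
}

# ---- MMD ----

#' RBF-kernel maximum mean discrepancy between two samples
#'
#' Unbiased two-sample MMD^2 estimate with a Gaussian kernel whose
#' bandwidth follows the median heuristic (median pairwise distance of the
#' pooled sample), clipped at zero. For a sample of size one the biased
#' (V-statistic) estimator is used with a warning.
#'
#' @param a,b Numeric vectors, or matrices with one sample per row.
#' @param bandwidth Kernel bandwidth; default median heuristic.
#' @return Non-negative scalar.
#' @export
mmd_rbf <- function(a, b, bandwidth = NULL) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  if (nrow(a) == 0 || nrow(b) == 0) abort("Both samples must be non-empty.")
  biased <- FALSE
  if (nrow(a) == 1 || nrow(b) == 1) {
    warn("Sample of size 1: using the biased MMD estimator.")
    biased <- TRUE
  }
  pool <- rbind(a, b)
  D2 <- as.matrix(stats::dist(pool))^2
  if (is.null(bandwidth)) {
    dvals <- sqrt(D2[lower.tri(D2)])
    bandwidth <- max(stats::median(dvals), 1e-3)
  }
  K <- exp(-D2 / (2 * bandwidth^2))
  m <- nrow(a)
  n <- nrow(b)
  Kaa <- K[seq_len(m), seq_len(m), drop = FALSE]
  Kbb <- K[m + seq_len(n), m + seq_len(n), drop = FALSE]
  Kab <- K[seq_len(m), m + seq_len(n), drop = FALSE]
  if (biased) {
    v <- mean(Kaa) + mean(Kbb) - 2 * mean(Kab)
  } else {
    v <- (sum(Kaa) - m) / (m * (m - 1)) + (sum(Kbb) - n) / (n * (n - 1)) -
      2 * mean(Kab)
  }
  max(v, 0)
}

# value and gradients of the unbiased MMD^2 between score vectors (the
# bandwidth is treated as a constant w.r.t. the scores)
mmd_rbf_grad <- function(a, b) {
  m <- length(a)
  n <- length(b)
  if (m < 2 || n < 2) {
    return(list(value = 0, da = numeric(m), db = numeric(n)))
  }
  pool <- c(a, b)
  D <- abs(outer(pool, pool, "-"))
  sigma <- max(stats::median(D[lower.tri(D)]), 1e-3)
  K <- exp(-D^2 / (2 * sigma^2))
  ia <- seq_len(m)
  ib <- m + seq_len(n)
  Kaa <- K[ia, ia]
  Kbb <- K[ib, ib]
  Kab <- K[ia, ib, drop = FALSE]
  value <- (sum(Kaa) - m) / (m * (m - 1)) + (sum(Kbb) - n) / (n * (n - 1)) -
    2 * mean(Kab)
  Daa <- outer(a, a, "-")
  Dab <- outer(a, b, "-")
  Dbb <- outer(b, b, "-")
  gKaa <- -Daa / sigma^2 * Kaa
  gKab <- -Dab / sigma^2 * Kab
  gKbb <- -Dbb / sigma^2 * Kbb
  da <- 2 * rowSums(gKaa) / (m * (m - 1)) - 2 * rowSums(gKab) / (m * n)
  db <- 2 * rowSums(gKbb) / (n * (n - 1)) + 2 * colSums(gKab) / (m * n)
  if (value <= 0) return(list(value = max(value, 0),
                              da = numeric(m), db = numeric(n)))
  list(value = value, da = da, db = db)
}

# ---- per-batch penalty dispatch used by cnn_fit ----

debias_init <- function(debias, adapter, seed, groups = NULL) {
  if (is.null(debias)) return(NULL)
  if (is.null(groups)) {
    abort(sprintf("Debias method '%s' requires a group attribute.",
                  debias$method))
  }
  state <- list(mu = debias$mu0, missing_group_batches = 0L)
  if (debias$method == "adversarial") {
    Fdim <- adapter$channels[length(adapter$channels)]
    state$adv_levels <- sort(unique(as.character(groups)))
    state$adv <- adv_init(Fdim, length(state$adv_levels),
                          debias$adversary_hidden, seed + 1L)
    state$adv_opt <- adam_init(state$adv)
  }
  state
}

group_pairs <- function(gs) {
  lv <- sort(unique(gs))
  if (length(lv) < 2) return(NULL)
  utils::combn(lv, 2, simplify = FALSE)
}

bce_terms <- function(s, y, eps = 1e-7) {
  sc <- pmin(pmax(s, eps), 1 - eps)
  list(val = -(y * log(sc) + (1 - y) * log(1 - sc)),
       dval = ifelse(s > eps & s < 1 - eps,
                     -y / sc + (1 - y) / (1 - sc), 0))
}

debias_batch <- function(debias, state, scores, features, Yb, groups_b) {
  B <- nrow(scores)
  K <- ncol(scores)
  d_scores <- NULL
  d_feat <- NULL
  penalty <- 0
  constraint <- NULL
  adv_loss <- NULL
  method <- debias$method
  pairs <- group_pairs(groups_b)
  if (is.null(pairs) && method != "adversarial") {
    state$missing_group_batches <- state$missing_group_batches + 1L
    return(list(state = state, d_scores = NULL, d_feat = NULL, penalty = 0,
                constraint = NULL, adv_loss = NULL))
  }
  if (method == "adversarial") {
    gi <- factor(groups_b, levels = state$adv_levels)
    gh <- one_hot(gi)
    stp <- adv_step(state$adv, state$adv_opt, features, gh)
    state$adv <- stp$adv
    state$adv_opt <- stp$opt
    adv_loss <- stp$loss
    # gradient reversal: the main model ascends the adversary's loss
    d_feat <- -debias$lambda * stp$d_feats
    penalty <- -debias$lambda * stp$loss
  } else if (method %in% c("distmatch_mean", "distmatch_mmd")) {
    d_scores <- matrix(0, B, K)
    for (pr in pairs) {
      ia <- which(groups_b == pr[1])
      ib <- which(groups_b == pr[2])
      for (k in seq_len(K)) {
        if (method == "distmatch_mean") {
          delta <- mean(scores[ia, k]) - mean(scores[ib, k])
          penalty <- penalty + delta^2
          d_scores[ia, k] <- d_scores[ia, k] + 2 * delta / length(ia)
          d_scores[ib, k] <- d_scores[ib, k] - 2 * delta / length(ib)
        } else {
          g <- mmd_rbf_grad(scores[ia, k], scores[ib, k])
          penalty <- penalty + g$value
          d_scores[ia, k] <- d_scores[ia, k] + g$da
          d_scores[ib, k] <- d_scores[ib, k] + g$db
        }
      }
    }
    norm <- length(pairs) * K
    penalty <- debias$gamma * penalty / norm
    d_scores <- debias$gamma * d_scores / norm
  } else if (method == "fairalm") {
    # constraint c: difference of group-mean BCE risks (max pairwise
    # difference for > 2 groups), penalised as mu*c + (rho/2) c^2
    risks <- lapply(pairs, function(pr) {
      ia <- which(groups_b == pr[1])
      ib <- which(groups_b == pr[2])
      bt <- bce_terms(scores, Yb)
      ra <- mean(bt$val[ia, , drop = FALSE])
      rb <- mean(bt$val[ib, , drop = FALSE])
      list(pr = pr, c = ra - rb, ia = ia, ib = ib, bt = bt)
    })
    sel <- risks[[which.max(vapply(risks, function(r) abs(r$c), numeric(1)))]]
    cval <- sel$c
    coef <- state$mu + debias$rho * cval
    d_scores <- matrix(0, B, K)
    d_scores[sel$ia, ] <- coef * sel$bt$dval[sel$ia, , drop = FALSE] /
      (length(sel$ia) * K)
    d_scores[sel$ib, ] <- -coef * sel$bt$dval[sel$ib, , drop = FALSE] /
      (length(sel$ib) * K)
    penalty <- state$mu * cval + debias$rho / 2 * cval^2
    constraint <- cval
  }
  list(state = state, d_scores = d_scores, d_feat = d_feat,
       penalty = penalty, constraint = constraint, adv_loss = adv_loss)
}

fairalm_epoch_update <- function(debias, state, constraints) {
  if (length(constraints) > 0) {
    state$mu <- state$mu + debias$eta * mean(constraints)
  }
  if (!is.finite(state$mu) || abs(state$mu) > 1e6) {
    abort("FairALM multiplier diverged (|mu| > 1e6); reduce eta or rho.")
  }
  state
}

# ---- user-facing wrappers (all delegate to the label-detector loop) ----

#' Adversarial debiasing (gradient reversal)
#'
#' Trains the label detector with an auxiliary adversary — a two-layer
#' perceptron predicting the group from the penultimate features — whose
#' cross-entropy is subtracted (weight `lambda`) from the task loss via
#' gradient reversal. `lambda = 0` reduces to baseline training.
#'
#' @inheritParams train_label_detector
#' @param lambda Adversary weight.
#' @return Fitted adapter; the training log records the adversary loss.
#' @export
adversarial_train <- function(train, val, adapter = NULL,
                              schedule = train_schedule(),
                              attribute = "group", lambda = 1,
                              policy = NULL) {
  train_label_detector(train, val, adapter, schedule, policy = policy,
                       attribute = attribute,
                       debias = debias_config("adversarial",
                                              attribute = attribute,
                                              lambda = lambda))
}

#' Distribution-matching debiasing
#'
#' Adds `gamma` times a distribution-matching penalty between per-group
#' predicted-score batches to the task loss: the unbiased RBF-kernel MMD^2
#' (`penalty = "mmd"`) or the squared difference of group mean scores
#' (`penalty = "mean"`). Minibatches lacking a second group contribute no
#' penalty (counted in the fit state). `gamma = 0` reduces to baseline.
#'
#' @inheritParams train_label_detector
#' @param penalty `"mmd"` or `"mean"`.
#' @param gamma Penalty weight.
#' @return Fitted adapter.
#' @export
distmatch_train <- function(train, val, adapter = NULL,
                            schedule = train_schedule(),
                            attribute = "group",
                            penalty = c("mmd", "mean"), gamma = 1,
                            policy = NULL) {
  penalty <- match.arg(penalty)
  method <- paste0("distmatch_", penalty)
  train_label_detector(train, val, adapter, schedule, policy = policy,
                       attribute = attribute,
                       debias = debias_config(method, attribute = attribute,
                                              gamma = gamma))
}

#' FairALM: augmented-Lagrangian debiasing
#'
#' Alternates model steps on `task loss + mu c + (rho/2) c^2` with
#' multiplier steps `mu <- mu + eta c`, where the constraint `c` is the
#' difference of group-mean binary cross entropy risks (max pairwise
#' difference for more than two groups). Aborts if the multiplier diverges.
#'
#' @inheritParams train_label_detector
#' @param eta Multiplier step size (> 0).
#' @param rho Quadratic penalty coefficient.
#' @param mu0 Initial multiplier.
#' @return Fitted adapter; the log records the constraint and multiplier
#'   trajectories.
#' @export
fairalm_train <- function(train, val, adapter = NULL,
                          schedule = train_schedule(), attribute = "group",
                          eta = 0.01, rho = 1, mu0 = 0, policy = NULL) {
  train_label_detector(train, val, adapter, schedule, policy = policy,
                       attribute = attribute,
                       debias = debias_config("fairalm", attribute = attribute,
                                              eta = eta, rho = rho,
                                              mu0 = mu0))
}

#' Stratified training: one model per group
#'
#' Trains a separate label detector for each group; at inference a sample
#' is scored by its own group's model. Groups missing either class in
#' train or validation are reported in the error.
#'
#' @inheritParams train_label_detector
#' @param adapter_factory Function `(image_shape, n_outputs)` returning a
#'   fresh adapter; default [reference_small_cnn()] with a sigmoid head.
#' @return Object of class `stratified_model` (list of per-group adapters).
#' @export
stratified_train <- function(train, val, attribute = "group",
                             adapter_factory = NULL,
                             schedule = train_schedule(), policy = NULL) {
  check_subject_disjoint(train, val)
  groups <- sort(unique(as.character(train$info[[attribute]])))
  y_tr <- label_matrix(train)
  bad <- character(0)
  for (g in groups) {
    for (co in list(train, val)) {
      gi <- which(co$info[[attribute]] == g)
      y <- label_matrix(co)[gi, , drop = FALSE]
      if (length(gi) == 0 || any(apply(y, 2, function(cc)
        length(unique(cc)) < 2))) {
        bad <- union(bad, g)
      }
    }
  }
  if (length(bad) > 0) {
    abort(sprintf("Group(s) missing a class in train or val: %s",
                  paste(bad, collapse = ", ")))
  }
  if (is.null(adapter_factory)) {
    adapter_factory <- function(shape, k) {
      reference_small_cnn(shape, k, head = "sigmoid",
                          output_names = colnames(y_tr))
    }
  }
  adapters <- lapply(groups, function(g) {
    tr_g <- subset_cohort(train, which(train$info[[attribute]] == g))
    val_g <- subset_cohort(val, which(val$info[[attribute]] == g))
    train_label_detector(tr_g, val_g,
                         adapter_factory(dim(train$images[[1]]), ncol(y_tr)),
                         schedule, policy = policy)
  })
  names(adapters) <- groups
  structure(list(adapters = adapters, attribute = attribute,
                 label_names = colnames(y_tr)),
            class = "stratified_model")
}

#' @rdname predict_scores
#' @param cohort For `stratified_model`, an `image_cohort` (group routing
#'   needs the group column).
#' @export
predict_scores.stratified_model <- function(adapter, images, ...) {
  if (!inherits(images, "image_cohort")) {
    abort("A stratified model scores an `image_cohort` (group routing).")
  }
  gs <- as.character(images$info[[adapter$attribute]])
  unknown <- setdiff(unique(gs), names(adapter$adapters))
  if (length(unknown) > 0) {
    abort(sprintf("No stratified model for group(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  out <- matrix(NA_real_, length(images$images),
                length(adapter$label_names))
  colnames(out) <- adapter$label_names
  for (g in unique(gs)) {
    gi <- which(gs == g)
    out[gi, ] <- predict_scores(adapter$adapters[[g]], images$images[gi])
  }
  out
}
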