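# Dependence tests between demographic attributes and image labels:
# Pearson chi-square on the group x label contingency table and a
# permutation test comparing the in-sample AUC of a linear log-odds
# (logistic regression) model against label-shuffled refits.

#' Permutation test configuration
#'
#' @param n_permutations Number of label shuffles (default 100000).
#' @param alpha Significance level (default 0.001).
#' @param seed RNG seed.
#' @return Object of class `permutation_config`.
#' @export
permutation_config <- function(n_permutations = 100000, alpha = 0.001,
                               seed = 2021) {
  if (n_permutations < 1) abort("`n_permutations` must be >= 1.")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  structure(list(n_permutations = as.integer(n_permutations),
                 alpha = alpha, seed = as.integer(seed)),
            class = "permutation_config")
}

#' Pearson chi-square test of independence
#'
#' Computes the Pearson statistic `sum (O - E)^2 / E` on a groups x
#' label-states contingency table, with `(r - 1)(c - 1)` degrees of freedom
#' and the upper-tail chi-square p-value (no continuity correction). Errors
#' when any expected count is zero.
#'
#' @param counts Contingency table: non-negative integer matrix (or a pair
#'   of vectors via `table()` beforehand).
#' @return Tibble with `statistic`, `dof`, `p_value`.
#' @examples
#' chi_square_test(matrix(c(10, 20, 20, 10), 2, byrow = TRUE))
#' @export
chi_square_test <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("`counts` must be non-negative integers.")
  }
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    abort("`counts` must have at least two rows and two columns.")
  }
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected == 0)) {
    abort(paste("Zero expected count: merge sparse categories before",
                "testing."))
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  tibble::tibble(statistic = unname(ct$statistic),
                 dof = unname(ct$parameter),
                 p_value = unname(ct$p.value))
}

#' Fit a linear log-odds (logistic regression) scorer
#'
#' One-hot encodes the categorical demographic features and fits a logistic
#' regression by iteratively reweighted least squares. Under perfect
#' separation the fit is returned with a warning flag rather than an error.
#'
#' @param features Data frame of categorical demographic features.
#' @param label Binary 0/1 outcome, both classes present.
#' @return Object of class `linear_logodds` with elements `coef`,
#'   `fitted` (in-sample probabilities), `separation_warning`. `predict()`
#'   returns probabilities for new data.
#' @export
fit_linear_logodds <- function(features, label) {
  features <- as.data.frame(features, stringsAsFactors = TRUE)
  features[] <- lapply(features, function(c) if (is.character(c)) factor(c) else c)
  y <- as.numeric(label)
  if (length(unique(y)) < 2) abort("`label` must contain both classes.")
  X <- stats::model.matrix(~., data = features)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(X, y, family = stats::binomial()),
    warning = function(w) {
      sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  structure(list(coef = fit$coefficients,
                 fitted = fit$fitted.values,
                 terms_data = features,
                 separation_warning = sep),
            class = "linear_logodds")
}

#' @export
predict.linear_logodds <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata, stringsAsFactors = TRUE)
  newdata[] <- lapply(newdata, function(c) if (is.character(c)) factor(c) else c)
  X <- stats::model.matrix(~., data = newdata)
  beta <- object$coef
  beta[is.na(beta)] <- 0
  eta <- drop(X[, names(beta), drop = FALSE] %*% beta)
  1 / (1 + exp(-eta))
}

#' Permutation AUC test of label-demographics dependence
#'
#' Fits the linear log-odds scorer on the observed labels and compares its
#' in-sample AUC against refits on uniformly permuted labels. The p-value
#' uses the add-one (Phipson-Smyth) correction,
#' `p = (1 + #\{AUC_perm >= AUC_obs\}) / (1 + n_permutations)`, so it can
#' never be exactly zero and is super-uniform under the null.
#'
#' @inheritParams fit_linear_logodds
#' @param config A [permutation_config()].
#' @return Object of class `permutation_auc_test`: list with `observed_auc`,
#'   `p_value`, `n_permutations`, `alpha`, `reject`.
#' @export
permutation_auc_test <- function(features, label,
                                 config = permutation_config()) {
  features <- as.data.frame(features, stringsAsFactors = TRUE)
  features[] <- lapply(features, function(c) if (is.character(c)) factor(c) else c)
  y <- as.numeric(label)
  if (length(unique(y)) < 2) abort("`label` must contain both classes.")
  X <- stats::model.matrix(~., data = features)
  fit_auc <- function(yy) {
    f <- suppressWarnings(stats::glm.fit(X, yy, family = stats::binomial()))
    auc(f$fitted.values, yy)
  }
  observed <- fit_auc(y)
  set.seed(config$seed)
  exceed <- 0L
  for (b in seq_len(config$n_permutations)) {
    if (fit_auc(sample(y)) >= observed) exceed <- exceed + 1L
  }
  p <- (1 + exceed) / (1 + config$n_permutations)
  structure(list(observed_auc = observed, p_value = p,
                 n_permutations = config$n_permutations,
                 alpha = config$alpha, reject = p < config$alpha),
            class = "permutation_auc_test")
}

#' @export
print.permutation_auc_test <- function(x, ...) {
  cat(sprintf("<permutation_auc_test> AUC = %.4f, p = %.4g (%d permutations)%s\n",
              x$observed_auc, x$p_value, x$n_permutations,
              if (x$reject) " *" else ""))
  invisible(x)
}

#' @export
tidy.permutation_auc_test <- function(x, ...) {
  tibble::tibble(observed_auc = x$observed_auc, p_value = x$p_value,
                 n_permutations = x$n_permutations, alpha = x$alpha,
                 reject = x$reject)
}

#' Scan all labels of a cohort for dependence on the group attribute
#'
#' Runs the chi-square test and the permutation AUC test for every label
#' against the cohort's group attribute; the association-testing experiment
#' in one call.
#'
#' @param info Cohort table (e.g. `cohort$info`): one row per sample with a
#'   `group` column and `label_*` columns.
#' @param attribute Grouping column name.
#' @param config A [permutation_config()].
#' @return Tibble with one row per label: chi-square `statistic`, `dof`,
#'   `chi2_p`, `observed_auc`, `perm_p`, `reject`.
#' @export
assoc_scan <- function(info, attribute = "group",
                       config = permutation_config()) {
  label_cols <- grep("^label_", names(info), value = TRUE)
  if (length(label_cols) == 0) abort("No `label_*` columns found.")
  purrr::map_dfr(label_cols, function(lc) {
    y <- info[[lc]]
    tab <- table(info[[attribute]], y)
    chi <- if (length(unique(y)) >= 2) {
      chi_square_test(unclass(tab))
    } else {
      tibble::tibble(statistic = NA_real_, dof = NA_real_, p_value = NA_real_)
    }
    perm <- if (length(unique(y)) >= 2) {
      pt <- permutation_auc_test(info[attribute], y, config)
      tibble::tibble(observed_auc = pt$observed_auc, perm_p = pt$p_value,
                     reject = pt$reject)
    } else {
      tibble::tibble(observed_auc = NA_real_, perm_p = NA_real_, reject = NA)
    }
    dplyr::bind_cols(tibble::tibble(label = sub("^label_", "", lc)),
                     dplyr::rename(chi, chi2_p = "p_value"), perm)
  })
}
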