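# Evaluation layer: threshold-free metrics (AUC, BCE, ECE), thresholded
# metrics (error rate, precision — the equalised-odds / equal-opportunity
# operationalisations), per-group tables, fairness gaps (max - min across
# groups by default), seeded bootstrap confidence intervals, and per-group
# ROC curves with the operating point implied by a global threshold.

#' Build a score set
#'
#' The substrate of all metrics: per-sample prediction scores joined to
#' binary truths and group assignments, in long format (one row per sample
#' and label).
#'
#' @param scores Numeric matrix (samples x labels) of probabilities in
#'   \[0, 1\]; a vector is treated as a single label.
#' @param truths Binary matrix/vector of the same shape.
#' @param groups Data frame (or named list) of per-sample group assignments,
#'   one column per grouping attribute; or a single vector (attribute
#'   `"group"`).
#' @param sample_id Optional sample identifiers (default `s1, s2, ...`).
#' @param subject_id Optional per-sample subject identifiers.
#' @return A tibble of class `score_set` with columns `sample_id`, `label`,
#'   `score`, `truth`, one column per grouping attribute and, when given,
#'   `subject_id`. Attributes: `labels`, `group_attrs`.
#' @export
score_set <- function(scores, truths, groups = NULL, sample_id = NULL,
                      subject_id = NULL) {
  scores <- as.matrix(scores)
  truths <- as.matrix(truths)
  if (!all(dim(scores) == dim(truths))) {
    abort("`scores` and `truths` must have identical dimensions.")
  }
  if (any(!is.finite(scores)) || any(scores < 0 | scores > 1)) {
    abort("`scores` must lie in [0, 1].")
  }
  if (!all(truths %in% c(0, 1))) abort("`truths` must be 0/1.")
  n <- nrow(scores)
  labels <- colnames(scores) %||% paste0("label", seq_len(ncol(scores)))
  sample_id <- sample_id %||% paste0("s", seq_len(n))
  out <- tidyr::expand_grid(sample_id = sample_id, label = labels)
  # expand_grid varies `label` fastest; align scores accordingly
  out$score <- as.vector(t(scores))
  out$truth <- as.integer(t(truths))
  group_attrs <- character(0)
  if (!is.null(groups)) {
    if (is.atomic(groups)) groups <- tibble::tibble(group = groups)
    groups <- tibble::as_tibble(groups)
    if (nrow(groups) != n) abort("`groups` must have one row per sample.")
    group_attrs <- names(groups)
    for (g in group_attrs) {
      out[[g]] <- rep(as.character(groups[[g]]), each = length(labels))
    }
  }
  if (!is.null(subject_id)) {
    out$subject_id <- rep(as.character(subject_id), each = length(labels))
  }
  structure(out, labels = labels, group_attrs = group_attrs,
            class = c("score_set", class(out)))
}

ss_labels <- function(ss) attr(ss, "labels") %||% unique(ss$label)

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive scores
#' above a random negative, with ties counted 1/2 (average ranks). Agrees
#' with trapezoidal ROC integration to numerical precision.
#'
#' @param scores Numeric scores.
#' @param truths Binary 0/1 truths.
#' @return AUC in \[0, 1\].
#' @examples
#' auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))  # 1
#' @export
auc <- function(scores, truths) {
  n1 <- sum(truths == 1)
  n0 <- sum(truths == 0)
  if (n1 == 0 || n0 == 0) {
    abort("AUC undefined: both classes must be present.")
  }
  r <- rank(scores)
  (sum(r[truths == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Binary cross entropy
#'
#' Mean of `-(y log s + (1 - y) log(1 - s))` with scores clipped to
#' `[eps, 1 - eps]`.
#'
#' @inheritParams auc
#' @param eps Clipping constant (default 1e-7).
#' @return Non-negative value.
#' @export
bce <- function(scores, truths, eps = 1e-7) {
  s <- pmin(pmax(scores, eps), 1 - eps)
  -mean(truths * log(s) + (1 - truths) * log(1 - s))
}

#' Expected calibration error
#'
#' Equal-width, right-closed bins on \[0, 1\] (scores of 0 fall in the first
#' bin): `ECE = sum_b (n_b / N) |acc_b - conf_b|`; empty bins contribute 0.
#'
#' @inheritParams auc
#' @param n_bins Number of bins (default 10).
#' @return Value in \[0, 1\].
#' @export
ece <- function(scores, truths, n_bins = 10) {
  if (n_bins < 1) abort("`n_bins` must be >= 1.")
  bin <- pmin(pmax(ceiling(scores * n_bins), 1L), n_bins)
  N <- length(scores)
  val <- 0
  for (b in unique(bin)) {
    in_b <- bin == b
    val <- val + sum(in_b) / N * abs(mean(truths[in_b]) - mean(scores[in_b]))
  }
  val
}

#' Thresholded error rate
#'
#' `(FP + FN) / N` with predicted positive defined as `score >= threshold`.
#'
#' @inheritParams auc
#' @param threshold Decision threshold in \[0, 1\].
#' @return Value in \[0, 1\].
#' @export
error_rate <- function(scores, truths, threshold) {
  pred <- as.integer(scores >= threshold)
  mean(pred != truths)
}

#' Thresholded precision
#'
#' `TP / (TP + FP)` with predicted positive defined as `score >= threshold`.
#' Returns `NA` with a warning when no sample is predicted positive
#' (undefined precision); such groups are excluded from gap computations
#' rather than imputed.
#'
#' @inheritParams error_rate
#' @return Value in \[0, 1\], or `NA` when undefined.
#' @export
precision <- function(scores, truths, threshold) {
  pred <- scores >= threshold
  if (!any(pred)) {
    warn("Precision undefined: no sample predicted positive; returning NA.")
    return(NA_real_)
  }
  sum(pred & truths == 1) / sum(pred)
}

metric_row <- function(scores, truths, threshold) {
  a <- if (length(unique(truths)) == 2) auc(scores, truths) else NA_real_
  tibble::tibble(
    n = length(scores),
    auc = a,
    bce = bce(scores, truths),
    ece = ece(scores, truths),
    error_rate = error_rate(scores, truths, threshold),
    precision = suppressWarnings(precision(scores, truths, threshold)))
}

resolve_thresholds <- function(thresholds, labels) {
  if (length(thresholds) == 1 && is.null(names(thresholds))) {
    thresholds <- setNames(rep(thresholds, length(labels)), labels)
  }
  if (!all(labels %in% names(thresholds))) {
    abort("`thresholds` must be named with one entry per label.")
  }
  thresholds[labels]
}

#' Per-group metric table
#'
#' Computes all five metrics (AUC, BCE, ECE, error rate, precision) for each
#' group of `attribute` and each label, using the same global per-label
#' thresholds for every group. AUC is omitted (NA, with a warning) for a
#' group observing a single class.
#'
#' @param ss A [score_set()].
#' @param attribute Grouping attribute (a column of `ss`).
#' @param thresholds Named per-label thresholds, or a single value.
#' @return Tibble with columns `label`, `group`, `n`, `auc`, `bce`, `ece`,
#'   `error_rate`, `precision`.
#' @export
group_metrics <- function(ss, attribute = "group", thresholds = 0.5) {
  if (!attribute %in% names(ss)) {
    abort(sprintf("Attribute '%s' not present in the score set.", attribute))
  }
  labels <- ss_labels(ss)
  thresholds <- resolve_thresholds(thresholds, labels)
  out <- ss |>
    dplyr::group_by(label = .data$label, group = .data[[attribute]]) |>
    dplyr::group_modify(function(d, key) {
      metric_row(d$score, d$truth, thresholds[[key$label]])
    }) |>
    dplyr::ungroup()
  if (any(is.na(out$auc))) {
    warn("AUC omitted for group(s) observing a single class.")
  }
  out
}

#' Fairness gap across group values
#'
#' The default disparity is the range, `max(values) - min(values)`; the
#' mean pairwise absolute difference is available as an alternative
#' aggregation. Non-finite entries (e.g. undefined precision) are dropped;
#' fewer than two finite values is an error.
#'
#' @param values Numeric per-group metric values.
#' @param method `"range"` (default) or `"mean_pairwise"`.
#' @return Non-negative gap.
#' @examples
#' fairness_gap(c(0.937, 0.954, 0.950))  # 0.017
#' @export
fairness_gap <- function(values, method = c("range", "mean_pairwise")) {
  method <- match.arg(method)
  v <- values[is.finite(values)]
  if (length(v) < 2) {
    abort("Need at least two finite group values to compute a gap.")
  }
  if (method == "range") {
    max(v) - min(v)
  } else {
    mean(abs(outer(v, v, "-"))[lower.tri(diag(length(v)))])
  }
}

#' Macro-averaged gap across labels
#'
#' Unweighted mean of per-label gaps (the multi-label "macro average
#' disparity").
#'
#' @param gaps Numeric vector of per-label gaps.
#' @return Scalar mean, ignoring NA.
#' @export
macro_average_gap <- function(gaps) mean(gaps, na.rm = TRUE)

#' Bootstrap configuration
#'
#' @param iterations Number of bootstrap replicates B (default 1000).
#' @param seed RNG seed (default 2021).
#' @param unit Resampling unit: `"sample"` (individual test samples, the
#'   default) or `"subject"`.
#' @return An object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(iterations = 1000, seed = 2021,
                             unit = c("sample", "subject")) {
  unit <- match.arg(unit)
  if (iterations < 1) abort("`iterations` must be >= 1.")
  structure(list(iterations = as.integer(iterations), seed = as.integer(seed),
                 unit = unit), class = "bootstrap_config")
}

#' Bootstrap mean and 95% confidence interval of a statistic
#'
#' Resamples units (samples or subjects) with replacement from the whole
#' score set, recomputes `statistic` on each replicate, and reports the
#' replicate mean with empirical 2.5/97.5 percentile bounds. Replicates on
#' which the statistic is undefined (error or NA) are dropped and counted.
#' Deterministic given `config$seed`.
#'
#' @param ss A [score_set()] (or any tibble with `sample_id`).
#' @param statistic Function taking a resampled score set and returning a
#'   scalar.
#' @param config A [bootstrap_config()].
#' @return Tibble with `estimate` (point statistic on the full set),
#'   `boot_mean`, `lower`, `upper`, `n_dropped`.
#' @export
bootstrap_ci <- function(ss, statistic, config = bootstrap_config()) {
  unit_col <- if (config$unit == "subject") "subject_id" else "sample_id"
  if (!unit_col %in% names(ss)) {
    abort(sprintf("Column '%s' required for unit '%s'.", unit_col, config$unit))
  }
  ids <- unique(ss[[unit_col]])
  idx_of <- split(seq_len(nrow(ss)), ss[[unit_col]])
  point <- tryCatch(statistic(ss), error = function(e) NA_real_)
  set.seed(config$seed)
  vals <- rep(NA_real_, config$iterations)
  for (b in seq_len(config$iterations)) {
    drawn <- sample(ids, length(ids), replace = TRUE)
    rep_ss <- ss[unlist(idx_of[drawn], use.names = FALSE), , drop = FALSE]
    vals[b] <- tryCatch(suppressWarnings(statistic(rep_ss)),
                        error = function(e) NA_real_)
  }
  ok <- is.finite(vals)
  qs <- if (any(ok)) quantile(vals[ok], c(0.025, 0.975), names = FALSE) else
    c(NA_real_, NA_real_)
  tibble::tibble(estimate = point,
                 boot_mean = if (any(ok)) mean(vals[ok]) else NA_real_,
                 lower = qs[1], upper = qs[2],
                 n_dropped = sum(!ok))
}

#' Grouped fairness report with bootstrap confidence intervals
#'
#' The grouped-disparity machine: per-group values of the five metrics, the
#' per-label fairness gap for each metric, the macro-averaged gap across
#' labels, and seeded bootstrap CIs for every gap.
#'
#' @inheritParams group_metrics
#' @param boot A [bootstrap_config()]; `NULL` skips the bootstrap.
#' @param gap_method Passed to [fairness_gap()].
#' @return Object of class `gap_report`: list with `per_group`, `gaps`
#'   (per label x metric with CI columns), `macro` (per metric), plus the
#'   call metadata. `tidy()` returns the gaps, `glance()` the macro
#'   averages, `autoplot()` a value-versus-gap scatter.
#' @export
gap_report <- function(ss, attribute = "group", thresholds = 0.5,
                       boot = bootstrap_config(), gap_method = "range") {
  labels <- ss_labels(ss)
  thresholds <- resolve_thresholds(thresholds, labels)
  per_group <- suppressWarnings(group_metrics(ss, attribute, thresholds))
  metric_names <- c("auc", "bce", "ece", "error_rate", "precision")
  gap_tbl <- function(pg) {
    pg |>
      tidyr::pivot_longer(dplyr::all_of(metric_names), names_to = "metric") |>
      dplyr::group_by(.data$label, .data$metric) |>
      dplyr::summarise(gap = tryCatch(fairness_gap(.data$value, gap_method),
                                      error = function(e) NA_real_),
                       .groups = "drop")
  }
  gaps <- gap_tbl(per_group)
  macro <- gaps |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(macro_gap = macro_average_gap(.data$gap),
                     .groups = "drop")
  if (!is.null(boot)) {
    set.seed(boot$seed)
    unit_col <- if (boot$unit == "subject") "subject_id" else "sample_id"
    ids <- unique(ss[[unit_col]])
    idx_of <- split(seq_len(nrow(ss)), ss[[unit_col]])
    reps <- vector("list", boot$iterations)
    for (b in seq_len(boot$iterations)) {
      drawn <- sample(ids, length(ids), replace = TRUE)
      rep_ss <- ss[unlist(idx_of[drawn], use.names = FALSE), , drop = FALSE]
      attr(rep_ss, "labels") <- labels
      pg <- tryCatch(
        suppressWarnings(group_metrics(rep_ss, attribute, thresholds)),
        error = function(e) NULL)
      if (is.null(pg)) next
      g <- gap_tbl(pg)
      g$rep <- b
      reps[[b]] <- g
    }
    repg <- dplyr::bind_rows(reps)
    ci <- repg |>
      dplyr::group_by(.data$label, .data$metric) |>
      dplyr::summarise(
        boot_mean = mean(.data$gap, na.rm = TRUE),
        lower = quantile(.data$gap, 0.025, na.rm = TRUE, names = FALSE),
        upper = quantile(.data$gap, 0.975, na.rm = TRUE, names = FALSE),
        n_dropped = boot$iterations - sum(is.finite(.data$gap)),
        .groups = "drop")
    gaps <- dplyr::left_join(gaps, ci, by = c("label", "metric"))
    macro_ci <- repg |>
      dplyr::group_by(.data$metric, .data$rep) |>
      dplyr::summarise(m = macro_average_gap(.data$gap), .groups = "drop") |>
      dplyr::group_by(.data$metric) |>
      dplyr::summarise(
        boot_mean = mean(.data$m, na.rm = TRUE),
        lower = quantile(.data$m, 0.025, na.rm = TRUE, names = FALSE),
        upper = quantile(.data$m, 0.975, na.rm = TRUE, names = FALSE),
        .groups = "drop")
    macro <- dplyr::left_join(macro, macro_ci, by = "metric")
  }
  structure(list(per_group = per_group, gaps = gaps, macro = macro,
                 attribute = attribute, thresholds = thresholds,
                 gap_method = gap_method, boot = boot),
            class = "gap_report")
}

#' @export
print.gap_report <- function(x, ...) {
  cat(sprintf("<gap_report> attribute '%s' (%s gaps)\n", x$attribute,
              x$gap_method))
  print(x$macro)
  invisible(x)
}

#' @export
tidy.gap_report <- function(x, ...) x$gaps

#' @export
glance.gap_report <- function(x, ...) x$macro

#' @export
autoplot.gap_report <- function(object, ...) {
  pg <- object$per_group |>
    tidyr::pivot_longer(c("auc", "bce", "ece", "error_rate", "precision"),
                        names_to = "metric")
  dat <- dplyr::left_join(pg, object$gaps, by = c("label", "metric"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$gap, y = .data$value,
                                    colour = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::facet_grid(metric ~ label, scales = "free") +
    ggplot2::labs(x = "fairness gap", y = "metric value",
                  title = sprintf("Per-group performance vs. gap ('%s')",
                                  object$attribute)) +
    ggplot2::theme_minimal()
}

#' Per-group ROC curves with the global-threshold operating point
#'
#' Returns per-group, per-label ROC point lists (one point per distinct
#' score, plus the (0,0) origin) and the (FPR, TPR) operating point implied
#' by the global per-label threshold. Trapezoidal integration of the curve
#' reproduces [auc()].
#'
#' @inheritParams group_metrics
#' @return Object of class `roc_report`: list with `curves` (tibble `label`,
#'   `group`, `fpr`, `tpr`) and `cutoffs` (tibble `label`, `group`,
#'   `threshold`, `fpr`, `tpr`).
#' @export
roc_with_cutoff <- function(ss, attribute = "group", thresholds = 0.5) {
  labels <- ss_labels(ss)
  thresholds <- resolve_thresholds(thresholds, labels)
  one_curve <- function(scores, truths) {
    o <- order(scores, decreasing = TRUE)
    s <- scores[o]
    y <- truths[o]
    keep <- c(s[-length(s)] != s[-1], TRUE)  # last index of each tie group
    tp <- cumsum(y)[keep]
    fp <- cumsum(1 - y)[keep]
    tibble::tibble(fpr = c(0, fp / sum(1 - truths)),
                   tpr = c(0, tp / sum(truths)))
  }
  grouped <- ss |>
    dplyr::group_by(label = .data$label, group = .data[[attribute]])
  curves <- grouped |>
    dplyr::group_modify(function(d, key) {
      if (length(unique(d$truth)) < 2) {
        warn(sprintf("ROC omitted for group '%s' (single class).", key$group))
        return(tibble::tibble(fpr = numeric(0), tpr = numeric(0)))
      }
      one_curve(d$score, d$truth)
    }) |>
    dplyr::ungroup()
  cutoffs <- grouped |>
    dplyr::group_modify(function(d, key) {
      thr <- thresholds[[key$label]]
      pred <- d$score >= thr
      tibble::tibble(
        threshold = thr,
        fpr = if (any(d$truth == 0)) mean(pred[d$truth == 0]) else NA_real_,
        tpr = if (any(d$truth == 1)) mean(pred[d$truth == 1]) else NA_real_)
    }) |>
    dplyr::ungroup()
  structure(list(curves = curves, cutoffs = cutoffs, attribute = attribute),
            class = "roc_report")
}

#' @export
print.roc_report <- function(x, ...) {
  cat(sprintf("<roc_report> attribute '%s'\n", x$attribute))
  print(x$cutoffs)
  invisible(x)
}

#' @export
autoplot.roc_report <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$fpr, y = .data$tpr,
                               colour = .data$group)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(data = object$cutoffs, shape = 4, size = 3) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::facet_wrap(~label) +
    ggplot2::labs(x = "false positive rate", y = "true positive rate") +
    ggplot2::theme_minimal()
}
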