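# End-to-end experiment orchestration: simulate -> association tests ->
# demographic classification (with/without augmentation) -> label detection
# (with/without augmentation, optional debiasing) with thresholding,
# test-time augmentation and grouped disparity reports -> task-transfer
# probe. Every stage is seeded from the single experiment seed; failures
# are recorded per stage without discarding earlier outputs.

#' Experiment configuration
#'
#' Bundles everything [run_experiment()] needs. The defaults are the
#' desk-scale study conditions: the default synthetic cohort, the
#' 2D (chest-radiograph-like) augmentation preset, the reference CNN and
#' the default training schedule.
#'
#' @param spec A [cohort_spec()].
#' @param fractions Subject-wise train/val/test fractions.
#' @param schedule A [train_schedule()]; defaults to `train_schedule(seed =
#'   seed)`.
#' @param policy An [aug_policy()]; defaults to the preset matching the
#'   spec's dimensionality.
#' @param debias Optional [debias_config()] applied to the label detector.
#' @param perm A [permutation_config()] for the association stage.
#' @param boot A [bootstrap_config()] for disparity intervals.
#' @param tta Whether to also score the test set with test-time
#'   augmentation.
#' @param reps_per_method TTA copies per method.
#' @param probe_boot Bootstrap config for the task-transfer probe.
#' @param seed Master seed.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(spec = cohort_spec(),
                              fractions = c(0.6, 0.2, 0.2),
                              schedule = NULL, policy = NULL, debias = NULL,
                              perm = permutation_config(n_permutations = 1000),
                              boot = bootstrap_config(iterations = 200),
                              tta = TRUE, reps_per_method = 3,
                              probe_boot = bootstrap_config(iterations = 200),
                              seed = 2021) {
  nd <- length(spec$image_shape)
  policy <- policy %||% preset_policy(if (nd == 2) "cxr_2d" else "mri_3d")
  schedule <- schedule %||% train_schedule(seed = seed)
  structure(list(spec = spec, fractions = fractions, schedule = schedule,
                 policy = policy, debias = debias, perm = perm, boot = boot,
                 tta = tta, reps_per_method = reps_per_method,
                 probe_boot = probe_boot, seed = as.integer(seed)),
            class = "experiment_config")
}

#' Run the full audit pipeline on a synthetic cohort
#'
#' Executes, in order: cohort simulation and subject-wise splitting;
#' association tests between group and labels; demographic classification
#' trained without and with the augmentation policy (held-out macro
#' one-vs-rest AUCs); label detection without and with augmentation
#' (validation-selected thresholds, plain and test-time-augmented scoring,
#' grouped disparity reports); and the task-transfer probe of both
#' detectors. A stage failure is recorded in the manifest and dependent
#' stages are skipped; earlier outputs are preserved.
#'
#' @param config An [experiment_config()].
#' @return Object of class `run_manifest`: list with `config`, `stages`
#'   (status tibble), `results` (per-stage outputs) and `summary` (tibble
#'   comparing the unaugmented and augmented runs).
#' @export
run_experiment <- function(config = experiment_config()) {
  results <- list()
  status <- list()
  run_stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(list(ok = TRUE, value = force(expr)),
                    error = function(e) list(ok = FALSE, value = NULL,
                                             msg = conditionMessage(e)))
    status[[name]] <<- tibble::tibble(
      stage = name, ok = out$ok,
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
      error = if (out$ok) NA_character_ else out$msg)
    if (!out$ok) return(NULL)
    out$value
  }

  sim <- run_stage("simulate", {
    cohort <- generate_cohort(config$spec)
    splits <- split_by_subject(cohort, config$fractions, seed = config$seed)
    list(cohort = cohort, splits = splits)
  })
  if (!is.null(sim)) results$cohort <- sim$cohort

  results$assoc <- run_stage("assoc", {
    assoc_scan(sim$cohort$info, config = config$perm)
  })

  demo <- run_stage("demographics", {
    tr <- sim$splits$train
    va <- sim$splits$val
    te <- sim$splits$test
    g_te <- te$info$group
    clf0 <- train_demographic_classifier(tr, va, schedule = config$schedule)
    clf1 <- train_demographic_classifier(tr, va, schedule = config$schedule,
                                         policy = config$policy)
    list(auc_noaug = macro_ovr_auc(predict_scores(clf0, te), g_te),
         auc_aug = macro_ovr_auc(predict_scores(clf1, te), g_te),
         clf_noaug = clf0, clf_aug = clf1)
  })
  results$demographics <- demo

  det <- run_stage("detection", {
    tr <- sim$splits$train
    va <- sim$splits$val
    te <- sim$splits$test
    fit_one <- function(policy) {
      m <- train_label_detector(tr, va, schedule = config$schedule,
                                policy = policy, debias = config$debias)
      val_ss <- detector_scores(m, va)
      thr <- suppressWarnings(select_thresholds(val_ss))
      te_ss <- detector_scores(m, te)
      rep0 <- gap_report(te_ss, thresholds = thr, boot = config$boot)
      out <- list(model = m, thresholds = thr, test_scores = te_ss,
                  report = rep0,
                  test_auc = mean(vapply(ss_labels(te_ss), function(l) {
                    d <- te_ss[te_ss$label == l, ]
                    auc(d$score, d$truth)
                  }, numeric(1))))
      if (config$tta) {
        tta_ss <- detector_scores(m, te, tta_policy = config$policy,
                                  reps_per_method = config$reps_per_method)
        out$tta_report <- gap_report(tta_ss, thresholds = thr,
                                     boot = config$boot)
      }
      out
    }
    list(noaug = fit_one(NULL), aug = fit_one(config$policy))
  })
  results$detection <- det

  probe <- run_stage("probe", {
    tr <- sim$splits$train
    va <- sim$splits$val
    te <- sim$splits$test
    list(noaug = task_transfer_probe(det$noaug$model, tr, va, te,
                                     boot = config$probe_boot,
                                     seed = config$seed),
         aug = task_transfer_probe(det$aug$model, tr, va, te,
                                   boot = config$probe_boot,
                                   seed = config$seed))
  })
  results$probe <- probe

  summary <- NULL
  if (!is.null(demo) && !is.null(det) && !is.null(probe)) {
    er_gap <- function(rep) {
      rep$gaps$gap[rep$gaps$metric == "error_rate"][1]
    }
    summary <- tibble::tibble(
      quantity = c("demographic_auc", "label_auc", "probe_auc",
                   "error_rate_gap"),
      unaugmented = c(demo$auc_noaug, det$noaug$test_auc, probe$noaug$auc,
                      er_gap(det$noaug$report)),
      augmented = c(demo$auc_aug, det$aug$test_auc, probe$aug$auc,
                    er_gap(det$aug$report)))
  }
  structure(list(config = config, stages = dplyr::bind_rows(status),
                 results = results, summary = summary),
            class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>\n")
  print(x$stages)
  if (!is.null(x$summary)) print(x$summary)
  invisible(x)
}
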