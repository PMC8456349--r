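test_that("roc_auc matches hand examples and handles degenerate input", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(0.3, 6), c(0, 1, 0, 1, 0, 1))$auc, 0.5)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
  rc <- roc_auc(c(0.2, 0.6, 0.4, 0.9), c(0, 0, 1, 1))
  expect_equal(rc$roc_points$fpr[1], 0)
  expect_equal(utils::tail(rc$roc_points$tpr, 1), 1)
  expect_true(all(diff(rc$roc_points$fpr) >= 0))
  expect_true(all(diff(rc$roc_points$tpr) >= 0))
})

test_that("roc_auc equals the brute-force pairwise estimator with ties", {
  set.seed(7)
  for (i in 1:60) {
    n <- sample(4:60, 1)
    labels <- c(0, 1, stats::rbinom(n - 2, 1, 0.4))
    scores <- round(stats::rnorm(n), 1)  # coarse rounding forces ties
    expect_equal(roc_auc(scores, labels)$auc,
                 brute_force_auc(scores, labels))
  }
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(8)
  scores <- stats::rnorm(80)
  labels <- stats::rbinom(80, 1, 0.3)
  labels[1:2] <- c(0, 1)
  a0 <- roc_auc(scores, labels)$auc
  expect_equal(roc_auc(2 * scores + 5, labels)$auc, a0)
  expect_equal(roc_auc(exp(scores), labels)$auc, a0)
  expect_equal(roc_auc(stats::plogis(scores), labels)$auc, a0)
})

test_that("confusion metrics match the contingency-table arithmetic", {
  # TP=3, FP=1, FN=2, TN=10
  pred <- c(rep(1, 3), rep(0, 2), rep(1, 1), rep(0, 10))
  labels <- c(rep(1, 5), rep(0, 11))
  cm <- confusion_metrics(pred, labels)
  expect_equal(cm$sensitivity, 0.6)
  expect_equal(cm$specificity, 10 / 11)
  expect_equal(cm$f1, 2 / 3)
  perfect <- confusion_metrics(labels, labels)
  expect_equal(c(perfect$f1, perfect$sensitivity, perfect$specificity),
               c(1, 1, 1))
  allneg <- confusion_metrics(rep(0, 16), labels)
  expect_equal(c(allneg$f1, allneg$sensitivity, allneg$specificity),
               c(0, 0, 1))
  expect_error(confusion_metrics(c(0, 1), c(0, 1, 1)), "length")
})

test_that("fold assignments form a stratified partition", {
  labels <- c(rep(1L, 20), rep(0L, 180))
  folds <- make_folds(labels, k = 4, seed = 1)
  expect_equal(sort(unique(folds)), 1:4)
  expect_length(folds, 200)
  for (f in 1:4) {
    expect_equal(sum(labels[folds == f]), 5)  # stratification
    expect_equal(sum(folds == f), 50)
  }
})

test_that("patient partition keeps each patient inside one fold", {
  sim <- shared_cohort()
  cl <- clean_cohort(sim$sessions)
  ft <- build_feature_table(cl$sessions)
  folds <- make_folds(ft$labels, k = 4, seed = 2, partition = "patient",
                      patient_id = ft$patient_id)
  spread <- tapply(folds, ft$patient_id, function(x) length(unique(x)))
  expect_true(all(spread == 1))
  expect_equal(sort(unique(folds)), 1:4)
  expect_error(make_folds(ft$labels, k = 4, partition = "patient"),
               "patient_id")
})

test_that("cross-validation separates signal from permuted labels", {
  sim <- shared_cohort()
  cl <- clean_cohort(sim$sessions)
  ft <- build_feature_table(cl$sessions)
  spec <- model_spec("perceptron",
                     config = perceptron_config(max_iterations = 10))
  ev <- cross_validate(ft$features, ft$labels, spec, k = 4, repeats = 2,
                       seed = 5)
  expect_s3_class(ev, "hd_eval")
  expect_equal(nrow(ev$per_fold), 8)
  expect_true(ev$mean_auc > 0.7)
  expect_true(all(ev$per_fold$n_pos_test > 0))
  expect_true(ev$specificity > ev$sensitivity)  # imbalanced operating point
  # reproducibility in the root seed
  ev2 <- cross_validate(ft$features, ft$labels, spec, k = 4, repeats = 2,
                        seed = 5)
  expect_identical(ev$per_fold, ev2$per_fold)
})

test_that("patient-level evaluation stays close to session-level", {
  sim <- shared_cohort()
  cl <- clean_cohort(sim$sessions)
  ft <- build_feature_table(cl$sessions)
  spec <- model_spec("perceptron",
                     config = perceptron_config(max_iterations = 10))
  ev_p <- cross_validate(ft$features, ft$labels, spec, k = 4, repeats = 2,
                         partition = "patient", patient_id = ft$patient_id,
                         seed = 5)
  expect_gt(ev_p$mean_auc, 0.6)
})

test_that("the cutoff experiment returns one evaluation per cutoff", {
  sim <- shared_cohort()
  cl <- clean_cohort(sim$sessions)
  spec <- model_spec("perceptron",
                     config = perceptron_config(max_iterations = 5))
  out <- run_cutoff_experiment(cl$sessions, cutoffs = c(0, 20, 60),
                               spec = spec, repeats = 1, seed = 3)
  expect_equal(nrow(out$summary), 3)
  expect_equal(out$summary$cutoff_min, c(0, 20, 60))
  expect_true(all(out$summary$n_positive > 0))
  # later cutoffs can only shrink the usable cohort
  expect_true(all(diff(out$summary$n_sessions) <= 0))
})

test_that("probability consistency flags only sessions above threshold everywhere", {
  sim <- shared_cohort()
  cl <- clean_cohort(sim$sessions)
  spec <- model_spec("perceptron",
                     config = perceptron_config(max_iterations = 5))
  expect_warning(
    out <- probability_consistency(cl$sessions, cutoffs = c(0, 10),
                                   spec = spec, n_sample = 10000, seed = 4),
    "exceeds")
  expect_equal(ncol(out$probabilities), 2)
  ok <- !is.na(out$probabilities[, 1]) & !is.na(out$probabilities[, 2])
  manual <- rownames(out$probabilities)[unname(ok &
    out$probabilities[, 1] > 0.8 & out$probabilities[, 2] > 0.8)]
  expect_setequal(out$consistent, manual)
  # threshold 0 admits every fully-scored session
  out0 <- probability_consistency(cl$sessions[1:60], cutoffs = c(0, 10),
                                  spec = spec, threshold = 0,
                                  n_sample = 30, seed = 4)
  scored <- unname(apply(out0$probabilities, 1,
                         function(v) all(!is.na(v))))
  expect_setequal(out0$consistent, rownames(out0$probabilities)[scored])
})

test_that("negative-session truncation modes run and differ from the baseline", {
  sim <- shared_cohort()
  cl <- clean_cohort(sim$sessions)
  spec <- model_spec("perceptron",
                     config = perceptron_config(max_iterations = 5))
  base <- run_truncation_experiment(cl$sessions, "none", spec = spec,
                                    repeats = 1, seed = 6)
  fx <- run_truncation_experiment(cl$sessions, "fixed", 198, spec = spec,
                                  repeats = 1, seed = 6)
  un <- run_truncation_experiment(cl$sessions, "uniform", c(180, 210),
                                  spec = spec, repeats = 1, seed = 6)
  expect_s3_class(fx, "hd_eval")
  expect_s3_class(un, "hd_eval")
  # determinism per seed
  fx2 <- run_truncation_experiment(cl$sessions, "fixed", 198, spec = spec,
                                   repeats = 1, seed = 6)
  expect_identical(fx$per_fold, fx2$per_fold)
  # mode "none" equals the plain evaluation on truncated sessions
  ft <- build_feature_table(cl$sessions)
  plain <- cross_validate(ft$features, ft$labels, spec, k = 4, repeats = 1,
                          seed = 6)
  expect_identical(base$per_fold, plain$per_fold)
})
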