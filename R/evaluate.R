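# Cross-validated evaluation: ROC/AUC, confusion metrics, repeated k-fold
# with session- or patient-level partitioning, and the cutoff-timing /
# truncation / probability-consistency experiment drivers.

#' ROC curve and AUC
#'
#' The AUC equals the Mann-Whitney probability that a random positive
#' outscores a random negative, with ties counted one half; it is computed
#' from rank sums. ROC points come from a threshold sweep over the distinct
#' scores.
#'
#' @param scores real-valued classifier scores (higher = more positive).
#' @param labels 0/1 labels; both classes must be present.
#' @return list with `auc` and `roc_points` (data.frame of `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  r <- rank(scores)  # midranks handle ties as 1/2
  auc <- (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(th) sum(scores >= th & labels == 1) / npos,
                numeric(1))
  fpr <- vapply(thr, function(th) sum(scores >= th & labels == 0) / nneg,
                numeric(1))
  list(auc = auc,
       roc_points = data.frame(fpr = c(0, fpr), tpr = c(0, tpr)))
}

#' Confusion-table metrics at a fixed operating point
#'
#' @param pred 0/1 predictions.
#' @param labels 0/1 labels of the same length.
#' @return list with `f1` (0 when there are no true positives),
#'   `sensitivity`, `specificity` and `precision`.
#' @export
confusion_metrics <- function(pred, labels) {
  if (length(pred) != length(labels)) {
    stop("length mismatch", call. = FALSE)
  }
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (tp == 0) 0 else 2 * prec * sens / (prec + sens)
  list(f1 = f1, sensitivity = sens, specificity = spec, precision = prec)
}

#' Fold assignment for cross-validation
#'
#' `"session"` partition stratifies folds by label so every fold holds both
#' classes at the cohort's positive rate; `"patient"` partition assigns all
#' of a patient's sessions to the same fold (interpatient evaluation).
#'
#' @param labels 0/1 labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @param partition `"session"` or `"patient"`.
#' @param patient_id patient ids (required for the patient partition).
#' @return integer fold assignment in `1..k` per example.
#' @export
make_folds <- function(labels, k = 4, seed = 1,
                       partition = c("session", "patient"),
                       patient_id = NULL) {
  partition <- match.arg(partition)
  n <- length(labels)
  set.seed(substream_seed(seed, paste0("folds-", partition)))
  folds <- integer(n)
  if (partition == "session") {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      folds[idx] <- (seq_along(idx) %% k + 1L)[sample.int(length(idx))]
    }
  } else {
    if (is.null(patient_id)) {
      stop("patient partition needs patient_id", call. = FALSE)
    }
    pats <- unique(patient_id)
    if (length(pats) < k) {
      stop("patient partition needs >= k patients", call. = FALSE)
    }
    pf <- stats::setNames((seq_along(pats) %% k + 1L)[sample.int(length(pats))],
                          sample(pats))
    folds <- as.integer(pf[patient_id])
  }
  folds
}

# inject a deterministic per-fit seed into a model spec
spec_with_seed <- function(spec, s) {
  a <- spec$args
  if (spec$model %in% c("perceptron", "rusboost")) {
    cfg <- a$config
    if (is.null(cfg)) {
      cfg <- if (spec$model == "perceptron") perceptron_config() else
        rusboost_config()
    }
    cfg$seed <- as.integer(s %% .Machine$integer.max)
    a$config <- cfg
  } else if (spec$model == "forest") {
    a$seed <- as.integer(s %% .Machine$integer.max)
  }
  structure(list(model = spec$model, args = a), class = "hd_model_spec")
}

#' Repeated stratified cross-validation of a classifier
#'
#' Per repeat, a fresh seed-derived fold shuffle; per fold, the model (and
#' its standardization, for the perceptron) is fit on the training folds
#' only and scored on the held-out fold. AUC, F1, sensitivity and
#' specificity are computed per fold at the model's native threshold and
#' aggregated as mean and SD over all folds x repeats. A held-out fold with
#' a single class skips AUC with a warning.
#'
#' @param X feature matrix.
#' @param labels 0/1 labels.
#' @param spec a [model_spec()].
#' @param k folds (default 4).
#' @param repeats repeats with different fold shuffles (default 3).
#' @param partition `"session"` (label-stratified) or `"patient"`.
#' @param patient_id patient ids, needed for the patient partition.
#' @param seed integer root seed.
#' @return object of class `hd_eval`: `mean_auc`, `sd_auc`, `f1`,
#'   `sensitivity`, `specificity`, `per_fold` (one row per fold x repeat),
#'   `roc_points` (vertically averaged ROC at a fixed FPR grid), and the
#'   configuration echo.
#' @export
cross_validate <- function(X, labels, spec = model_spec("perceptron"),
                           k = 4, repeats = 3,
                           partition = c("session", "patient"),
                           patient_id = NULL, seed = 1) {
  partition <- match.arg(partition)
  stopifnot(k >= 2, nrow(X) == length(labels))
  fpr_grid <- seq(0, 1, by = 0.02)
  per_fold <- list()
  tpr_curves <- list()
  for (r in seq_len(repeats)) {
    rep_seed <- substream_seed(seed, paste0("cv-rep-", r))
    folds <- make_folds(labels, k, rep_seed, partition, patient_id)
    for (f in seq_len(k)) {
      tr <- folds != f
      te <- !tr
      fit <- train_model(X[tr, , drop = FALSE], labels[tr],
                         spec_with_seed(spec, rep_seed + f))
      sc <- model_score(fit, X[te, , drop = FALSE])
      pred <- as.integer(sc > native_threshold(fit))
      cm <- confusion_metrics(pred, labels[te])
      if (length(unique(labels[te])) < 2) {
        warning("fold ", f, " repeat ", r,
                " holds a single class; AUC skipped")
        auc <- NA_real_
      } else {
        rc <- roc_auc(sc, labels[te])
        auc <- rc$auc
        # step-function TPR at the fixed FPR grid for vertical averaging
        tpr_curves[[length(tpr_curves) + 1L]] <-
          vapply(fpr_grid, function(g) max(rc$roc_points$tpr[
            rc$roc_points$fpr <= g]), numeric(1))
      }
      per_fold[[length(per_fold) + 1L]] <- data.frame(
        repeat_ = r, fold = f, auc = auc, f1 = cm$f1,
        sensitivity = cm$sensitivity, specificity = cm$specificity,
        n_test = sum(te), n_pos_test = sum(labels[te] == 1)
      )
    }
  }
  pf <- do.call(rbind, per_fold)
  mean_roc <- if (length(tpr_curves)) {
    data.frame(fpr = fpr_grid, tpr = colMeans(do.call(rbind, tpr_curves)))
  } else {
    data.frame(fpr = numeric(0), tpr = numeric(0))
  }
  structure(
    list(mean_auc = mean(pf$auc, na.rm = TRUE),
         sd_auc = stats::sd(pf$auc, na.rm = TRUE),
         f1 = mean(pf$f1, na.rm = TRUE),
         sensitivity = mean(pf$sensitivity, na.rm = TRUE),
         specificity = mean(pf$specificity, na.rm = TRUE),
         per_fold = pf, roc_points = mean_roc,
         config = list(spec = spec, k = k, repeats = repeats,
                       partition = partition, seed = seed)),
    class = "hd_eval"
  )
}

#' @export
print.hd_eval <- function(x, ...) {
  cat(sprintf(
    paste0("<hd_eval> %s, %d-fold x %d repeats (%s partition)\n",
           "  mean AUC %.3f (SD %.3f)  F1 %.3f  sens %.3f  spec %.3f\n"),
    x$config$spec$model, x$config$k, x$config$repeats, x$config$partition,
    x$mean_auc, x$sd_auc, x$f1, x$sensitivity, x$specificity))
  invisible(x)
}

#' Cutoff-ending-time experiment
#'
#' Re-runs the full pipeline (cutoff truncation, feature extraction,
#' cross-validated evaluation) for each cutoff ending time point: 0 minutes
#' means one time point before the first adverse event (or the full session
#' when event-free); larger cutoffs stop feature collection earlier.
#'
#' @param sessions cleaned `hd_session` list.
#' @param cutoffs cutoff ending time points in minutes.
#' @param spec a [model_spec()].
#' @param scheme labeling scheme name or object.
#' @param k,repeats,partition,seed passed to [cross_validate()].
#' @param registry feature registry.
#' @return list with `summary` (one row per cutoff: AUC/F1/sensitivity/
#'   specificity and session counts) and `results` (the `hd_eval` objects).
#' @export
run_cutoff_experiment <- function(sessions, cutoffs = c(0, 5, 10, 15, 20, 60),
                                  spec = model_spec("perceptron"),
                                  scheme = "any_event", k = 4, repeats = 3,
                                  partition = "session", seed = 1,
                                  registry = feature_registry()) {
  results <- list()
  rows <- list()
  for (m in cutoffs) {
    ft <- build_feature_table(sessions, scheme, cutoff_min = m,
                              registry = registry)
    if (sum(ft$labels == 1) == 0) {
      stop("cutoff ", m, " leaves no positive sessions", call. = FALSE)
    }
    ev <- cross_validate(ft$features, ft$labels, spec, k = k,
                         repeats = repeats, partition = partition,
                         patient_id = ft$patient_id, seed = seed)
    results[[as.character(m)]] <- ev
    rows[[length(rows) + 1L]] <- data.frame(
      cutoff_min = m, mean_auc = ev$mean_auc, sd_auc = ev$sd_auc,
      f1 = ev$f1, sensitivity = ev$sensitivity,
      specificity = ev$specificity, n_sessions = length(ft$labels),
      n_positive = sum(ft$labels == 1)
    )
  }
  list(summary = do.call(rbind, rows), results = results)
}

#' Per-session probability consistency across cutoff ending time points
#'
#' Randomly samples sessions and compares their cross-validated predicted
#' event probabilities across cutoffs. A session is "consistent" when its
#' probability exceeds the threshold at every cutoff (strictly); a session
#' excluded at any cutoff (record floor) cannot be consistent.
#'
#' @param sessions cleaned `hd_session` list.
#' @param cutoffs cutoff ending time points (default 0, 5, 10, 15, 20).
#' @param spec a [model_spec()] (probabilities are the logistic squashing of
#'   the model score).
#' @param threshold consistency threshold on the probability (default 0.8).
#' @param n_sample number of sessions to sample (default 500; capped at the
#'   cohort size with a warning).
#' @param scheme labeling scheme.
#' @param k folds used for held-out scoring.
#' @param seed integer seed.
#' @param registry feature registry.
#' @return list with `probabilities` (sampled sessions x cutoffs matrix),
#'   `labels` (true labels of the sampled sessions) and `consistent`
#'   (session ids passing the threshold at every cutoff).
#' @export
probability_consistency <- function(sessions, cutoffs = c(0, 5, 10, 15, 20),
                                    spec = model_spec("perceptron"),
                                    threshold = 0.8, n_sample = 500,
                                    scheme = "any_event", k = 4, seed = 1,
                                    registry = feature_registry()) {
  all_ids <- unname(vapply(sessions, `[[`, character(1), "session_id"))
  if (n_sample > length(all_ids)) {
    warning("n_sample exceeds the cohort size; using all sessions")
    n_sample <- length(all_ids)
  }
  set.seed(substream_seed(seed, "consistency-sample"))
  sampled <- sort(pickn(all_ids, n_sample))
  prob <- matrix(NA_real_, n_sample, length(cutoffs),
                 dimnames = list(sampled, as.character(cutoffs)))
  lab_out <- stats::setNames(rep(NA_integer_, n_sample), sampled)
  for (ci in seq_along(cutoffs)) {
    ft <- build_feature_table(sessions, scheme, cutoff_min = cutoffs[ci],
                              registry = registry)
    folds <- make_folds(ft$labels, k, substream_seed(seed, "consistency"),
                        "session")
    sc <- numeric(length(ft$labels))
    for (f in seq_len(k)) {
      tr <- folds != f
      fit <- train_model(ft$features[tr, , drop = FALSE], ft$labels[tr],
                         spec_with_seed(spec, seed + f))
      sc[!tr] <- model_score(fit, ft$features[!tr, , drop = FALSE])
    }
    # floor at the smallest positive double: the logistic probability is
    # never exactly 0, but plogis underflows for very large negative scores
    p <- pmax(stats::plogis(sc), .Machine$double.xmin)
    hit <- match(sampled, ft$session_id)
    prob[, ci] <- p[hit]
    lab_out[!is.na(hit)] <- ft$labels[hit[!is.na(hit)]]
  }
  consistent <- rownames(prob)[apply(prob, 1, function(v) {
    all(!is.na(v)) && all(v > threshold)
  })]
  list(probabilities = prob, labels = lab_out, consistent = consistent)
}

#' Negative-session truncation experiment
#'
#' Event sessions keep their first-event truncation; event-free sessions are
#' truncated to matched endpoints — `"fixed"` at a stated time (e.g. 198 min
#' = 3.3 h) or `"uniform"` with per-session endpoints drawn from a window
#' (180-210 min, or the wider 150-210 min variant) — before feature
#' extraction and cross-validation. `"none"` reproduces the main analysis.
#'
#' @param sessions cleaned `hd_session` list.
#' @param mode `"none"`, `"fixed"` or `"uniform"`.
#' @param window_or_point endpoint (fixed) or window (uniform), in minutes.
#' @param spec,scheme,k,repeats,partition,seed,registry as in
#'   [run_cutoff_experiment()].
#' @return an `hd_eval` object.
#' @export
run_truncation_experiment <- function(sessions,
                                      mode = c("none", "fixed", "uniform"),
                                      window_or_point = NULL,
                                      spec = model_spec("perceptron"),
                                      scheme = "any_event", k = 4,
                                      repeats = 3, partition = "session",
                                      seed = 1,
                                      registry = feature_registry()) {
  mode <- match.arg(mode)
  if (mode != "none") {
    stopifnot(!is.null(window_or_point))
    sessions <- lapply(sessions, function(s) {
      if (nrow(s$events)) return(s)  # positives keep their own endpoints
      truncate_negative(s, mode, window_or_point, seed = seed)
    })
  }
  ft <- build_feature_table(sessions, scheme, cutoff_min = 0,
                            registry = registry)
  cross_validate(ft$features, ft$labels, spec, k = k, repeats = repeats,
                 partition = partition, patient_id = ft$patient_id,
                 seed = seed)
}
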