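# Classifiers: the two-class averaged perceptron (primary model), ensemble
# random-undersampling boosted trees (the selection scorer), and thin
# adapters for SVM / logistic regression / decision forest baselines.
# All models share the train/score contract: train_model() -> object,
# model_score(object, X) -> real score monotone in confidence,
# native_threshold(object) -> the model's own operating point.

#' Averaged perceptron configuration
#'
#' @param learning_rate positive step size applied to every misclassification
#'   update (default 20; meaningful because features are standardized).
#' @param max_iterations number of passes (epochs) over the data (default 20).
#' @param seed integer seed controlling the per-epoch visit order.
#' @param standardize center and scale features to zero mean / unit SD
#'   (SD floor 1e-8) before training (default `TRUE`).
#' @return list of class `hd_perceptron_config`.
#' @export
perceptron_config <- function(learning_rate = 20, max_iterations = 20,
                              seed = 1, standardize = TRUE) {
  stopifnot(learning_rate > 0, max_iterations >= 1)
  structure(list(learning_rate = learning_rate,
                 max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed), standardize = standardize),
            class = "hd_perceptron_config")
}

standardize_fit <- function(X) {
  mu <- colMeans(X)
  sdev <- apply(X, 2, stats::sd)
  list(mean = mu, sd = pmax(sdev, 1e-8))
}

standardize_apply <- function(X, std) {
  sweep(sweep(X, 2, std$mean, "-"), 2, std$sd, "/")
}

#' Train a two-class averaged perceptron
#'
#' Standard averaged-perceptron training under the +/-1 label convention:
#' per epoch, examples are visited in a seed-shuffled order; on a
#' misclassification by the current weights (`y * (w.x + b) <= 0`) the
#' update `w <- w + lr * y * x`, `b <- b + lr * y` is applied. The running
#' average of the weight vector over all visits is returned as the model,
#' which is markedly more stable than the final weights.
#'
#' @param X numeric feature matrix (finite entries).
#' @param y 0/1 labels with both classes present.
#' @param config a [perceptron_config()].
#' @return object of class `hd_perceptron` with the averaged weights (one
#'   per feature plus bias), the standardization parameters and training
#'   metadata.
#' @export
train_averaged_perceptron <- function(X, y, config = perceptron_config()) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("X must be finite", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("y must be 0/1", call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  std <- if (config$standardize) standardize_fit(X) else
    list(mean = rep(0, ncol(X)), sd = rep(1, ncol(X)))
  Xs <- standardize_apply(X, std)
  yy <- ifelse(y == 1, 1, -1)
  n <- nrow(Xs); p <- ncol(Xs)
  lr <- config$learning_rate
  w <- numeric(p); b <- 0
  wsum <- numeric(p); bsum <- 0
  n_updates <- 0L
  set.seed(substream_seed(config$seed, "perceptron-shuffle"))
  for (epoch in seq_len(config$max_iterations)) {
    for (i in sample.int(n)) {
      xi <- Xs[i, ]
      if (yy[i] * (sum(w * xi) + b) <= 0) {
        w <- w + lr * yy[i] * xi
        b <- b + lr * yy[i]
        n_updates <- n_updates + 1L
      }
      wsum <- wsum + w
      bsum <- bsum + b
    }
  }
  steps <- n * config$max_iterations
  structure(
    list(weights = wsum / steps, bias = bsum / steps, std = std,
         config = config, n_updates = n_updates,
         feature_names = colnames(X)),
    class = "hd_perceptron"
  )
}

#' @export
print.hd_perceptron <- function(x, ...) {
  cat(sprintf(
    "<hd_perceptron> %d features, lr %g, %d epochs, %d updates\n",
    length(x$weights), x$config$learning_rate, x$config$max_iterations,
    x$n_updates))
  invisible(x)
}

#' Decision scores and class predictions
#'
#' `model_score()` returns a real score monotone in the model's confidence
#' (so ROC curves are well defined); `model_predict()` thresholds it, with
#' ties classified as 0 (the specificity-favoring convention).
#'
#' @param model a trained model (`hd_perceptron`, `hd_rusboost`, `hd_svm`,
#'   `hd_logistic` or `hd_forest`).
#' @param X feature matrix with the training dimension.
#' @param threshold decision threshold; defaults to the model's native
#'   operating point ([native_threshold()]).
#' @return numeric scores, or 0/1 classes.
#' @export
model_score <- function(model, X) UseMethod("model_score")

#' @rdname model_score
#' @export
model_predict <- function(model, X, threshold = native_threshold(model)) {
  as.integer(model_score(model, X) > threshold)
}

#' @rdname model_score
#' @export
native_threshold <- function(model) UseMethod("native_threshold")

#' @export
native_threshold.default <- function(model) 0

#' @export
model_score.hd_perceptron <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$weights)) {
    stop("feature dimension mismatch: model has ", length(model$weights),
         ", data has ", ncol(X), call. = FALSE)
  }
  Xs <- standardize_apply(X, model$std)
  as.numeric(Xs %*% model$weights + model$bias)
}

#' Calibrated event probability of a perceptron score
#'
#' A logistic squashing `1 / (1 + exp(-score))` of the averaged-perceptron
#' decision score, used by the probability-consistency experiment (its 0.8
#' consistency threshold applies to this value).
#'
#' @param model an `hd_perceptron`.
#' @param X feature matrix.
#' @return probabilities in (0, 1).
#' @export
perceptron_probability <- function(model, X) {
  stats::plogis(model_score(model, X))
}

#' Serialize / restore a perceptron as JSON
#'
#' @param model an `hd_perceptron`.
#' @param path JSON file path.
#' @return `write_perceptron_json()` returns `path` invisibly;
#'   `read_perceptron_json()` the restored model.
#' @export
write_perceptron_json <- function(model, path) {
  jsonlite::write_json(
    list(weights = model$weights, bias = model$bias,
         std_mean = model$std$mean, std_sd = model$std$sd,
         learning_rate = model$config$learning_rate,
         max_iterations = model$config$max_iterations,
         seed = model$config$seed, standardize = model$config$standardize,
         n_updates = model$n_updates, feature_names = model$feature_names),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_perceptron_json
#' @export
read_perceptron_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(weights = j$weights, bias = j$bias,
         std = list(mean = j$std_mean, sd = j$std_sd),
         config = perceptron_config(j$learning_rate, j$max_iterations,
                                    j$seed, j$standardize),
         n_updates = j$n_updates, feature_names = j$feature_names),
    class = "hd_perceptron"
  )
}

#' RUSBoost configuration
#'
#' @param n_rounds boosting rounds (default 100).
#' @param maxdepth weak-tree depth, 1 (stumps) to 4 (default 2).
#' @param ratio majority:minority undersampling ratio per round (default 1).
#' @param minbucket minimum leaf size of the weak trees.
#' @param seed integer seed.
#' @return list of class `hd_rusboost_config`.
#' @export
rusboost_config <- function(n_rounds = 100, maxdepth = 2, ratio = 1,
                            minbucket = 5, seed = 1) {
  stopifnot(n_rounds >= 1, maxdepth >= 1, ratio > 0)
  structure(list(n_rounds = as.integer(n_rounds),
                 maxdepth = as.integer(maxdepth), ratio = ratio,
                 minbucket = as.integer(minbucket),
                 seed = as.integer(seed)),
            class = "hd_rusboost_config")
}

#' Train ensemble random-undersampling boosted trees (RUSBoost)
#'
#' AdaBoost.M1 with per-round random undersampling of the majority class:
#' each round draws a uniform random subset of majority examples down to the
#' configured ratio against the minority class, fits a weighted weak tree on
#' the reduced sample, computes the round weight from its weighted error on
#' the full set, and reweights examples. The ensemble score is the weighted
#' vote, a real value monotone in confidence.
#'
#' @param X numeric feature matrix.
#' @param y 0/1 labels with both classes present.
#' @param config a [rusboost_config()].
#' @return object of class `hd_rusboost`.
#' @export
train_rusboost <- function(X, y, config = rusboost_config()) {
  X <- as.matrix(X)
  if (!all(y %in% c(0, 1))) stop("y must be 0/1", call. = FALSE)
  if (min(table(y)) < 1 || length(unique(y)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  n <- nrow(X)
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  df <- as.data.frame(X)
  yy <- ifelse(y == 1, 1, -1)
  minority <- as.integer(names(which.min(table(y))))
  idx_min <- which(y == minority)
  idx_maj <- which(y != minority)
  D <- rep(1 / n, n)
  trees <- list(); alphas <- numeric(0)
  set.seed(substream_seed(config$seed, "rusboost"))
  ctrl <- rpart::rpart.control(maxdepth = config$maxdepth,
                               minbucket = config$minbucket,
                               cp = 0, xval = 0, maxsurrogate = 0)
  for (t in seq_len(config$n_rounds)) {
    n_take <- min(length(idx_maj),
                  max(1L, round(config$ratio * length(idx_min))))
    take <- c(idx_min, pickn(idx_maj, n_take))
    wt <- D[take] / sum(D[take])
    fit_df <- df[take, , drop = FALSE]
    fit_df$.y <- factor(y[take], levels = c(0, 1))
    tree <- rpart::rpart(.y ~ ., data = fit_df, weights = wt * length(take),
                         method = "class", control = ctrl)
    pred <- as.integer(as.character(predict(tree, df, type = "class")))
    h <- ifelse(pred == 1, 1, -1)
    err <- sum(D[h != yy])
    err <- min(max(err, 1e-10), 1 - 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    trees[[t]] <- tree
    alphas[t] <- alpha
    D <- D * exp(-alpha * yy * h)
    D <- D / sum(D)
  }
  structure(list(trees = trees, alphas = alphas, config = config,
                 n_features = ncol(X)),
            class = "hd_rusboost")
}

#' @export
model_score.hd_rusboost <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$n_features) {
    stop("feature dimension mismatch", call. = FALSE)
  }
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  df <- as.data.frame(X)
  s <- numeric(nrow(X))
  for (t in seq_along(model$trees)) {
    pred <- as.integer(as.character(
      predict(model$trees[[t]], df, type = "class")))
    s <- s + model$alphas[t] * ifelse(pred == 1, 1, -1)
  }
  s
}

#' Baseline classifier adapters
#'
#' Thin wrappers over established implementations — linear support vector
#' machine (`e1071::svm`), logistic regression (`stats::glm`) and a decision
#' forest (`randomForest`) — exposing the same train/score contract as the
#' perceptron so the evaluation harness treats all models uniformly.
#'
#' @param X numeric feature matrix.
#' @param y 0/1 labels.
#' @param ... passed through to the underlying fit function.
#' @param seed integer seed for the forest.
#' @return model objects of class `hd_svm`, `hd_logistic`, `hd_forest`.
#' @name baselines
NULL

#' @rdname baselines
#' @export
train_svm <- function(X, y, ...) {
  X <- as.matrix(X)
  fit <- e1071::svm(X, factor(y, levels = c(0, 1)), kernel = "linear",
                    scale = apply(X, 2, stats::sd) > 0, ...)
  structure(list(fit = fit, n_features = ncol(X)), class = "hd_svm")
}

#' @export
model_score.hd_svm <- function(model, X) {
  X <- as.matrix(X)
  dv <- attr(predict(model$fit, X, decision.values = TRUE),
             "decision.values")
  s <- as.numeric(dv[, 1])
  # orient so that larger score means class 1
  if (grepl("^0/", colnames(dv)[1])) s <- -s
  s
}

#' @rdname baselines
#' @export
train_logistic <- function(X, y, ...) {
  df <- as.data.frame(as.matrix(X))
  names(df) <- paste0("f", seq_len(ncol(df)))
  df$.y <- y
  fit <- suppressWarnings(stats::glm(.y ~ ., data = df, family = "binomial",
                                     ...))
  structure(list(fit = fit, n_features = ncol(X)), class = "hd_logistic")
}

#' @export
model_score.hd_logistic <- function(model, X) {
  df <- as.data.frame(as.matrix(X))
  names(df) <- paste0("f", seq_len(ncol(df)))
  # linear predictor; the native threshold 0 equals probability 0.5
  as.numeric(suppressWarnings(predict(model$fit, df, type = "link")))
}

#' @rdname baselines
#' @export
train_forest <- function(X, y, seed = 1, ...) {
  set.seed(substream_seed(seed, "forest"))
  fit <- randomForest::randomForest(as.matrix(X),
                                    factor(y, levels = c(0, 1)), ...)
  structure(list(fit = fit, n_features = ncol(X)), class = "hd_forest")
}

#' @export
model_score.hd_forest <- function(model, X) {
  # vote fraction for class 1, shifted so the native threshold is 0
  p <- predict(model$fit, as.matrix(X), type = "prob")[, "1"]
  as.numeric(p) - 0.5
}

#' Model specification for the evaluation harness
#'
#' @param model one of `"perceptron"`, `"svm"`, `"logistic"`, `"forest"`,
#'   `"rusboost"`.
#' @param ... configuration passed to the trainer (e.g. a
#'   [perceptron_config()] as `config`).
#' @return list of class `hd_model_spec`.
#' @export
model_spec <- function(model = c("perceptron", "svm", "logistic", "forest",
                                 "rusboost"), ...) {
  model <- match.arg(model)
  structure(list(model = model, args = list(...)), class = "hd_model_spec")
}

train_model <- function(X, y, spec) {
  stopifnot(inherits(spec, "hd_model_spec"))
  fn <- switch(spec$model,
    perceptron = train_averaged_perceptron,
    svm = train_svm,
    logistic = train_logistic,
    forest = train_forest,
    rusboost = train_rusboost
  )
  do.call(fn, c(list(X, y), spec$args))
}
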