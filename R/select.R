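# Greedy forward feature-combination search scored by RUSBoost, and the
# key-feature frequency ranking over the retained combinations.

#' Score one feature combination
#'
#' k-fold cross-validation of the RUSBoost classifier restricted to the
#' combination. Under the default `"rates"` convention the score is
#' sensitivity + specificity aggregated over the held-out folds (range 0-2,
#' chance about 1, robust to class imbalance); the `"counts"` convention
#' instead sums the true-positive and true-negative fractions of all
#' examples (range 0-1).
#'
#' @param X feature matrix.
#' @param labels 0/1 labels, both classes present.
#' @param combo integer vector of feature (column) indices.
#' @param scorer_config a [rusboost_config()].
#' @param k folds (default 4).
#' @param seed integer seed (fixed across combos when comparing them).
#' @param convention `"rates"` or `"counts"`.
#' @param folds optional precomputed fold assignment, so every combination
#'   in a comparison is scored on identical splits.
#' @return list of class `hd_combo_score` with `combo`, `score` and the
#'   pooled confusion counts.
#' @export
score_combo <- function(X, labels, combo,
                        scorer_config = rusboost_config(),
                        k = 4, seed = 1,
                        convention = c("rates", "counts"),
                        folds = NULL) {
  convention <- match.arg(convention)
  if (!length(combo)) stop("empty combination", call. = FALSE)
  combo <- sort(unique(as.integer(combo)))
  if (is.null(folds)) folds <- make_folds(labels, k, seed, "session")
  Xc <- X[, combo, drop = FALSE]
  tp <- fp <- fn <- tn <- 0
  for (f in sort(unique(folds))) {
    tr <- folds != f
    cfg <- scorer_config
    cfg$seed <- substream_seed(seed, paste0("combo-fold-", f))
    fit <- train_rusboost(Xc[tr, , drop = FALSE], labels[tr], cfg)
    pred <- as.integer(model_score(fit, Xc[!tr, , drop = FALSE]) > 0)
    lt <- labels[!tr]
    tp <- tp + sum(pred == 1 & lt == 1)
    fp <- fp + sum(pred == 1 & lt == 0)
    fn <- fn + sum(pred == 0 & lt == 1)
    tn <- tn + sum(pred == 0 & lt == 0)
  }
  score <- if (convention == "rates") {
    (if (tp + fn > 0) tp / (tp + fn) else 0) +
      (if (tn + fp > 0) tn / (tn + fp) else 0)
  } else {
    (tp + tn) / (tp + fp + fn + tn)
  }
  structure(list(combo = combo, score = score,
                 confusion = c(tp = tp, fp = fp, fn = fn, tn = tn),
                 convention = convention, seed = seed),
            class = "hd_combo_score")
}

combo_key <- function(combo) paste(combo, collapse = "-")

# deterministic ordering: score desc, then lexicographic combo
order_combos <- function(combos, scores) {
  keys <- vapply(combos, function(cb) {
    paste(sprintf("%03d", cb), collapse = "-")
  }, character(1))
  order(-scores, keys)
}

#' Greedy forward search over feature combinations
#'
#' Level 1 scores every single feature and keeps the top one. At each later
#' level every retained combination is extended by each unused feature, and
#' extensions scoring strictly higher than the best retained score of the
#' previous level (the level benchmark) are kept, truncated to `beam_cap`
#' per level by score with deterministic tie-breaking. The search stops at
#' `max_size` or as soon as no extension improves. The scoring seed (and
#' hence the folds) is fixed within a level so comparisons are paired.
#'
#' The procedure is greedy as specified, not globally optimal: a pair of
#' features that is informative only jointly is found only when one of them
#' survives an earlier level.
#'
#' @param X feature matrix.
#' @param labels 0/1 labels.
#' @param max_size largest combination size to grow (default 20).
#' @param scorer_config a [rusboost_config()] for the scorer.
#' @param beam_cap retained combinations per level (default 50; `Inf`
#'   reproduces the uncapped rule on small problems).
#' @param k scorer folds.
#' @param seed integer root seed.
#' @param convention score convention, see [score_combo()].
#' @return object of class `hd_selection_trace`: per-level retained
#'   combinations with scores, the per-level benchmarks, and the final size
#'   reached.
#' @export
greedy_forward_search <- function(X, labels, max_size = 20,
                                  scorer_config = rusboost_config(),
                                  beam_cap = 50, k = 4, seed = 1,
                                  convention = c("rates", "counts")) {
  convention <- match.arg(convention)
  p <- ncol(X)
  stopifnot(max_size <= p, max_size >= 1)
  levels <- list()
  benchmarks <- numeric(0)

  score_level <- function(combos, size) {
    lvl_seed <- substream_seed(seed, paste0("level-", size))
    folds <- make_folds(labels, k, lvl_seed, "session")
    vapply(combos, function(cb) {
      score_combo(X, labels, cb, scorer_config, k = k, seed = lvl_seed,
                  convention = convention, folds = folds)$score
    }, numeric(1))
  }

  singles <- lapply(seq_len(p), function(j) j)
  s1 <- score_level(singles, 1L)
  best <- order_combos(singles, s1)[1]
  levels[[1]] <- list(combos = singles[best], scores = s1[best])
  benchmarks[1] <- s1[best]

  size <- 1L
  while (size < max_size) {
    parents <- levels[[size]]$combos
    pool <- list()
    for (pc in parents) {
      for (j in setdiff(seq_len(p), pc)) {
        cand <- sort(c(pc, j))
        pool[[combo_key(cand)]] <- cand
      }
    }
    pool <- unname(pool)
    if (!length(pool)) break
    sc <- score_level(pool, size + 1L)
    keep <- sc > benchmarks[size]
    if (!any(keep)) break
    pool <- pool[keep]; sc <- sc[keep]
    ord <- order_combos(pool, sc)
    if (is.finite(beam_cap)) ord <- utils::head(ord, beam_cap)
    size <- size + 1L
    levels[[size]] <- list(combos = pool[ord], scores = sc[ord])
    benchmarks[size] <- max(sc)
  }

  structure(list(levels = levels, benchmarks = benchmarks,
                 final_size = size, max_size = max_size,
                 beam_cap = beam_cap, convention = convention, seed = seed),
            class = "hd_selection_trace")
}

#' @export
print.hd_selection_trace <- function(x, ...) {
  cat(sprintf(
    "<hd_selection_trace> reached size %d of %d; %d combo(s) retained, best score %.4f\n",
    x$final_size, x$max_size, length(x$levels[[x$final_size]]$combos),
    x$benchmarks[x$final_size]))
  invisible(x)
}

#' Key features of a selection trace
#'
#' Ranks features by how often they appear in the retained largest
#' combinations (the 20-feature combinations when the search reached size
#' 20; the deepest level reached otherwise, with a warning). Ties are broken
#' by the best score of a retained combination containing the feature, then
#' by lower index.
#'
#' @param trace an `hd_selection_trace`.
#' @param top_n number of features to return (default 21).
#' @return data.frame with `feature` (column index), `count` (appearances)
#'   and `best_score`, ranked.
#' @export
key_features <- function(trace, top_n = 21) {
  stopifnot(inherits(trace, "hd_selection_trace"))
  if (!length(trace$levels)) stop("empty trace", call. = FALSE)
  if (trace$final_size < trace$max_size) {
    warning("search stopped at size ", trace$final_size,
            "; ranking over that level")
  }
  lvl <- trace$levels[[trace$final_size]]
  feats <- unlist(lvl$combos)
  cnt <- table(feats)
  best <- vapply(as.integer(names(cnt)), function(j) {
    max(lvl$scores[vapply(lvl$combos, function(cb) j %in% cb, logical(1))])
  }, numeric(1))
  out <- data.frame(feature = as.integer(names(cnt)),
                    count = as.integer(cnt), best_score = best)
  out <- out[order(-out$count, -out$best_score, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  if (top_n < nrow(out)) out <- out[seq_len(top_n), , drop = FALSE]
  if (top_n > nrow(out)) {
    warning("only ", nrow(out), " features appear in the retained ",
            "combinations; returning all of them")
  }
  out
}
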