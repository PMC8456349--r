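# Shared fixtures: hand-built sessions with controllable series, and small
# independent oracles used across test files.

default_static <- function() {
  list(age = 60, gender = "male", vintage_years = 5,
       predialytic_weight = 62)
}

# A fully controllable session: machine records every `machine_step` minutes,
# vitals every `vitals_step` minutes. Series can be overridden per
# measurement with a function of time.
make_test_session <- function(session_id = "S1", patient_id = "P1",
                              machine_step = 10, vitals_step = 60,
                              length_min = 240,
                              bfr = function(t) rep(250, length(t)),
                              vp = function(t) 100 + 0.2 * t +
                                6 * sin(t / 7),
                              tmp = function(t) 90 + 0.1 * t +
                                6 * cos(t / 11),
                              uf_rate = function(t) ifelse(t < 120, 600, 500),
                              uf_volume = function(t) ifelse(
                                t < 120, 600 * t / 60,
                                1200 + 500 * (t - 120) / 60),
                              sbp = function(t) 140 - 0.05 * t,
                              dbp = function(t) 75 - 0.02 * t,
                              pulse = function(t) 76 + 0.01 * t,
                              events = NULL,
                              static = default_static()) {
  mt <- seq(0, length_min, by = machine_step)
  vt <- seq(0, length_min, by = vitals_step)
  rec <- rbind(
    data.frame(measurement_id = 5, time_min = mt, value = bfr(mt)),
    data.frame(measurement_id = 6, time_min = mt, value = vp(mt)),
    data.frame(measurement_id = 7, time_min = mt, value = tmp(mt)),
    data.frame(measurement_id = 8, time_min = mt, value = uf_rate(mt)),
    data.frame(measurement_id = 9, time_min = mt, value = uf_volume(mt)),
    data.frame(measurement_id = 1, time_min = vt, value = sbp(vt)),
    data.frame(measurement_id = 2, time_min = vt, value = dbp(vt)),
    data.frame(measurement_id = 3, time_min = vt,
               value = sbp(vt) - dbp(vt)),
    data.frame(measurement_id = 4, time_min = vt, value = pulse(vt))
  )
  if (is.null(events)) {
    events <- data.frame(event_type = character(0), time_min = numeric(0),
                         stringsAsFactors = FALSE)
  }
  hd_session(session_id, patient_id, rec, static, events,
             scheduled_length_min = length_min)
}

# small deterministic cohort shared by several files (generated once)
shared_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_cohort(simulation_config(n_patients = 8, seed = 404))
    }
    cache
  }
})

# --- independent oracles -----------------------------------------------------

# brute-force pairwise Mann-Whitney AUC, ties counted 1/2
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# exhaustive level-by-level enumeration applying the same keep-if-better
# rule as the greedy search, scored with the identical paired scorer
exhaustive_selection <- function(X, labels, max_size, scorer_config,
                                 k = 4, seed = 1) {
  p <- ncol(X)
  score_all <- function(combos, size) {
    lvl_seed <- hdevents:::substream_seed(seed, paste0("level-", size))
    folds <- make_folds(labels, k, lvl_seed, "session")
    vapply(combos, function(cb) {
      score_combo(X, labels, cb, scorer_config, k = k, seed = lvl_seed,
                  folds = folds)$score
    }, numeric(1))
  }
  singles <- lapply(seq_len(p), function(j) j)
  sc <- score_all(singles, 1L)
  keys <- vapply(singles, function(cb) {
    paste(sprintf("%03d", cb), collapse = "-")
  }, character(1))
  best <- order(-sc, keys)[1]
  retained <- list(list(combos = singles[best], scores = sc[best]))
  bench <- sc[best]
  size <- 1L
  while (size < max_size) {
    # every subset of size+1 that extends a retained combo
    pool <- list()
    for (cb in retained[[size]]$combos) {
      for (j in setdiff(seq_len(p), cb)) {
        cand <- sort(c(cb, j))
        pool[[paste(cand, collapse = "-")]] <- cand
      }
    }
    pool <- unname(pool)
    if (!length(pool)) break
    sc <- score_all(pool, size + 1L)
    keep <- sc > bench
    if (!any(keep)) break
    pool <- pool[keep]; sc <- sc[keep]
    keys <- vapply(pool, function(cb) {
      paste(sprintf("%03d", cb), collapse = "-")
    }, character(1))
    ord <- order(-sc, keys)
    size <- size + 1L
    retained[[size]] <- list(combos = pool[ord], scores = sc[ord])
    bench <- max(sc)
  }
  list(levels = retained, final_size = size)
}
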