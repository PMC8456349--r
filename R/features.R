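# The 84-feature registry and extraction engine: linear summaries,
# regression features, finite-difference derivative features and
# ultrafiltration-rate change features over cleaned, truncated sessions.

#' Linear summaries of an irregular series
#'
#' Computes the mean, the standard deviation of the mean (the standard error,
#' sample SD / sqrt(n)), the coefficient of variation (sample SD / |mean|),
#' and the extrema of the recorded values. Sampling times do not enter these
#' summaries; only recorded values do.
#'
#' @param time_min,value numeric vectors of equal length (>= 1 point;
#'   >= 2 for the dispersion summaries).
#' @return named list with `mean`, `sd_of_mean`, `cv`, `max`, `min` and the
#'   plain sample `sd`.
#' @export
linear_summary <- function(time_min, value) {
  if (!length(value)) stop("empty series", call. = FALSE)
  m <- mean(value)
  s <- if (length(value) > 1) stats::sd(value) else 0
  cv <- if (s == 0) 0 else if (m == 0) NaN else s / abs(m)
  list(mean = m, sd_of_mean = s / sqrt(length(value)), cv = cv,
       max = max(value), min = min(value), sd = s)
}

#' Ordinary least-squares summaries of an irregular series
#'
#' Unweighted OLS of value on time at the recorded points only (no LOCF
#' densification). The slope is in value units per minute; `r_squared` is the
#' squared Pearson correlation of time and value, defined as 0 for a constant
#' series.
#'
#' @param time_min,value numeric vectors (>= 2 distinct times).
#' @return named list with `slope` and `r_squared`.
#' @export
regression_summary <- function(time_min, value) {
  if (length(unique(time_min)) < 2) {
    stop("regression needs >= 2 distinct times", call. = FALSE)
  }
  st <- stats::var(time_min)
  sv <- stats::var(value)
  cov_tv <- stats::cov(time_min, value)
  slope <- cov_tv / st
  r2 <- if (sv == 0) 0 else (cov_tv^2) / (st * sv)
  list(slope = slope, r_squared = r2)
}

#' Finite-difference derivative summaries
#'
#' First derivative over consecutive records,
#' `d1_k = (y_k - y_(k-1)) / (t_k - t_(k-1))`, and second derivative
#' `d2_k = (d1_(k+1) - d1_k) / (t_(k+1) - t_k)`; summaries are the max, min
#' and mean of each finite-difference sequence. Records sharing a timestamp
#' are collapsed to the last value at that time before differencing.
#'
#' @param time_min,value numeric vectors (>= 3 distinct times).
#' @return named list with `d1_max`, `d1_min`, `d1_mean`, `d2_max`,
#'   `d2_min`, `d2_mean`.
#' @export
derivative_summary <- function(time_min, value) {
  keep <- !duplicated(time_min, fromLast = TRUE)
  t <- time_min[keep]; y <- value[keep]
  ord <- order(t)
  t <- t[ord]; y <- y[ord]
  if (length(t) < 3) {
    stop("derivative summaries need >= 3 distinct times", call. = FALSE)
  }
  d1 <- diff(y) / diff(t)
  d2 <- diff(d1) / utils::tail(diff(t), -1)
  list(d1_max = max(d1), d1_min = min(d1), d1_mean = mean(d1),
       d2_max = max(d2), d2_min = min(d2), d2_mean = mean(d2))
}

#' Ultrafiltration-rate change summaries
#'
#' A change is any pair of consecutive records with different rate values.
#' Returns the number of changes and the mean of the signed differences over
#' the changed pairs (0 by convention when the rate never changes).
#'
#' @param time_min,value numeric vectors (>= 2 points).
#' @return named list with `count_of_changes` and `mean_of_changes`.
#' @export
uf_rate_changes <- function(time_min, value) {
  if (length(value) < 2) stop("need >= 2 records", call. = FALSE)
  d <- diff(value)
  changed <- d != 0
  list(count_of_changes = sum(changed),
       mean_of_changes = if (any(changed)) mean(d[changed]) else 0)
}

# 7-slot linear/regression block shared by most measurements
.summary_kinds <- c("mean", "sd_of_mean", "cv", "slope", "r_squared",
                    "max", "min")

#' The canonical 84-feature registry
#'
#' The registry fixes the order, source and kind of the 84 features extracted
#' per session: 4 static patient fields; a 7-summary block (mean, SD of the
#' mean, CV, OLS slope, R-squared, max, min) for each of systolic/diastolic
#' blood pressure, pulse pressure, pulse rate, blood flow rate, venous
#' pressure and transmembranous pressure; first- and second-order derivative
#' summaries of venous pressure (indices 47-52), transmembranous pressure
#' (60-65) and pulse pressure (66-68); record-change counts of the pressure
#' channels; 8 ultrafiltration-rate features (70-77, ending in the change
#' count at 76 and the mean rate change at 77); and 6 cumulative
#' ultrafiltration-volume features (78-83, led by the maximum volume at 78
#' with the OLS slope at 82).
#'
#' Group tags: `uf_rate` (8) and `uf_volume` (6) form the 14 ultrafiltration
#' features whose complement has 70; `bp_related` has exactly 24 entries;
#' `demographic` the 4 static fields; `top21` the 21 key features most
#' frequently retained by the greedy search on the reference cohort (age,
#' blood-pressure and pulse summaries, venous-pressure derivatives,
#' transmembranous-pressure summaries), none of them ultrafiltration-tagged.
#' The exact per-index composition beyond these pinned constraints is a
#' documented canonical ordering of this package.
#'
#' @return data.frame with columns `index`, `name`, `source`, `kind`, and
#'   logical group columns `uf_rate`, `uf_volume`, `bp_related`,
#'   `demographic`, `derivative`, `top21`.
#' @export
feature_registry <- function() {
  blk <- function(meas) {
    data.frame(name = paste0(meas, "_", .summary_kinds), source = meas,
               kind = .summary_kinds, stringsAsFactors = FALSE)
  }
  dblk <- function(meas, kinds) {
    data.frame(name = paste0(meas, "_", kinds), source = meas, kind = kinds,
               stringsAsFactors = FALSE)
  }
  reg <- rbind(
    data.frame(name = c("gender", "age", "vintage_years",
                        "predialytic_weight"),
               source = "static",
               kind = "static", stringsAsFactors = FALSE),        # 1-4
    blk("systolic_blood_pressure"),                               # 5-11
    blk("diastolic_blood_pressure"),                              # 12-18
    blk("pulse_pressure"),                                        # 19-25
    blk("pulse_rate"),                                            # 26-32
    blk("blood_flow_rate"),                                       # 33-39
    blk("venous_pressure"),                                       # 40-46
    dblk("venous_pressure",                                       # 47-52
         c("d2_max", "d2_min", "d2_mean", "d1_max", "d1_min", "d1_mean")),
    blk("transmembranous_pressure"),                              # 53-59
    dblk("transmembranous_pressure",                              # 60-65
         c("d2_max", "d2_min", "d2_mean", "d1_max", "d1_min", "d1_mean")),
    dblk("pulse_pressure", c("d1_max", "d1_min", "d1_mean")),     # 66-68
    dblk("venous_pressure", "count_of_changes"),                  # 69
    data.frame(name = paste0("uf_rate_",                          # 70-77
                             c("mean", "sd_of_mean", "cv", "slope",
                               "r_squared", "max", "count_of_changes",
                               "mean_of_changes")),
               source = "uf_rate",
               kind = c("mean", "sd_of_mean", "cv", "slope", "r_squared",
                        "max", "count_of_changes", "mean_of_changes"),
               stringsAsFactors = FALSE),
    data.frame(name = paste0("uf_volume_",                        # 78-83
                             c("max", "mean", "sd_of_mean", "cv", "slope",
                               "r_squared")),
               source = "uf_volume",
               kind = c("max", "mean", "sd_of_mean", "cv", "slope",
                        "r_squared"),
               stringsAsFactors = FALSE),
    dblk("transmembranous_pressure", "count_of_changes")          # 84
  )
  reg$index <- seq_len(nrow(reg))
  reg$uf_rate <- reg$source == "uf_rate"
  reg$uf_volume <- reg$source == "uf_volume"
  reg$bp_related <- reg$source %in%
    c("systolic_blood_pressure", "diastolic_blood_pressure",
      "pulse_pressure")
  reg$demographic <- reg$source == "static"
  reg$derivative <- grepl("^d[12]_", reg$kind)
  reg$top21 <- reg$index %in% c(2, 5, 8, 11, 15, 18, 22, 23, 25, 29, 34, 39,
                                47:52, 53, 56, 58)
  reg[, c("index", "name", "source", "kind", "uf_rate", "uf_volume",
          "bp_related", "demographic", "derivative", "top21")]
}

#' Export the feature registry as YAML
#'
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_registry_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required for YAML export", call. = FALSE)
  }
  reg <- feature_registry()
  entries <- lapply(seq_len(nrow(reg)), function(i) {
    r <- reg[i, ]
    groups <- c("uf_rate", "uf_volume", "bp_related", "demographic",
                "derivative", "top21")
    list(index = r$index, name = r$name, source = r$source, kind = r$kind,
         groups = groups[unlist(r[groups])])
  })
  yaml::write_yaml(list(version = 1L, features = entries), path)
  invisible(path)
}

#' Extract the 84-feature vector of one session
#'
#' The session must already be cleaned and truncated (first-event truncation
#' or cutoff applied); extraction depends only on the records present.
#' Static features are copied from the patient fields (gender encoded
#' male = 1, female = 0); every time-series feature is computed from the
#' relevant measurement's surviving records.
#'
#' @param session an `hd_session`.
#' @param registry the feature registry (default [feature_registry()]).
#' @return named numeric vector of length 84, in registry order.
#' @export
extract_features <- function(session, registry = feature_registry()) {
  series <- lapply(1:9, function(m) measurement_series(session, m))
  npts <- vapply(series, nrow, integer(1))
  if (any(npts < MIN_RECORDS_PER_MEASUREMENT)) {
    short <- measurement_catalog()$name[npts < MIN_RECORDS_PER_MEASUREMENT]
    stop("record floor unmet for: ", paste(short, collapse = ", "),
         call. = FALSE)
  }
  names(series) <- measurement_catalog()$name
  lin <- lapply(series, function(s) linear_summary(s$time_min, s$value))
  ols <- lapply(series, function(s) regression_summary(s$time_min, s$value))
  deriv <- lapply(series[c("venous_pressure", "transmembranous_pressure",
                           "pulse_pressure")],
                  function(s) derivative_summary(s$time_min, s$value))
  chg <- lapply(series[c("uf_rate", "venous_pressure",
                         "transmembranous_pressure")],
                function(s) uf_rate_changes(s$time_min, s$value))
  statics <- c(
    gender = if (session$static$gender == "male") 1 else 0,
    age = session$static$age,
    vintage_years = session$static$vintage_years,
    predialytic_weight = session$static$predialytic_weight
  )
  vals <- vapply(seq_len(nrow(registry)), function(i) {
    src <- registry$source[i]
    kind <- registry$kind[i]
    if (kind == "static") return(statics[[registry$name[i]]])
    if (kind %in% c("mean", "sd_of_mean", "cv", "max", "min")) {
      return(lin[[src]][[kind]])
    }
    if (kind %in% c("slope", "r_squared")) return(ols[[src]][[kind]])
    if (grepl("^d[12]_", kind)) return(deriv[[src]][[kind]])
    if (kind %in% c("count_of_changes", "mean_of_changes")) {
      return(chg[[src]][[kind]])
    }
    stop("unknown feature kind: ", kind, call. = FALSE)
  }, numeric(1))
  stats::setNames(vals, registry$name)
}

#' Column subset of a feature matrix by registry group
#'
#' @param x feature matrix or data.frame with 84 registry-ordered columns.
#' @param registry the feature registry.
#' @param group one of `"uf"` (rate and volume, 14 columns), `"uf_rate"`,
#'   `"uf_volume"`, `"not_uf"` (the 70-column complement), `"bp"` (24
#'   blood-pressure-related columns), `"demographic"`, `"derivative"`,
#'   `"top21"` or `"all"`.
#' @return the column-filtered matrix.
#' @export
feature_subset <- function(x, registry = feature_registry(),
                           group = c("all", "uf", "uf_rate", "uf_volume",
                                     "not_uf", "bp", "demographic",
                                     "derivative", "top21")) {
  group <- match.arg(group)
  sel <- switch(group,
    all = rep(TRUE, nrow(registry)),
    uf = registry$uf_rate | registry$uf_volume,
    uf_rate = registry$uf_rate,
    uf_volume = registry$uf_volume,
    not_uf = !(registry$uf_rate | registry$uf_volume),
    bp = registry$bp_related,
    demographic = registry$demographic,
    derivative = registry$derivative,
    top21 = registry$top21
  )
  x[, registry$index[sel], drop = FALSE]
}

#' Build the modeling feature table for a cohort
#'
#' The main-analysis assembly line: sessions are labeled under the given
#' scheme, event sessions are terminated at the cutoff ending time point
#' anchored on their first in-scope event (0 minutes = one time point before
#' the event; event-free sessions anchor on their last record), features are
#' extracted, and sessions falling under the per-measurement record floor
#' after truncation are excluded with a reason.
#'
#' @param sessions list of cleaned `hd_session` objects.
#' @param scheme a labeling scheme name or object, see [label_scheme()].
#' @param cutoff_min cutoff ending time point in minutes (default 0).
#' @param registry the feature registry.
#' @return list with `features` (n x 84 matrix), `labels` (0/1 integer
#'   vector), `session_id`, `patient_id`, and `excluded` (data.frame of
#'   excluded sessions and reasons).
#' @export
build_feature_table <- function(sessions, scheme = "any_event",
                                cutoff_min = 0,
                                registry = feature_registry()) {
  scheme <- label_scheme(scheme)
  labels <- label_sessions(sessions, scheme)
  rows <- vector("list", length(sessions))
  ok <- logical(length(sessions))
  reason <- character(length(sessions))
  for (i in seq_along(sessions)) {
    s <- sessions[[i]]
    # anchor on in-scope events only: a session whose only events are out of
    # scope is label 0 and keeps its full record (event-free anchoring)
    cut <- apply_cutoff(s, cutoff_min, event_types = scheme$included)
    fv <- tryCatch(extract_features(cut, registry), error = function(e) e)
    if (inherits(fv, "error")) {
      reason[i] <- conditionMessage(fv)
    } else if (any(!is.finite(fv))) {
      reason[i] <- paste("non-finite feature(s):",
                         paste(names(fv)[!is.finite(fv)], collapse = ", "))
    } else {
      rows[[i]] <- fv
      ok[i] <- TRUE
    }
  }
  sid <- vapply(sessions, `[[`, character(1), "session_id")
  pid <- vapply(sessions, `[[`, character(1), "patient_id")
  X <- do.call(rbind, rows[ok])
  if (is.null(X)) {
    X <- matrix(numeric(0), nrow = 0, ncol = nrow(registry),
                dimnames = list(NULL, registry$name))
  } else {
    rownames(X) <- sid[ok]
  }
  list(
    features = X,
    labels = labels[ok],
    session_id = sid[ok],
    patient_id = pid[ok],
    excluded = data.frame(session_id = sid[!ok], reason = reason[!ok],
                          stringsAsFactors = FALSE)
  )
}
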