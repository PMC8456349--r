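# HD session container and CSV (de)serialization.

#' Construct an HD session object
#'
#' An `hd_session` bundles one dialysis session: the irregular time-stamped
#' measurement records, static patient fields, and adverse-event annotations.
#' Records are stored in long form and kept sorted by time (stable within
#' ties), measured in minutes from session start.
#'
#' @param session_id,patient_id opaque identifier strings.
#' @param records data.frame with columns `measurement_id` (integer 1-9),
#'   `time_min` (finite, >= 0) and `value`.
#' @param static list or one-row data.frame with `age` (years, > 0),
#'   `gender` (`"male"` or `"female"`), `vintage_years` (>= 0) and
#'   `predialytic_weight` (kg, > 0).
#' @param events data.frame with columns `event_type` (canonical vocabulary)
#'   and `time_min` in (0, session end]; may have zero rows.
#' @param scheduled_length_min scheduled session length in minutes.
#' @return An object of class `hd_session`.
#' @export
hd_session <- function(session_id, patient_id, records, static,
                       events = empty_events(),
                       scheduled_length_min = 240) {
  static <- as.list(static)
  # numeric storage is double throughout so serialization round-trips exactly
  records$measurement_id <- as.integer(records$measurement_id)
  records$time_min <- as.numeric(records$time_min)
  records$value <- as.numeric(records$value)
  if (nrow(events)) events$time_min <- as.numeric(events$time_min)
  for (f in c("age", "vintage_years", "predialytic_weight")) {
    static[[f]] <- as.numeric(static[[f]])
  }
  static$gender <- as.character(static$gender)
  scheduled_length_min <- as.numeric(scheduled_length_min)
  stopifnot(
    is.character(session_id) || is.factor(session_id),
    all(c("measurement_id", "time_min", "value") %in% names(records)),
    all(c("age", "gender", "vintage_years", "predialytic_weight") %in%
          names(static))
  )
  if (!all(is.finite(records$time_min)) || any(records$time_min < 0)) {
    stop("record times must be finite and >= 0", call. = FALSE)
  }
  if (!all(records$measurement_id %in% 1:9)) {
    stop("measurement_id must be in 1..9", call. = FALSE)
  }
  if (static$age <= 0 || static$vintage_years < 0 ||
      static$predialytic_weight <= 0) {
    stop("invalid static fields", call. = FALSE)
  }
  if (!static$gender %in% c("male", "female")) {
    stop("gender must be 'male' or 'female'", call. = FALSE)
  }
  if (nrow(events)) {
    events$event_type <- normalize_event_type(events$event_type)
    if (any(!is.finite(events$time_min)) || any(events$time_min <= 0) ||
        any(events$time_min > scheduled_length_min)) {
      stop("event times must lie in (0, scheduled_length_min]", call. = FALSE)
    }
    events <- events[order(events$time_min), , drop = FALSE]
  }
  if (any(records$time_min > scheduled_length_min)) {
    stop("record times exceed scheduled session length", call. = FALSE)
  }
  ord <- order(records$time_min)  # stable sort
  records <- records[ord, c("measurement_id", "time_min", "value"),
                     drop = FALSE]
  rownames(records) <- NULL
  rownames(events) <- NULL
  structure(
    list(
      session_id = as.character(session_id),
      patient_id = as.character(patient_id),
      records = records,
      static = static[c("age", "gender", "vintage_years",
                        "predialytic_weight")],
      events = events,
      scheduled_length_min = scheduled_length_min
    ),
    class = "hd_session"
  )
}

empty_events <- function() {
  data.frame(event_type = character(0), time_min = numeric(0),
             stringsAsFactors = FALSE)
}

#' @export
print.hd_session <- function(x, ...) {
  cat(sprintf(
    "<hd_session %s> patient %s: %d records, %d event(s), %g min scheduled\n",
    x$session_id, x$patient_id, nrow(x$records), nrow(x$events),
    x$scheduled_length_min
  ))
  invisible(x)
}

#' Number of distinct record times carrying a given measurement
#'
#' @param session an `hd_session`.
#' @param measurement_id integer measurement id (1-9).
#' @return integer count.
#' @export
n_records <- function(session, measurement_id) {
  sum(session$records$measurement_id == measurement_id)
}

#' Per-measurement series of one session
#'
#' @param session an `hd_session`.
#' @param measurement_id integer measurement id (1-9).
#' @return data.frame with columns `time_min`, `value`, sorted by time.
#' @export
measurement_series <- function(session, measurement_id) {
  r <- session$records[session$records$measurement_id == measurement_id,
                       c("time_min", "value"), drop = FALSE]
  rownames(r) <- NULL
  r
}

first_event_time <- function(session, event_types = NULL) {
  ev <- session$events
  if (!is.null(event_types)) {
    ev <- ev[ev$event_type %in% event_types, , drop = FALSE]
  }
  if (!nrow(ev)) return(NA_real_)
  min(ev$time_min)
}

# full-precision numeric formatting so CSV round-trips are exact
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    s <- format(v, digits = 17, scientific = FALSE, trim = TRUE)
    if (as.numeric(s) != v) s <- sprintf("%.17g", v)
    s
  }, character(1))
  out
}

#' Read HD sessions from the three-table CSV layout
#'
#' The on-disk layout is three UTF-8 CSV files: a long-format record table
#' (`session_id, patient_id, time_min, measurement, value` with `measurement`
#' the snake_case catalog name), a per-session metadata table
#' (`session_id, patient_id, age, gender, vintage_years, predialytic_weight,
#' scheduled_length_min`) and an event table
#' (`session_id, time_min, event_type`).
#'
#' @param session_file,metadata_file,event_file paths to the three CSVs.
#' @return list of [hd_session()] objects, one per distinct `session_id` in
#'   the metadata table, records sorted by time.
#' @export
read_sessions <- function(session_file, metadata_file, event_file) {
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      stop(sprintf("%s is missing required column(s): %s", what,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  rec <- utils::read.csv(session_file, stringsAsFactors = FALSE)
  meta <- utils::read.csv(metadata_file, stringsAsFactors = FALSE)
  ev <- utils::read.csv(event_file, stringsAsFactors = FALSE)
  need(rec, c("session_id", "patient_id", "time_min", "measurement", "value"),
       "session table")
  need(meta, c("session_id", "patient_id", "age", "gender", "vintage_years",
               "predialytic_weight", "scheduled_length_min"),
       "metadata table")
  need(ev, c("session_id", "time_min", "event_type"), "event table")

  cat_names <- measurement_catalog()$name
  bad <- !(rec$measurement %in% cat_names)
  if (any(bad)) {
    stop("unknown measurement name(s): ",
         paste(unique(rec$measurement[bad]), collapse = ", "), call. = FALSE)
  }
  if (nrow(ev)) {
    if (any(is.na(ev$time_min))) {
      stop("events without a time are not supported; offending session(s): ",
           paste(unique(ev$session_id[is.na(ev$time_min)]), collapse = ", "),
           call. = FALSE)
    }
    ev$event_type <- normalize_event_type(ev$event_type)
  }
  rec$measurement_id <- match(rec$measurement, cat_names)

  rec_split <- split(rec, rec$session_id)
  ev_split <- split(ev, ev$session_id)
  sessions <- lapply(seq_len(nrow(meta)), function(i) {
    m <- meta[i, ]
    sid <- as.character(m$session_id)
    r <- rec_split[[sid]]
    if (is.null(r)) {
      stop("session ", sid, " has no records", call. = FALSE)
    }
    e <- ev_split[[sid]]
    if (is.null(e)) e <- empty_events()
    hd_session(
      session_id = sid, patient_id = as.character(m$patient_id),
      records = r[, c("measurement_id", "time_min", "value")],
      static = list(age = m$age, gender = m$gender,
                    vintage_years = m$vintage_years,
                    predialytic_weight = m$predialytic_weight),
      events = e[, c("event_type", "time_min")],
      scheduled_length_min = m$scheduled_length_min
    )
  })
  names(sessions) <- as.character(meta$session_id)
  sessions
}

#' Write HD sessions to the three-table CSV layout
#'
#' Inverse of [read_sessions()]: numeric fields are written at full precision
#' so that a read-back reproduces every value exactly.
#'
#' @param sessions list of `hd_session` objects.
#' @param session_file,metadata_file,event_file output paths.
#' @return invisibly, the three paths.
#' @export
write_sessions <- function(sessions, session_file, metadata_file,
                           event_file) {
  cat_names <- measurement_catalog()$name
  rec <- do.call(rbind, lapply(sessions, function(s) {
    if (!nrow(s$records)) return(NULL)
    data.frame(
      session_id = s$session_id, patient_id = s$patient_id,
      time_min = fmt_num(s$records$time_min),
      measurement = cat_names[s$records$measurement_id],
      value = fmt_num(s$records$value),
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(rec)) {
    rec <- data.frame(session_id = character(0), patient_id = character(0),
                      time_min = character(0), measurement = character(0),
                      value = character(0))
  }
  meta <- do.call(rbind, lapply(sessions, function(s) {
    data.frame(
      session_id = s$session_id, patient_id = s$patient_id,
      age = fmt_num(s$static$age), gender = s$static$gender,
      vintage_years = fmt_num(s$static$vintage_years),
      predialytic_weight = fmt_num(s$static$predialytic_weight),
      scheduled_length_min = fmt_num(s$scheduled_length_min),
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(meta)) {
    meta <- data.frame(session_id = character(0), patient_id = character(0),
                       age = character(0), gender = character(0),
                       vintage_years = character(0),
                       predialytic_weight = character(0),
                       scheduled_length_min = character(0))
  }
  ev <- do.call(rbind, lapply(sessions, function(s) {
    if (!nrow(s$events)) return(NULL)
    data.frame(session_id = s$session_id,
               time_min = fmt_num(s$events$time_min),
               event_type = s$events$event_type,
               stringsAsFactors = FALSE)
  }))
  if (is.null(ev)) {
    ev <- data.frame(session_id = character(0), time_min = character(0),
                     event_type = character(0))
  }
  utils::write.csv(rec, session_file, row.names = FALSE, quote = TRUE)
  utils::write.csv(meta, metadata_file, row.names = FALSE, quote = TRUE)
  utils::write.csv(ev, event_file, row.names = FALSE, quote = TRUE)
  invisible(c(session_file, metadata_file, event_file))
}
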