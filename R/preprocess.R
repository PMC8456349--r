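# Session cleaning, LOCF value assignment, truncation and cutoff rules.
#
# Cleaning semantics:
#  * the first machine time point is dropped when the blood flow rate differs
#    between the first two recorded times (setup artifact);
#  * every record whose contemporaneous blood flow rate (by LOCF over the BFR
#    series) is <= 0 is dropped; a maximal contiguous run of nonpositive-flow
#    time counts as one interruption;
#  * a session interrupted more than once is rejected outright;
#  * a surviving session must keep at least `min_records` records for every
#    measurement (the floor needed by slope/R-squared/derivative features).

MIN_RECORDS_PER_MEASUREMENT <- 3L

#' Clean one HD session
#'
#' Applies the first-point rule, the nonpositive blood-flow drop rule and the
#' interruption-count rejection rule, and checks the per-measurement record
#' floor.
#'
#' @param session an `hd_session`.
#' @param min_records minimum surviving records required per measurement
#'   (default 3, the floor for regression and derivative features).
#' @return A list with elements `session` (the cleaned `hd_session`, or
#'   `NULL` when rejected) and `report`, a one-row data.frame with columns
#'   `session_id`, `dropped_first_point`, `n_points_dropped_nonpositive_flow`,
#'   `n_interruptions`, `rejected` and `reason`
#'   (`"multiple_interruptions"` or `"too_few_records"`).
#' @export
clean_session <- function(session, min_records = MIN_RECORDS_PER_MEASUREMENT) {
  stopifnot(inherits(session, "hd_session"))
  rec <- session$records
  if (!nrow(rec)) stop("session has no records", call. = FALSE)
  bfr <- rec[rec$measurement_id == MEAS[["bfr"]], , drop = FALSE]
  if (nrow(bfr) < 2) stop("session needs >= 2 machine records", call. = FALSE)

  report <- data.frame(
    session_id = session$session_id, dropped_first_point = FALSE,
    n_points_dropped_nonpositive_flow = 0L, n_interruptions = 0L,
    rejected = FALSE, reason = NA_character_, stringsAsFactors = FALSE
  )

  machine_ids <- MEAS[c("bfr", "vp", "tmp", "uf_rate", "uf_volume")]
  # first-point rule: drop all machine records at T_1 when BFR(T_1) != BFR(T_2)
  if (bfr$value[1] != bfr$value[2]) {
    t1 <- bfr$time_min[1]
    drop_first <- rec$measurement_id %in% machine_ids & rec$time_min == t1
    rec <- rec[!drop_first, , drop = FALSE]
    bfr <- bfr[-1, , drop = FALSE]
    report$dropped_first_point <- TRUE
  }

  # interruptions: maximal runs of BFR <= 0 along the BFR record sequence
  nonpos <- bfr$value <= 0
  runs <- rle(nonpos)
  n_int <- sum(runs$values)
  report$n_interruptions <- n_int
  if (n_int >= 2) {
    report$rejected <- TRUE
    report$reason <- "multiple_interruptions"
    return(list(session = NULL, report = report))
  }
  if (n_int == 1) {
    # drop every record whose contemporaneous (LOCF) blood flow rate is <= 0:
    # from the first nonpositive BFR time up to (excluding) the next positive
    run_idx <- which(nonpos)
    t_start <- bfr$time_min[min(run_idx)]
    nxt <- max(run_idx) + 1
    t_end <- if (nxt <= nrow(bfr)) bfr$time_min[nxt] else Inf
    in_run <- rec$time_min >= t_start & rec$time_min < t_end
    report$n_points_dropped_nonpositive_flow <- sum(in_run)
    rec <- rec[!in_run, , drop = FALSE]
  }

  out <- session
  out$records <- rec
  rownames(out$records) <- NULL
  low <- vapply(1:9, function(m) sum(rec$measurement_id == m) < min_records,
                logical(1))
  if (any(low)) {
    report$rejected <- TRUE
    report$reason <- "too_few_records"
    return(list(session = NULL, report = report))
  }
  list(session = out, report = report)
}

#' Clean a cohort of sessions
#'
#' @param sessions list of `hd_session` objects.
#' @param min_records per-measurement record floor, see [clean_session()].
#' @return list with `sessions` (the retained, cleaned sessions) and
#'   `report` (row-bound clean reports for every input session).
#' @export
clean_cohort <- function(sessions,
                         min_records = MIN_RECORDS_PER_MEASUREMENT) {
  res <- lapply(sessions, clean_session, min_records = min_records)
  keep <- !vapply(res, function(r) is.null(r$session), logical(1))
  list(
    sessions = lapply(res[keep], `[[`, "session"),
    report = do.call(rbind, c(lapply(res, `[[`, "report"),
                              list(make.row.names = FALSE)))
  )
}

#' Last-observation-carried-forward value at an arbitrary time
#'
#' The machine logs a record only when venous or transmembranous pressure
#' changes, so the value of any measurement at a time between two record
#' stamps is the most recent recorded value (right-continuous piecewise
#' constant; exact at record times).
#'
#' @param session an `hd_session`.
#' @param measurement_id integer measurement id (1-9).
#' @param t time in minutes from session start.
#' @return the carried-forward value at `t`.
#' @export
#' @examples
#' # records (0, 10), (30, 20): value at 15 min is 10, at 30 min it is 20
value_at <- function(session, measurement_id, t) {
  ser <- measurement_series(session, measurement_id)
  if (!nrow(ser)) stop("no records for measurement ", measurement_id,
                       call. = FALSE)
  idx <- findInterval(t, ser$time_min)
  if (any(idx == 0)) {
    stop("time precedes the first record for measurement ", measurement_id,
         call. = FALSE)
  }
  ser$value[idx]
}

#' Truncate an event session before its first adverse event
#'
#' Keeps only records strictly preceding the first (in-scope) adverse event;
#' the events list is retained for labeling.
#'
#' @param session an `hd_session`.
#' @param event_types optional subset of the event vocabulary; the anchor is
#'   the first event of one of these types (default: any event).
#' @return the truncated `hd_session`; a session without (in-scope) events is
#'   returned unchanged with a warning.
#' @export
truncate_before_first_event <- function(session, event_types = NULL) {
  t0 <- first_event_time(session, event_types)
  if (is.na(t0)) {
    warning("session ", session$session_id,
            " has no in-scope event; returned unchanged")
    return(session)
  }
  session$records <- session$records[session$records$time_min < t0, ,
                                     drop = FALSE]
  rownames(session$records) <- NULL
  session
}

#' Terminate feature collection at a cutoff ending time point
#'
#' The anchor is the first (in-scope) adverse event for event sessions, and
#' the last record time for event-free sessions. Records after
#' `anchor - minutes_before` are removed; the anchor time point itself is
#' excluded on event sessions (a cutoff of 0 minutes means "one time point
#' before the adverse event"), and included on event-free ones.
#'
#' @param session an `hd_session`.
#' @param minutes_before nonnegative cutoff in minutes (the experiments use
#'   0, 5, 10, 15, 20 and 60).
#' @param event_types optional event-type subset defining the anchor.
#' @return the truncated `hd_session`.
#' @export
apply_cutoff <- function(session, minutes_before, event_types = NULL) {
  stopifnot(minutes_before >= 0)
  t0 <- first_event_time(session, event_types)
  if (is.na(t0)) {
    anchor <- max(session$records$time_min)
    keep <- session$records$time_min <= anchor - minutes_before
  } else if (minutes_before == 0) {
    # "one time point before the adverse event": open right endpoint
    keep <- session$records$time_min < t0
  } else {
    keep <- session$records$time_min <= t0 - minutes_before
  }
  session$records <- session$records[keep, , drop = FALSE]
  rownames(session$records) <- NULL
  session
}

#' Truncate an event-free session to an earlier endpoint
#'
#' Used by the session-length control experiment: event-free ("negative")
#' sessions are cut to an endpoint matched to the typical length of event
#' sessions, either at a fixed time (e.g. 3.3 h = 198 min) or drawn uniformly
#' per session from a window (3-3.5 h, or the wider 2.5-3.5 h variant). The
#' value of every measurement at the endpoint is carried forward ([value_at()])
#' and appended as a final record, mirroring how the data set is defined at an
#' arbitrary termination time.
#'
#' @param session an event-free `hd_session`.
#' @param mode `"fixed"` or `"uniform"`.
#' @param window_or_point endpoint in minutes (`fixed`), or length-2 window
#'   `c(lo, hi)` (`uniform`).
#' @param seed integer seed for the uniform draw.
#' @return the truncated `hd_session`.
#' @export
truncate_negative <- function(session, mode = c("fixed", "uniform"),
                              window_or_point, seed = 1) {
  mode <- match.arg(mode)
  if (nrow(session$events)) {
    stop("truncate_negative applies only to event-free sessions",
         call. = FALSE)
  }
  if (mode == "fixed") {
    t_end <- window_or_point[1]
  } else {
    stopifnot(length(window_or_point) == 2)
    set.seed(substream_seed(seed, paste0("tend-", session$session_id)))
    t_end <- stats::runif(1, window_or_point[1], window_or_point[2])
  }
  rec <- session$records[session$records$time_min <= t_end, , drop = FALSE]
  # LOCF endpoint record for every measurement present before t_end
  endpoint <- do.call(rbind, lapply(1:9, function(m) {
    ser <- rec[rec$measurement_id == m, , drop = FALSE]
    if (!nrow(ser) || max(ser$time_min) == t_end) return(NULL)
    data.frame(measurement_id = m, time_min = t_end,
               value = ser$value[nrow(ser)])
  }))
  session$records <- rbind(rec, endpoint)
  session$records <- session$records[order(session$records$time_min), ,
                                     drop = FALSE]
  rownames(session$records) <- NULL
  session
}
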