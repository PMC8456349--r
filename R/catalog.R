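# Measurement catalog and adverse-event vocabulary shared by all modules.

#' Catalog of the nine time-varying measurements
#'
#' Each hemodialysis (HD) session carries nine time-varying series: four
#' vitals recorded by staff at 30-60 minute visits (systolic/diastolic blood
#' pressure, pulse pressure, pulse rate) and five machine series logged
#' automatically whenever venous or transmembranous pressure changes (blood
#' flow rate, venous pressure, transmembranous pressure, ultrafiltration rate,
#' cumulative ultrafiltration volume).
#'
#' @return A data.frame with columns `measurement_id` (1-9), `name`
#'   (snake_case), `unit`, and `source` (`"staff"` or `"machine"`).
#' @export
#' @examples
#' measurement_catalog()
measurement_catalog <- function() {
  data.frame(
    measurement_id = 1:9,
    name = c(
      "systolic_blood_pressure", "diastolic_blood_pressure",
      "pulse_pressure", "pulse_rate", "blood_flow_rate",
      "venous_pressure", "transmembranous_pressure",
      "uf_rate", "uf_volume"
    ),
    unit = c("mmHg", "mmHg", "mmHg", "bpm", "mL/min",
             "mmHg", "mmHg", "mL/h", "mL"),
    source = c("staff", "staff", "staff", "staff", "machine",
               "machine", "machine", "machine", "machine"),
    stringsAsFactors = FALSE
  )
}

# id lookup used throughout; BFR drives the cleaning rules
MEAS <- c(
  sbp = 1L, dbp = 2L, pp = 3L, pulse = 4L, bfr = 5L,
  vp = 6L, tmp = 7L, uf_rate = 8L, uf_volume = 9L
)

#' Closed vocabulary of intradialytic adverse events
#'
#' The 27 event categories documented by dialysis staff, with the episode
#' counts observed in a three-month single-center cohort. The counts serve as
#' the empirical type distribution for the synthetic generator.
#'
#' @return A data.frame with columns `event_type` (snake_case) and
#'   `episodes` (observed episode count).
#' @export
adverse_event_types <- function() {
  data.frame(
    event_type = c(
      "muscle_cramps", "blood_pressure_elevation", "low_blood_pressure",
      "miscellaneous", "headache", "lightheadedness", "chest_tightness",
      "vascular_access_thrombosis", "cold_sweating", "nausea_vomiting",
      "fever", "tachycardia", "dyspnea", "hoarseness", "chills",
      "leg_pain", "low_back_pain", "shoulder_pain", "altered_mental_status",
      "chest_discomfort", "numb_hands", "tinnitus",
      "vascular_access_occlusion", "abdominal_pain", "hypersomnia",
      "palpitation", "pruritus"
    ),
    episodes = c(138L, 108L, 64L, 45L, 28L, 26L, 23L, 23L, 22L, 12L,
                 10L, 10L, 8L, 8L, 5L, 5L, 5L, 5L, 4L, 3L, 3L, 3L,
                 3L, 2L, 1L, 1L, 1L),
    stringsAsFactors = FALSE
  )
}

#' Normalize an adverse-event label to the canonical vocabulary
#'
#' Accepts free-form capitalization and punctuation (e.g. `"Muscle cramps"`,
#' `"Nausea/vomiting"`) and maps to the snake_case vocabulary; unknown types
#' raise an error naming the offending label.
#'
#' @param x character vector of event labels.
#' @return character vector of canonical event types.
#' @export
normalize_event_type <- function(x) {
  canon <- adverse_event_types()$event_type
  norm <- tolower(trimws(as.character(x)))
  norm <- gsub("[^a-z0-9]+", "_", norm)
  norm <- gsub("^_+|_+$", "", norm)
  bad <- !(norm %in% canon)
  if (any(bad)) {
    stop("unknown adverse event type(s): ",
         paste(unique(x[bad]), collapse = ", "),
         call. = FALSE)
  }
  norm
}
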