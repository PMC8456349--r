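# Synthetic HD-cohort generator with a known event-generating mechanism.
#
# Latent model per session: patient-level baseline + session-level linear
# drift + AR(1) (discretized Ornstein-Uhlenbeck) jitter for the pressure
# channels, discretized by the machine trigger rule (a record is emitted only
# when venous or transmembranous pressure moves by more than
# `machine_trigger_sd` since the last emitted record). Staff vitals appear
# only at visit times spaced `vitals_interval_min` apart. The event hazard is
# a logistic function of configured session-level latent quantities, so
# feature-recovery is testable against ground truth.

#' Simulation configuration for a synthetic HD cohort
#'
#' Defaults emulate the cohort the pipeline is designed for: 108 patients on
#' thrice-weekly maintenance HD for three months (39-40 sessions each, about
#' 4200 sessions), roughly 4-hour sessions, 9.6% of sessions carrying at
#' least one adverse event, events concentrated in the second half of the
#' session, staff vitals every 30-60 minutes, and machine records triggered
#' by venous/transmembranous pressure changes.
#'
#' @param n_patients number of patients (>= 1).
#' @param sessions_per_patient integer vector of allowed per-patient session
#'   counts; each patient draws one uniformly (default `c(39, 40)`).
#' @param seed integer root seed; fully determines the cohort. Named
#'   substreams (statics, trajectories, events, interruptions) are derived
#'   from it so stages are independently reproducible.
#' @param event_session_fraction target fraction of sessions with >= 1
#'   adverse event (default 0.096).
#' @param signal_features data.frame with columns `measurement` (catalog
#'   name), `stat` (`"mean"` or `"slope"`) and `effect` (log-odds per SD of
#'   the session-level latent quantity). The default couples the hazard to a
#'   falling systolic-pressure drift and a high mean ultrafiltration rate.
#'   An empty data.frame gives labels independent of all features.
#' @param vitals_interval_min length-2 range of staff-visit spacing (min).
#' @param machine_trigger_sd pressure change (mmHg) that triggers a machine
#'   record.
#' @param second_half_event_bias probability that an event falls after the
#'   session midpoint (default 0.8).
#' @param scheduled_length_min scheduled session length (default 240).
#' @param first_point_artifact_prob fraction of sessions whose first machine
#'   record carries a not-yet-ramped-up blood flow rate, exercising the
#'   first-point cleaning rule.
#' @param grid_step_min latent-trajectory discretization step (min).
#' @return A list of class `hd_sim_config`.
#' @export
simulation_config <- function(n_patients = 108,
                              sessions_per_patient = c(39, 40),
                              seed = 1,
                              event_session_fraction = 0.096,
                              signal_features = default_signal_features(),
                              vitals_interval_min = c(30, 60),
                              machine_trigger_sd = 5,
                              second_half_event_bias = 0.8,
                              scheduled_length_min = 240,
                              first_point_artifact_prob = 0.3,
                              grid_step_min = 2) {
  if (n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  if (any(sessions_per_patient < 1)) {
    stop("sessions_per_patient must be >= 1", call. = FALSE)
  }
  if (event_session_fraction < 0 || event_session_fraction > 1 ||
      second_half_event_bias < 0 || second_half_event_bias > 1) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (nrow(signal_features)) {
    stopifnot(all(c("measurement", "stat", "effect") %in%
                    names(signal_features)))
    if (!all(signal_features$measurement %in% measurement_catalog()$name)) {
      stop("signal_features$measurement must be catalog names", call. = FALSE)
    }
    if (!all(signal_features$stat %in% c("mean", "slope"))) {
      stop("signal_features$stat must be 'mean' or 'slope'", call. = FALSE)
    }
  }
  structure(
    list(n_patients = n_patients,
         sessions_per_patient = as.integer(sessions_per_patient),
         seed = as.integer(seed),
         event_session_fraction = event_session_fraction,
         signal_features = signal_features,
         vitals_interval_min = vitals_interval_min,
         machine_trigger_sd = machine_trigger_sd,
         second_half_event_bias = second_half_event_bias,
         scheduled_length_min = scheduled_length_min,
         first_point_artifact_prob = first_point_artifact_prob,
         grid_step_min = grid_step_min),
    class = "hd_sim_config"
  )
}

#' @rdname simulation_config
#' @export
default_signal_features <- function() {
  data.frame(
    measurement = c("systolic_blood_pressure", "uf_rate"),
    stat = c("slope", "mean"),
    effect = c(-1.2, 1.0),
    stringsAsFactors = FALSE
  )
}

# sample one/many elements of a vector without the 1:n surprise of sample()
pick1 <- function(v) v[sample.int(length(v), 1)]
pickn <- function(v, n, replace = FALSE, prob = NULL) {
  v[sample.int(length(v), n, replace = replace, prob = prob)]
}

# deterministic substream seed, always < 2^31
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  (as.integer(seed) %% 1000003L) * 1009L + (h %% 1009L)
}

#' Simulate a synthetic HD cohort
#'
#' @param config an [simulation_config()] object.
#' @return A list with elements `sessions` (list of [hd_session()]) and
#'   `ground_truth` (per-session event probabilities, the latent quantities
#'   and coefficients actually used, and the realized event flags).
#' @export
#' @examples
#' sim <- simulate_cohort(simulation_config(n_patients = 3, seed = 7))
#' length(sim$sessions)
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "hd_sim_config"))
  L <- config$scheduled_length_min

  ## -- patient statics ------------------------------------------------------
  set.seed(substream_seed(config$seed, "statics"))
  np <- config$n_patients
  age <- round(truncnorm(np, 64, 12, lower = 18), 1)
  gender <- ifelse(stats::runif(np) < 0.56, "male", "female")
  vintage <- round(stats::rgamma(np, shape = 2, scale = 3.85), 1)
  weight <- round(truncnorm(np, 62, 11, lower = 35), 1)
  nsess <- pickn(config$sessions_per_patient, np, replace = TRUE)
  # patient-level baselines
  p_sbp <- stats::rnorm(np, 140, 15)
  p_dbp <- stats::rnorm(np, 72, 8)
  p_pulse <- stats::rnorm(np, 76, 8)
  p_bfr <- round(truncnorm(np, 260, 25, lower = 200) / 10) * 10
  p_vp <- stats::rnorm(np, 120, 15)
  p_tmp <- stats::rnorm(np, 100, 18)
  p_ufshare <- truncnorm(np, 40, 8, lower = 20)  # mL per kg per session

  ## -- session latent trajectories and records ------------------------------
  set.seed(substream_seed(config$seed, "trajectories"))
  pat_idx <- rep(seq_len(np), nsess)
  n <- length(pat_idx)
  sess_num <- unlist(lapply(nsess, seq_len), use.names = FALSE)
  grid <- seq(0, L, by = config$grid_step_min)
  phi <- exp(-config$grid_step_min / 30)  # OU mean-reversion, tau = 30 min
  ou_sd <- 6
  cat_names <- measurement_catalog()$name

  sessions <- vector("list", n)
  latent <- vector("list", n)
  for (i in seq_len(n)) {
    p <- pat_idx[i]
    # session-level drifts and offsets
    sbp_slope <- stats::rnorm(1, -0.05, 0.08)
    dbp_slope <- 0.5 * sbp_slope + stats::rnorm(1, 0, 0.02)
    pulse_slope <- stats::rnorm(1, 0, 0.03)
    vp_slope <- stats::rnorm(1, 0.05, 0.06)
    tmp_slope <- stats::rnorm(1, 0.10, 0.08)
    sbp0 <- p_sbp[p] + stats::rnorm(1, 0, 8)
    dbp0 <- p_dbp[p] + stats::rnorm(1, 0, 5)
    pulse0 <- p_pulse[p] + stats::rnorm(1, 0, 4)
    vp0 <- p_vp[p] + stats::rnorm(1, 0, 6)
    tmp0 <- p_tmp[p] + stats::rnorm(1, 0, 8)
    bfr <- p_bfr[p]

    # ultrafiltration plan: piecewise-constant rate, staff adjusts 0-3 times
    vol_target <- p_ufshare[p] * weight[p] * stats::runif(1, 0.85, 1.15)
    n_adj <- stats::rpois(1, 1.2)
    adj_t <- sort(stats::runif(n_adj, 30, L - 30))
    seg_t <- c(0, adj_t, L)
    rate0 <- vol_target / (L / 60)
    rates <- rate0 * cumprod(c(1, stats::runif(n_adj, 0.75, 1.25)))
    rates <- round(pmax(rates, 50))

    # pressure channels on the latent grid
    ou_vp <- as.numeric(stats::filter(
      stats::rnorm(length(grid), 0, ou_sd * sqrt(1 - phi^2)),
      phi, method = "recursive", init = stats::rnorm(1, 0, ou_sd)))
    ou_tmp <- as.numeric(stats::filter(
      stats::rnorm(length(grid), 0, ou_sd * sqrt(1 - phi^2)),
      phi, method = "recursive", init = stats::rnorm(1, 0, ou_sd)))
    vp_t <- vp0 + vp_slope * grid + ou_vp
    tmp_t <- tmp0 + tmp_slope * grid + ou_tmp

    # machine trigger rule: emit when either pressure moved enough,
    # at UF-rate adjustments, at start, and at session end
    force_idx <- unique(c(1L, vapply(adj_t, function(a) {
      which.min(abs(grid - a))
    }, integer(1)), length(grid)))
    emit <- logical(length(grid))
    last_vp <- vp_t[1]; last_tmp <- tmp_t[1]
    emit[1] <- TRUE
    for (g in 2:length(grid)) {
      if (abs(vp_t[g] - last_vp) > config$machine_trigger_sd ||
          abs(tmp_t[g] - last_tmp) > config$machine_trigger_sd ||
          g %in% force_idx) {
        emit[g] <- TRUE
        last_vp <- vp_t[g]; last_tmp <- tmp_t[g]
      }
    }
    mt <- grid[emit]
    seg_of <- findInterval(mt, seg_t, rightmost.closed = TRUE)
    rate_at <- rates[pmin(seg_of, length(rates))]
    # cumulative volume: integral of the piecewise-constant rate (mL/h)
    seg_cum <- c(0, cumsum(rates * diff(seg_t) / 60))
    vol_at <- seg_cum[seg_of] + rate_at * (mt - seg_t[seg_of]) / 60
    bfr_at <- rep(bfr, length(mt))
    if (stats::runif(1) < config$first_point_artifact_prob) {
      bfr_at[1] <- max(bfr - 100, 80)  # pump still ramping up at first log
    }
    machine <- data.frame(
      measurement_id = rep(c(MEAS[["bfr"]], MEAS[["vp"]], MEAS[["tmp"]],
                             MEAS[["uf_rate"]], MEAS[["uf_volume"]]),
                           each = length(mt)),
      time_min = rep(mt, 5),
      value = c(bfr_at, round(vp_t[emit]), round(tmp_t[emit]),
                rate_at, round(vol_at))
    )

    # staff vitals every 30-60 minutes
    vt <- 0
    repeat {
      nxt <- vt[length(vt)] + stats::runif(1, config$vitals_interval_min[1],
                                           config$vitals_interval_min[2])
      if (nxt > L) break
      vt <- c(vt, nxt)
    }
    vt <- round(vt)
    sbp_v <- round(sbp0 + sbp_slope * vt + stats::rnorm(length(vt), 0, 4))
    dbp_v <- round(dbp0 + dbp_slope * vt + stats::rnorm(length(vt), 0, 3))
    dbp_v <- pmin(dbp_v, sbp_v - 10)  # keep pulse pressure physiological
    pulse_v <- round(pulse0 + pulse_slope * vt +
                       stats::rnorm(length(vt), 0, 3))
    vitals <- data.frame(
      measurement_id = rep(c(MEAS[["sbp"]], MEAS[["dbp"]], MEAS[["pp"]],
                             MEAS[["pulse"]]), each = length(vt)),
      time_min = rep(vt, 4),
      value = c(sbp_v, dbp_v, sbp_v - dbp_v, pulse_v)
    )

    sessions[[i]] <- hd_session(
      session_id = sprintf("P%03d-S%02d", p, sess_num[i]),
      patient_id = sprintf("P%03d", p),
      records = rbind(machine, vitals),
      static = list(age = age[p], gender = gender[p],
                    vintage_years = vintage[p],
                    predialytic_weight = weight[p]),
      scheduled_length_min = L
    )
    mean_rate <- vol_target / (L / 60)
    latent[[i]] <- data.frame(
      measurement = cat_names,
      mean = c(sbp0 + sbp_slope * L / 2, dbp0 + dbp_slope * L / 2,
               (sbp0 - dbp0) + (sbp_slope - dbp_slope) * L / 2,
               pulse0 + pulse_slope * L / 2, bfr,
               vp0 + vp_slope * L / 2, tmp0 + tmp_slope * L / 2,
               mean_rate, vol_target / 2),
      slope = c(sbp_slope, dbp_slope, sbp_slope - dbp_slope, pulse_slope, 0,
                vp_slope, tmp_slope, 0, mean_rate / 60),
      stringsAsFactors = FALSE
    )
  }

  ## -- event mechanism ------------------------------------------------------
  set.seed(substream_seed(config$seed, "events"))
  sf <- config$signal_features
  eta <- numeric(n)
  if (nrow(sf)) {
    for (r in seq_len(nrow(sf))) {
      q <- vapply(latent, function(df) {
        df[df$measurement == sf$measurement[r], sf$stat[r]]
      }, numeric(1))
      s_q <- if (length(q) > 1) stats::sd(q) else 0
      z <- if (s_q > 1e-12) (q - mean(q)) / s_q else rep(0, length(q))
      eta <- eta + sf$effect[r] * z
    }
  }
  target <- config$event_session_fraction
  if (target == 0) {
    prob <- rep(0, n)
    alpha <- -Inf
  } else if (!nrow(sf) || all(eta == 0)) {
    alpha <- stats::qlogis(target)
    prob <- rep(target, n)
  } else {
    alpha <- stats::uniroot(
      function(a) mean(stats::plogis(a + eta)) - target,
      interval = c(-30, 30), tol = 1e-10)$root
    prob <- stats::plogis(alpha + eta)
  }
  has_event <- stats::runif(n) < prob
  vocab <- adverse_event_types()
  # multi-event multiplicity follows the observed 276:106:19:4 split
  mult_p <- c(276, 106, 19, 4) / 405
  for (i in which(has_event)) {
    k <- pickn(1:4, 1, prob = mult_p)
    if (stats::runif(1) < config$second_half_event_bias) {
      # triangular on the second half, density rising toward the session end
      t1 <- L / 2 + (L / 2 - 5) * sqrt(stats::runif(1))
    } else {
      t1 <- stats::runif(1, 20, L / 2)
    }
    t1 <- round(t1)
    extra <- if (k > 1) sort(round(stats::runif(k - 1, t1, L))) else numeric(0)
    types <- pickn(vocab$event_type, k, replace = TRUE,
                   prob = vocab$episodes)
    s <- sessions[[i]]
    s$events <- data.frame(event_type = types,
                           time_min = c(t1, extra),
                           stringsAsFactors = FALSE)
    s$events <- s$events[order(s$events$time_min), , drop = FALSE]
    rownames(s$events) <- NULL
    sessions[[i]] <- s
  }
  names(sessions) <- vapply(sessions, `[[`, character(1), "session_id")

  gt <- structure(
    list(event_prob = stats::setNames(prob, names(sessions)),
         intercept = alpha,
         signal_features = sf,
         latent = stats::setNames(latent, names(sessions)),
         has_event = stats::setNames(has_event, names(sessions)),
         config = config),
    class = "hd_ground_truth"
  )
  list(sessions = sessions, ground_truth = gt)
}

truncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- x < lower | x > upper
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- x < lower | x > upper
  }
  x
}

#' Inject blood-flow interruptions into a cohort
#'
#' Sets the blood flow rate to zero over short runs of machine records in a
#' chosen fraction of sessions — one run (`fraction_single`) or two separated
#' runs (`fraction_multiple`) — to exercise the cleaning rules. The injected
#' counts are recorded in the `"injected_interruptions"` attribute so tests
#' can require exact agreement with the cleaner's decisions.
#'
#' @param sessions list of `hd_session` objects.
#' @param fraction_single,fraction_multiple fractions of sessions receiving
#'   one, respectively two, interruptions (sum must be <= 1).
#' @param seed integer seed.
#' @return The modified session list with attribute
#'   `"injected_interruptions"`: a data.frame of `session_id` and
#'   `n_interruptions` for every session.
#' @export
simulate_interruptions <- function(sessions, fraction_single = 0,
                                   fraction_multiple = 0, seed = 1) {
  if (fraction_single + fraction_multiple > 1) {
    stop("interruption fractions must sum to <= 1", call. = FALSE)
  }
  set.seed(substream_seed(seed, "interruptions"))
  n <- length(sessions)
  n_one <- round(fraction_single * n)
  n_two <- round(fraction_multiple * n)
  pick <- sample(n, n_one + n_two)
  one_ids <- pick[seq_len(n_one)]
  two_ids <- pick[n_one + seq_len(n_two)]
  n_inj <- integer(n)
  inject <- function(s, runs) {
    bfr_pos <- which(s$records$measurement_id == MEAS[["bfr"]])
    nb <- length(bfr_pos)
    # keep the first two and last BFR records intact so the first-point rule
    # and the session end are unaffected; runs of length 2 separated by >= 2
    # clean records
    if (nb < 12) return(NULL)
    starts <- if (runs == 1) {
      pick1(3:(nb - 3))
    } else {
      s1 <- pick1(3:(nb - 9))
      c(s1, pick1((s1 + 4):(nb - 3)))
    }
    for (st in starts) {
      s$records$value[bfr_pos[c(st, st + 1)]] <- 0
    }
    s
  }
  for (i in one_ids) {
    out <- inject(sessions[[i]], 1)
    if (!is.null(out)) {
      sessions[[i]] <- out
      n_inj[i] <- 1L
    }
  }
  for (i in two_ids) {
    out <- inject(sessions[[i]], 2)
    if (!is.null(out)) {
      sessions[[i]] <- out
      n_inj[i] <- 2L
    }
  }
  attr(sessions, "injected_interruptions") <- data.frame(
    session_id = vapply(sessions, `[[`, character(1), "session_id"),
    n_interruptions = n_inj,
    stringsAsFactors = FALSE
  )
  sessions
}
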