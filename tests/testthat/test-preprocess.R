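test_that("first machine time point is dropped iff blood flow varied", {
  varied <- make_test_session(bfr = function(t) c(150, rep(250, length(t) - 1)))
  res <- clean_session(varied)
  expect_true(res$report$dropped_first_point)
  expect_false(0 %in% measurement_series(res$session, 6)$time_min)
  # staff vitals at t = 0 are untouched by the machine-artifact rule
  expect_true(0 %in% measurement_series(res$session, 1)$time_min)

  steady <- make_test_session()
  res2 <- clean_session(steady)
  expect_false(res2$report$dropped_first_point)
  expect_false(res2$report$rejected)
  expect_equal(res2$report$n_points_dropped_nonpositive_flow, 0)
  expect_identical(res2$session$records, steady$records)
})

test_that("two separated zero-flow runs reject the session", {
  two <- make_test_session(bfr = function(t) {
    v <- rep(250, length(t))
    v[c(5, 6, 12)] <- 0  # runs at records 5-6 and 12
    v
  })
  res <- clean_session(two)
  expect_true(res$report$rejected)
  expect_equal(res$report$reason, "multiple_interruptions")
  expect_equal(res$report$n_interruptions, 2)
  expect_null(res$session)
})

test_that("one interruption drops all records inside the nonpositive-flow run", {
  one <- make_test_session(bfr = function(t) {
    v <- rep(250, length(t))
    v[t >= 100 & t < 130] <- 0  # machine records at 100, 110, 120
    v
  }, vitals_step = 55)  # vital at 110 falls inside the run
  res <- clean_session(one)
  expect_false(res$report$rejected)
  expect_equal(res$report$n_interruptions, 1)
  kept <- res$session$records
  expect_false(any(kept$time_min >= 100 & kept$time_min < 130))
  expect_true(110 %in% one$records$time_min[one$records$measurement_id == 1])
  expect_false(110 %in% kept$time_min)
})

test_that("cleaning is idempotent", {
  s <- make_test_session(bfr = function(t) {
    v <- c(150, rep(250, length(t) - 1)); v[8:9] <- 0; v
  })
  once <- clean_session(s)$session
  twice <- clean_session(once)$session
  expect_identical(twice$records, once$records)
})

test_that("sessions under the record floor are excluded with a reason", {
  tiny <- make_test_session(machine_step = 120)  # 3 machine records
  expect_false(clean_session(tiny)$report$rejected)
  tinier <- make_test_session(machine_step = 240)  # 2 machine records
  res <- clean_session(tinier)
  expect_true(res$report$rejected)
  expect_equal(res$report$reason, "too_few_records")
})

test_that("value_at carries the last observation forward", {
  rec <- data.frame(measurement_id = c(5, 5), time_min = c(0, 30),
                    value = c(10, 20))
  s <- hd_session("a", "p", rec, default_static())
  expect_equal(value_at(s, 5, 15), 10)
  expect_equal(value_at(s, 5, 30), 20)   # exact at record times
  expect_equal(value_at(s, 5, 239), 20)  # constant extension
  expect_equal(value_at(s, 5, c(0, 10, 30, 100)), c(10, 10, 20, 20))
  expect_error(value_at(s, 5, -1), "precedes")
  one <- hd_session("b", "p",
                    data.frame(measurement_id = 5, time_min = 0, value = 7),
                    default_static())
  expect_equal(value_at(one, 5, 239), 7)
})

test_that("value_at is piecewise constant and right-continuous", {
  s <- make_test_session()
  ser <- measurement_series(s, 6)
  for (k in 2:6) {
    t_prev <- ser$time_min[k - 1]
    t_k <- ser$time_min[k]
    mid <- stats::runif(3, t_prev, t_k - 1e-9)
    expect_equal(value_at(s, 6, mid), rep(ser$value[k - 1], 3))
    expect_equal(value_at(s, 6, t_k), ser$value[k])
  }
})

test_that("truncation before the first event keeps strictly earlier records", {
  s <- make_test_session(events = data.frame(event_type = "muscle_cramps",
                                             time_min = 150))
  tr <- truncate_before_first_event(s)
  expect_true(all(tr$records$time_min < 150))
  expect_equal(nrow(tr$events), 1)  # events retained for labeling
  expect_warning(out <- truncate_before_first_event(make_test_session()),
                 "no in-scope event")
  expect_identical(out$records, make_test_session()$records)
})

test_that("cutoff semantics match the experiment design", {
  ev <- make_test_session(events = data.frame(event_type = "headache",
                                              time_min = 180))
  c20 <- apply_cutoff(ev, 20)
  expect_true(all(c20$records$time_min <= 160))
  expect_true(160 %in% c20$records$time_min)  # endpoint included

  free <- make_test_session()
  c60 <- apply_cutoff(free, 60)
  expect_equal(max(c60$records$time_min), 180)
  expect_identical(apply_cutoff(free, 0)$records, free$records)

  # cutoff 0 on an event session equals first-event truncation
  expect_identical(apply_cutoff(ev, 0)$records,
                   truncate_before_first_event(ev)$records)
})

test_that("cutoffs nest monotonically", {
  sim <- shared_cohort()
  labs <- label_sessions(sim$sessions)
  some <- c(sim$sessions[labs == 1][1:3], sim$sessions[labs == 0][1:3])
  cuts <- c(0, 5, 10, 15, 20, 60)
  for (s in some) {
    prev <- NULL
    for (m in rev(cuts)) {  # largest cutoff = fewest records
      cur <- apply_cutoff(s, m)$records
      if (!is.null(prev)) {
        key <- function(r) paste(r$measurement_id, r$time_min)
        expect_true(all(key(prev) %in% key(cur)))
      }
      prev <- cur
    }
  }
})

test_that("negative-session truncation appends an LOCF endpoint record", {
  s <- make_test_session()
  fx <- truncate_negative(s, "fixed", 198)
  expect_equal(max(fx$records$time_min), 198)
  for (m in c(1, 5, 6, 9)) {
    ser <- measurement_series(fx, m)
    expect_equal(ser$time_min[nrow(ser)], 198)
    expect_equal(ser$value[nrow(ser)], value_at(s, m, 198))
  }

  u1 <- truncate_negative(s, "uniform", c(180, 210), seed = 1)
  u2 <- truncate_negative(s, "uniform", c(180, 210), seed = 2)
  e1 <- max(u1$records$time_min)
  e2 <- max(u2$records$time_min)
  expect_true(e1 >= 180 && e1 <= 210)
  expect_true(e2 >= 180 && e2 <= 210)
  expect_false(e1 == e2)
  w <- truncate_negative(s, "uniform", c(150, 210), seed = 3)
  expect_true(max(w$records$time_min) >= 150)

  ev <- make_test_session(events = data.frame(event_type = "chills",
                                              time_min = 100))
  expect_error(truncate_negative(ev, "fixed", 198), "event-free")
})
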