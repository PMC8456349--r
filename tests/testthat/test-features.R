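test_that("linear summaries match hand and brute-force values", {
  s <- linear_summary(c(0, 30, 60), c(10, 20, 30))
  expect_equal(s$mean, 20)
  expect_equal(s$max, 30)
  expect_equal(s$min, 10)

  # frozen values computed from the n-1 definition by hand:
  # x = [2,4,4,4,5,5,7,9], mean 5, sum sq dev 32, sd = sqrt(32/7)
  x <- c(2, 4, 4, 4, 5, 5, 7, 9)
  s2 <- linear_summary(seq_along(x), x)
  expect_equal(s2$sd, sqrt(32 / 7), tolerance = 1e-12)
  expect_equal(s2$sd_of_mean, sqrt(32 / 7) / sqrt(8), tolerance = 1e-12)
  expect_equal(s2$cv, sqrt(32 / 7) / 5, tolerance = 1e-12)

  cst <- linear_summary(c(0, 10, 20), c(7, 7, 7))
  expect_equal(cst$sd_of_mean, 0)
  expect_equal(cst$cv, 0)
  expect_error(linear_summary(numeric(0), numeric(0)), "empty")
  expect_true(is.nan(linear_summary(1:3, c(-1, 0, 1))$cv))
})

test_that("regression summaries equal the least-squares oracle", {
  r <- regression_summary(c(0, 60, 120), c(0, 60, 120))
  expect_equal(r$slope, 1)
  expect_equal(r$r_squared, 1)
  expect_equal(regression_summary(c(0, 30, 60), c(5, 5, 5)),
               list(slope = 0, r_squared = 0))
  expect_error(regression_summary(c(3, 3, 3), 1:3), "distinct")

  # spec'd 4-point case against the normal equations via lm()
  t4 <- c(0, 30, 60, 90); y4 <- c(1, 3, 2, 5)
  fit <- stats::lm(y4 ~ t4)
  r4 <- regression_summary(t4, y4)
  expect_equal(r4$slope, unname(stats::coef(fit)[2]), tolerance = 1e-12)
  expect_equal(r4$r_squared, summary(fit)$r.squared, tolerance = 1e-12)

  set.seed(42)
  for (i in 1:50) {
    n <- sample(3:12, 1)
    t <- sort(stats::runif(n, 0, 240))
    y <- stats::rnorm(n, 100, 20)
    fit <- stats::lm(y ~ t)
    r <- regression_summary(t, y)
    expect_equal(r$slope, unname(stats::coef(fit)[2]), tolerance = 1e-10)
    expect_equal(r$r_squared, summary(fit)$r.squared, tolerance = 1e-10)
  }
})

test_that("derivative summaries are exact finite differences", {
  d <- derivative_summary(c(0, 1, 2), c(0, 1, 4))
  expect_equal(c(d$d1_max, d$d1_min, d$d1_mean), c(3, 1, 2))
  expect_equal(c(d$d2_max, d$d2_min, d$d2_mean), c(2, 2, 2))

  t <- c(0, 10, 25, 45, 70)
  lin <- derivative_summary(t, 5 + 0.3 * t)
  expect_equal(lin$d1_max, 0.3, tolerance = 1e-12)
  expect_equal(lin$d1_min, 0.3, tolerance = 1e-12)
  expect_equal(lin$d2_max, 0, tolerance = 1e-12)

  mono <- derivative_summary(c(0, 5, 12, 30), c(1, 4, 4, 9))
  expect_gte(mono$d1_min, 0)

  # duplicate timestamps collapse to the last value before differencing
  dup <- derivative_summary(c(0, 10, 10, 20), c(1, 99, 2, 3))
  expect_equal(dup$d1_max,
               derivative_summary(c(0, 10, 20), c(1, 2, 3))$d1_max)
  expect_error(derivative_summary(c(0, 10), c(1, 2)), ">= 3")
})

test_that("ultrafiltration rate changes are counted as defined", {
  ch <- uf_rate_changes(1:5, c(500, 500, 700, 700, 300))
  expect_equal(ch$count_of_changes, 2)
  expect_equal(ch$mean_of_changes, -100)
  cst <- uf_rate_changes(1:4, rep(600, 4))
  expect_equal(cst$count_of_changes, 0)
  expect_equal(cst$mean_of_changes, 0)
  two <- uf_rate_changes(1:2, c(400, 700))
  expect_equal(two$count_of_changes, 1)
  expect_equal(two$mean_of_changes, 300)
})

test_that("registry satisfies all pinned constraints", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 84)
  expect_equal(reg$index, 1:84)
  expect_equal(anyDuplicated(reg$name), 0)
  expect_true(all(reg$index[reg$uf_rate] == 70:77))
  expect_true(all(reg$index[reg$uf_volume] == 78:83))
  expect_equal(sum(reg$uf_rate | reg$uf_volume), 14)
  expect_equal(sum(!(reg$uf_rate | reg$uf_volume)), 70)
  expect_equal(sum(reg$bp_related), 24)
  expect_equal(reg$name[reg$demographic],
               c("gender", "age", "vintage_years", "predialytic_weight"))
  expect_equal(sum(reg$top21), 21)
  expect_false(any(reg$top21 & (reg$uf_rate | reg$uf_volume)))
  # pinned indices
  expect_equal(reg$kind[76], "count_of_changes")
  expect_equal(reg$name[77], "uf_rate_mean_of_changes")
  expect_equal(reg$name[78], "uf_volume_max")
  expect_equal(reg$name[82], "uf_volume_slope")
  # second-order venous-pressure parameters occupy 47-52
  expect_true(all(reg$source[47:52] == "venous_pressure"))
  expect_true(all(grepl("^d[12]_", reg$kind[47:52])))
})

test_that("extraction yields 84 finite features and honors group subsets", {
  sim <- shared_cohort()
  cl <- clean_cohort(sim$sessions[1:30])
  ft <- build_feature_table(cl$sessions)
  expect_equal(ncol(ft$features), 84)
  expect_true(all(is.finite(ft$features)))
  reg <- feature_registry()
  expect_equal(ncol(feature_subset(ft$features, reg, "uf")), 14)
  expect_equal(ncol(feature_subset(ft$features, reg, "not_uf")), 70)
  expect_equal(ncol(feature_subset(ft$features, reg, "bp")), 24)
  expect_equal(ncol(feature_subset(ft$features, reg, "top21")), 21)
  expect_error(feature_subset(ft$features, reg, "florbs"))
})

test_that("a constant session yields zero slopes, CVs and derivatives", {
  s <- make_test_session(
    bfr = function(t) rep(250, length(t)),
    vp = function(t) rep(100, length(t)),
    tmp = function(t) rep(90, length(t)),
    uf_rate = function(t) rep(600, length(t)),
    uf_volume = function(t) rep(1200, length(t)),
    sbp = function(t) rep(140, length(t)),
    dbp = function(t) rep(75, length(t)),
    pulse = function(t) rep(76, length(t)))
  v <- extract_features(s)
  reg <- feature_registry()
  expect_true(all(v[reg$kind %in% c("slope", "cv", "sd_of_mean",
                                    "r_squared")] == 0))
  expect_true(all(v[grepl("^d[12]_", reg$kind)] == 0))
  expect_true(all(v[reg$kind == "count_of_changes"] == 0))
  expect_equal(unname(v[c("age", "gender", "vintage_years",
                          "predialytic_weight")]),
               c(60, 1, 5, 62))
})

test_that("extraction is scale-covariant per measurement", {
  s <- make_test_session()
  v0 <- extract_features(s)
  c_ <- 2.5
  s2 <- s
  idx <- s2$records$measurement_id == 6  # venous pressure
  s2$records$value[idx] <- s2$records$value[idx] * c_
  v1 <- extract_features(s2)
  reg <- feature_registry()
  vp <- reg$source == "venous_pressure"
  scaled <- vp & reg$kind %in% c("mean", "sd_of_mean", "max", "min", "slope",
                                 "d1_max", "d1_min", "d1_mean", "d2_max",
                                 "d2_min", "d2_mean")
  invariant <- vp & reg$kind %in% c("cv", "r_squared", "count_of_changes")
  other <- !vp
  expect_equal(v1[scaled], c_ * v0[scaled], tolerance = 1e-12)
  expect_equal(v1[invariant], v0[invariant], tolerance = 1e-12)
  expect_equal(v1[other], v0[other])
})

test_that("features depend only on records up to the cutoff anchor", {
  s <- make_test_session(events = data.frame(event_type = "muscle_cramps",
                                             time_min = 150))
  for (m in c(0, 5, 20)) {
    cut <- apply_cutoff(s, m)
    v0 <- extract_features(cut)
    mut <- s
    late <- if (m == 0) mut$records$time_min >= 150 else
      mut$records$time_min > 150 - m
    mut$records$value[late] <- mut$records$value[late] + 1000
    v1 <- extract_features(apply_cutoff(mut, m))
    expect_identical(v1, v0)
  }
})

test_that("sessions under the record floor are excluded at extraction", {
  s <- make_test_session(events = data.frame(event_type = "headache",
                                             time_min = 15))
  expect_error(extract_features(apply_cutoff(s, 0)), "record floor")
  ft <- build_feature_table(list(s1 = s))
  expect_equal(nrow(ft$excluded), 1)
  expect_match(ft$excluded$reason, "record floor")
})

test_that("label-0 sessions with out-of-scope events keep their full record", {
  s <- make_test_session(events = data.frame(
    event_type = "blood_pressure_elevation", time_min = 120))
  ft <- build_feature_table(list(a = s), scheme = "group1")
  expect_equal(unname(ft$labels), 0L)
  bare <- make_test_session()
  expect_equal(ft$features[1, ], extract_features(bare))
})
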