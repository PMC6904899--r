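test_that("threshold comparisons are strict at both limits", {
  th1 <- threshold_config(1, "heart_rate", 60, 100)
  expect_identical(is_anomalous(55, th1), list(anomalous = TRUE, direction = "low"))
  expect_identical(is_anomalous(60, th1), list(anomalous = FALSE, direction = "none"))
  expect_identical(is_anomalous(100, th1), list(anomalous = FALSE, direction = "none"))
  expect_identical(is_anomalous(100.001, th1),
                   list(anomalous = TRUE, direction = "high"))
  th5 <- threshold_config(5, "heart_rate", 50, 102)
  expect_identical(is_anomalous(103, th5), list(anomalous = TRUE, direction = "high"))

  expect_error(is_anomalous(NaN, th1), "finite")
  expect_error(is_anomalous(Inf, th1), "finite")
  expect_error(is_anomalous(80, threshold_config(1, "heart_rate", 100, 60)),
               class = "quietward_config_error")
})

test_that("is_anomalous is monotone above the maximum and matches a brute re-scan", {
  th <- hr_threshold()
  set.seed(11)
  values <- c(runif(200, 40, 120), 60, 100, 59.999, 100.001)
  flags <- vapply(values, function(v) is_anomalous(v, th)$anomalous, logical(1))
  expect_identical(flags, values < 60 | values > 100)
  # raising an already-high value never flips the decision back
  high <- values[values > 100]
  expect_true(all(vapply(high + 50, function(v) is_anomalous(v, th)$anomalous,
                         logical(1))))
})

test_that("detect ignores in-range readings and errors on unconfigured pairs", {
  cfg <- hr_config()
  an <- detect(reading("p1", "heart_rate", 120, 5000), cfg)
  expect_s3_class(an, "anomaly_event")
  expect_identical(an$t_alpha, 5000L)
  expect_identical(an$direction, "high")

  expect_null(detect(reading("p1", "heart_rate", 80, 5000), cfg))
  expect_error(detect(reading("p9", "heart_rate", 80, 5000), cfg),
               class = "quietward_config_error")
})

test_that("trigger_alarm applies the configured triggering delay exactly", {
  an <- anomaly_event("p1", "heart_rate", 120, 5000, "high")
  expect_identical(trigger_alarm(an, notification_policy(300000L, 0L))$t_beta, 5000L)
  al <- trigger_alarm(an, notification_policy(300000L, 250L), alarm_id = 3L)
  expect_identical(al$t_beta, 5250L)
  expect_identical(al$alarm_id, 3L)

  # recomputing the delay from the emitted events recovers the configured one
  set.seed(21)
  for (d in sample(0:5000, 25L)) {
    t0 <- sample(0:1e6, 1L)
    a <- trigger_alarm(anomaly_event("p1", "heart_rate", 120, t0, "high"),
                       notification_policy(300000L, d))
    expect_identical(a$t_beta - a$anomaly$t_alpha, as.integer(d))
    expect_identical(a$d_beta, as.integer(d))
  }
})

test_that("every anomalous sample yields exactly one alarm", {
  anom_at <- c(5000L, 6000L, 42000L, 43000L, 44000L)
  stream <- hr_stream(anom_at, n = 60L)
  log <- run_replay(stream, hr_config())
  at <- alarm_table(log)
  expect_identical(nrow(at), length(anom_at))
  expect_identical(at$t_beta, anom_at)
  # equivalence with an independent per-reading re-scan
  th <- hr_threshold()
  brute <- sum(vapply(stream$value, function(v) is_anomalous(v, th)$anomalous,
                      logical(1)))
  expect_identical(nrow(at), brute)
})

test_that("CSV reader enforces header, finite values and per-patient time order", {
  stream <- hr_stream(c(3000L), n = 5L)
  f <- withr::local_tempfile(fileext = ".csv")
  write_readings(stream, f)
  back <- read_readings(f)
  expect_identical(back$time_ms, stream$time_ms)
  expect_identical(back$value, stream$value)

  bad_header <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,patient,sensor,value", "0,p1,heart_rate,80"), bad_header)
  expect_error(read_readings(bad_header), class = "quietward_parse_error")

  bad_value <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_ms,patient_id,sensor_type,value",
               "0,p1,heart_rate,80", "1000,p1,heart_rate,NA"), bad_value)
  expect_error(read_readings(bad_value), class = "quietward_parse_error")

  backwards <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_ms,patient_id,sensor_type,value",
               "1000,p1,heart_rate,80", "0,p1,heart_rate,80"), backwards)
  expect_error(read_readings(backwards), class = "quietward_parse_error")
})

test_that("routing-key stream format parses <patientID>.<value> pairs", {
  f <- withr::local_tempfile()
  writeLines(c("16.88", "16.120.5", "17.95"), f)
  df <- read_readings(f, format = "routing_key")
  expect_identical(df$patient_id, c("16", "16", "17"))
  expect_identical(df$value, c(88, 120.5, 95))
  # per-patient clocks start at 0 and advance by the assumed interval
  expect_identical(df$time_ms[df$patient_id == "16"], c(0L, 1000L))
  expect_identical(df$time_ms[df$patient_id == "17"], 0L)

  bad <- withr::local_tempfile()
  writeLines(c("16.88", "no-dot-here"), bad)
  expect_error(read_readings(bad, format = "routing_key"),
               class = "quietward_parse_error")
})

test_that("sub-second streams downsample to 1 Hz by first/mean/last", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(time_ms = c(0L, 10L, 990L, 1000L, 1500L),
                   patient_id = "p1", sensor_type = "heart_rate",
                   value = c(70, 80, 90, 100, 110))
  write_readings(df, f)
  expect_identical(read_readings(f, downsample = "first")$value, c(70, 100))
  expect_identical(read_readings(f, downsample = "last")$value, c(90, 110))
  expect_identical(read_readings(f, downsample = "mean")$value, c(80, 105))
  expect_identical(read_readings(f, downsample = "first")$time_ms, c(0L, 1000L))
})
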