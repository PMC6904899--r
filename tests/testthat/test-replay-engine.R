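test_that("in-range streams produce reading records only", {
  stream <- hr_stream(n = 2000L)
  log <- run_replay(stream, hr_config())
  kinds <- vapply(log$events, `[[`, character(1), "kind")
  expect_identical(sum(kinds == "reading"), 2000L)
  expect_identical(unique(kinds), "reading")
})

test_that("a single anomalous reading yields one anomaly, one alarm, one notification", {
  stream <- hr_stream(3000L, n = 10L)
  log <- run_replay(stream, hr_config())
  kinds <- vapply(log$events, `[[`, character(1), "kind")
  expect_identical(sum(kinds == "anomaly"), 1L)
  expect_identical(sum(kinds == "alarm"), 1L)
  expect_identical(sum(kinds == "notification"), 1L)
  # with zero triggering delay all three share the detection instant
  expect_identical(alarm_table(log)$t_beta, 3000L)
  expect_identical(alarm_table(log)$t_alpha, 3000L)
  expect_identical(notification_table(log)$t_mu, 3000L)
  expect_identical(delivery_table(log)$d_mu, 0L)
})

test_that("replays are deterministic and drain releases past the last reading", {
  stream <- hr_stream(c(0L, 1000L, 2000L), n = 5L)
  cfg <- hr_config(mni = 300000L)
  log1 <- run_replay(stream, cfg)
  log2 <- run_replay(stream, cfg)
  expect_identical(log1$events, log2$events)

  nt <- notification_table(log1)
  # grouped release fires at t_mu_k + MNI, well beyond the 4 s stream
  expect_identical(nt$t_mu, c(0L, 300000L))
  expect_identical(nt$n_alarms, c(1L, 2L))
})

test_that("an alarm landing exactly on a release time joins the departing buffer", {
  stream <- hr_stream(c(0L, 1000L, 300000L), n = 301L)
  log <- run_replay(stream, hr_config(mni = 300000L))
  nt <- notification_table(log)
  expect_identical(nt$t_mu, c(0L, 300000L))
  expect_identical(nt$n_alarms, c(1L, 2L))
  d <- delivery_table(log)
  expect_identical(d$d_mu[d$t_beta == 300000L], 0L)
  expect_lt(max(d$d_mu), 300000L)
  # audit agrees: strict latency bound, exact spacing, full conservation
  au <- audit_log(log)
  expect_identical(au$spacing_violations + au$missing_alarms +
                     au$duplicated_alarms + au$delay_violations, 0L)
})

test_that("flush-at-end delivers residual buffers at the last reading's time", {
  stream <- hr_stream(c(0L, 1000L, 2000L), n = 5L)
  cfg <- hr_config(mni = 300000L)
  log <- run_replay(stream, cfg, flush_at_end = TRUE)
  nt <- notification_table(log)
  expect_identical(nt$t_mu, c(0L, 4000L))
  expect_true(log$flushed)
  # conservation still holds under flushing
  expect_identical(sort(delivery_table(log)$alarm_id), alarm_table(log)$alarm_id)
})

test_that("patients interleave by time with id tie-break and independent buffers", {
  s1 <- hr_stream(c(0L, 1000L), n = 3L, patient = "p1")
  s2 <- hr_stream(c(0L, 1000L), n = 3L, patient = "p2", base = 75, spike = 130)
  cfg <- experiment_config(list(hr_threshold("p1"), hr_threshold("p2", 50, 105)),
                           notification_policy(300000L),
                           number_of_patients = 2L)
  log <- run_replay(rbind(s2, s1), cfg)  # input order must not matter
  readings0 <- Filter(function(r) r$kind == "reading" && r$time == 0L, log$events)
  expect_identical(vapply(readings0, `[[`, character(1), "patient_id"),
                   c("p1", "p2"))

  nt <- notification_table(log)
  # each patient gets its own immediate first notification and grouped release
  expect_identical(nt$t_mu[nt$patient_id == "p1"], c(0L, 300000L))
  expect_identical(nt$t_mu[nt$patient_id == "p2"], c(0L, 300000L))
  expect_identical(nt$notification_id[nt$patient_id == "p2"], c(1L, 2L))
})

test_that("event logs survive a JSONL round trip and export notification CSVs", {
  stream <- hr_stream(c(0L, 1000L, 2000L), n = 5L)
  log <- run_replay(stream, hr_config())
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_event_log(log, f)
  back <- read_event_log(f)
  expect_identical(back$events, log$events)

  csv <- withr::local_tempfile(fileext = ".csv")
  write_notifications_csv(log, csv)
  nt <- read.csv(csv)
  expect_identical(names(nt), c("notification_id", "patient_id", "event_type",
                                "t_mu", "n_alarms", "first_t_beta", "last_t_beta"))
  expect_identical(nrow(nt), 2L)
})

test_that("configuration problems abort before any processing", {
  stream <- hr_stream(1000L, n = 3L)
  bad <- experiment_config(threshold_config("p1", "heart_rate", 100, 60),
                           notification_policy(300000L))
  expect_error(run_replay(stream, bad), class = "quietward_config_error")
  other <- experiment_config(hr_threshold("p2"), notification_policy(300000L))
  expect_error(run_replay(stream, other), class = "quietward_config_error")
})

test_that("config files round-trip through YAML and JSON", {
  cfg <- hr_config(mni = 300000L, d_beta = 250L)
  for (ext in c(".yaml", ".json")) {
    f <- withr::local_tempfile(fileext = ext)
    write_config(cfg, f)
    back <- read_config(f)
    expect_identical(validate_config(back), character(0))
    expect_identical(back$policy$mni, 300000L)
    expect_identical(back$policy$d_beta_default, 250L)
    expect_identical(back$thresholds[[1L]]$v_min, 60)
  }
  incomplete <- withr::local_tempfile(fileext = ".yaml")
  writeLines("experiment:\n  number_of_wards: 1\n", incomplete)
  expect_error(read_config(incomplete), class = "quietward_config_error")
})

test_that("the millisecond oracle agrees with the engine and guards its horizon", {
  # empty stream
  empty <- hr_stream(n = 0L)
  expect_length(replay_oracle(empty, hr_config())$events, 0L)
  expect_length(run_replay(empty, hr_config())$events, 0L)

  # small mixed stream, zero and positive triggering delays
  stream <- hr_stream(c(0L, 1000L, 5000L, 9000L), n = 12L)
  for (d in c(0L, 250L)) {
    cfg <- hr_config(mni = 5000L, d_beta = d)
    expect_identical(run_replay(stream, cfg)$events,
                     replay_oracle(stream, cfg)$events)
  }

  far <- data.frame(time_ms = 2000000L, patient_id = "p1",
                    sensor_type = "heart_rate", value = 80)
  expect_error(replay_oracle(far, hr_config()), "horizon")
})

test_that("contiguous alarm runs group into 1 + ceil(span/MNI) notifications", {
  mni <- 5000L; interval <- 500L
  for (k in c(1L, 5L, 10L, 21L, 40L)) {
    stream <- hr_stream((0:(k - 1L)) * interval, n = k, interval = interval)
    cfg <- hr_config(mni = mni, v_min = 60, v_max = 100)
    log <- replay_oracle(stream, cfg)
    span <- (k - 1L) * interval
    expected <- 1L + as.integer(ceiling(span / mni))
    expect_identical(nrow(notification_table(log)), expected)
    # and the engine reproduces the oracle exactly
    expect_identical(run_replay(stream, cfg)$events, log$events)
  }
})
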