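# Shared builders: configs, deterministic streams, forged log records, and
# the randomized stream suites used by the property tests.

hr_threshold <- function(patient = "p1", v_min = 60, v_max = 100) {
  threshold_config(patient, "heart_rate", v_min, v_max)
}

hr_config <- function(patient = "p1", v_min = 60, v_max = 100,
                      mni = 300000L, d_beta = 0L) {
  experiment_config(hr_threshold(patient, v_min, v_max),
                    notification_policy(mni, d_beta))
}

# regular-grid heart-rate stream; readings at `anomalous_at` (ms) spike high
hr_stream <- function(anomalous_at = integer(0), n = NULL, interval = 1000L,
                      patient = "p1", base = 80, spike = 120) {
  if (is.null(n)) {
    n <- if (length(anomalous_at)) max(anomalous_at) %/% interval + 1L else 0L
  }
  times <- (seq_len(n) - 1L) * interval
  v <- rep(base, n)
  v[times %in% as.integer(anomalous_at)] <- spike
  data.frame(time_ms = times, patient_id = rep(patient, n),
             sensor_type = rep("heart_rate", n), value = v,
             stringsAsFactors = FALSE)
}

mk_alarm <- function(t_beta, id = 1L, patient = "p1", value = 120,
                     direction = "high", d_beta = 0L) {
  an <- anomaly_event(patient, "heart_rate", value, t_beta - d_beta, direction)
  alarm_event(id, an, t_beta)
}

# forged raw log records (shape of the engine's JSONL records) for audit tests
forge_alarm <- function(alarm_id, t_beta, patient = "p1") {
  list(kind = "alarm", time = as.integer(t_beta), alarm_id = as.integer(alarm_id),
       patient_id = patient, event_type = "heart_rate", value = 120,
       direction = "high", t_alpha = as.integer(t_beta),
       t_beta = as.integer(t_beta), d_beta = 0L)
}

forge_notification <- function(notification_id, t_mu, alarm_ids, t_betas,
                               patient = "p1") {
  list(kind = "notification", time = as.integer(t_mu),
       notification_id = as.integer(notification_id), patient_id = patient,
       event_type = "heart_rate", t_mu = as.integer(t_mu),
       n_alarms = length(alarm_ids), alarm_ids = as.integer(alarm_ids),
       t_betas = as.integer(t_betas),
       delays = as.integer(t_mu - as.integer(t_betas)))
}

# One randomized monitoring scenario: in-range Gaussian baseline punctuated
# by 0-3 non-overlapping anomalous episodes, random MNI.
random_stream_case <- function(seed, interval = 1000L,
                               n_range = c(150L, 600L),
                               mni_choices = c(30000L, 60000L, 120000L, 300000L),
                               d_beta_choices = 0L,
                               two_patients = FALSE) {
  set.seed(seed)
  n <- sample(n_range[1]:n_range[2], 1L)
  mni <- sample(mni_choices, 1L)
  d_beta <- sample(d_beta_choices, 1L)
  make_spec <- function(patient, spec_seed) {
    n_ep <- sample(0:3, 1L)
    episodes <- list()
    if (n_ep > 0L) {
      starts <- sort(sample(0:(n - 2L), n_ep))
      for (i in seq_len(n_ep)) {
        end_max <- if (i < n_ep) starts[i + 1L] - 1L else n - 1L
        dur <- sample(seq_len(max(1L, end_max - starts[i] + 1L)), 1L)
        episodes[[i]] <- episode_spec(starts[i] * interval, dur * interval,
                                      direction = sample(c("high", "low"), 1L),
                                      magnitude = 15)
      }
    }
    stream_spec(patient, baseline_mean = 80, baseline_sd = 5,
                interval = interval, n_readings = n, episodes = episodes,
                seed = spec_seed)
  }
  th1 <- hr_threshold("p1")
  specs <- list(make_spec("p1", seed + 10000L))
  thresholds <- list(th1)
  if (two_patients) {
    thresholds[[2L]] <- hr_threshold("p2", 50, 105)
    specs[[2L]] <- make_spec("p2", seed + 20000L)
  }
  cfg <- experiment_config(thresholds,
                           notification_policy(mni, d_beta),
                           number_of_patients = length(specs),
                           sensors_reading_interval = interval,
                           number_of_readings = n)
  readings <- do.call(rbind, lapply(seq_along(specs), function(i) {
    generate_stream(specs[[i]], thresholds[[i]])
  }))
  list(cfg = cfg, readings = readings, mni = mni)
}

# 200-case randomized suite shared by the spacing / latency / conservation
# property tests; computed once per test run.
property_suite <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- lapply(seq_len(200L), function(i) {
        case <- random_stream_case(1000L + i,
                                   two_patients = (i %% 10L == 0L))
        log <- run_replay(case$readings, case$cfg)
        list(log = log, mni = case$mni)
      })
    }
    cache
  }
})
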