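# Stream, config and event-log I/O.

#' Read a vital-sign stream
#'
#' The canonical format is CSV with mandatory header
#' `time_ms,patient_id,sensor_type,value`, one row per reading, times in
#' integer milliseconds, non-decreasing per patient. A convenience
#' `routing_key` format accepts one `<patientID>.<value>` pair per line (the
#' broker routing-key style used for heart-rate-only streams); such lines
#' carry no timestamps, so readings are stamped per patient at `0, interval,
#' 2*interval, ...` in order of appearance.
#'
#' Sub-second CSV data can be downsampled to 1 Hz by taking the first, mean
#' or last value of each (patient, sensor, second) bucket.
#'
#' @param path File to read.
#' @param format `"csv"` (default) or `"routing_key"`.
#' @param interval_ms Sampling interval assumed for `routing_key` streams.
#' @param downsample `"none"` (default), `"first"`, `"mean"` or `"last"`.
#' @param sensor_type Sensor name assigned to `routing_key` readings.
#' @return A data.frame with columns `time_ms` (integer), `patient_id`
#'   (character), `sensor_type` (character), `value` (numeric). Malformed
#'   input (bad header, missing/non-finite values, time going backwards for
#'   a patient) raises a parse error naming the file and line.
#' @export
read_readings <- function(path, format = c("csv", "routing_key"),
                          interval_ms = 1000L,
                          downsample = c("none", "first", "mean", "last"),
                          sensor_type = "heart_rate") {
  format <- match.arg(format)
  downsample <- match.arg(downsample)
  if (!file.exists(path)) abort_parse("stream file not found", file = path)

  if (format == "csv") {
    df <- tryCatch(
      read.csv(path, colClasses = c("numeric", "character", "character", "numeric"),
               check.names = FALSE),
      error = function(e) abort_parse(conditionMessage(e), file = path))
    expected <- c("time_ms", "patient_id", "sensor_type", "value")
    if (!identical(names(df), expected)) {
      abort_parse(sprintf("header must be exactly '%s'",
                          paste(expected, collapse = ",")), file = path, line = 1L)
    }
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    m <- regmatches(lines, regexec("^([^.[:space:]]+)\\.(.+)$", lines))
    bad <- which(vapply(m, length, integer(1)) != 3L)
    if (length(bad)) {
      abort_parse("line is not a <patientID>.<value> pair", file = path, line = bad[1L])
    }
    pid <- vapply(m, `[[`, character(1), 2L)
    val <- suppressWarnings(as.numeric(vapply(m, `[[`, character(1), 3L)))
    seq_in_patient <- stats::ave(seq_along(pid), pid, FUN = seq_along) - 1L
    df <- data.frame(time_ms = seq_in_patient * as.integer(interval_ms),
                     patient_id = pid,
                     sensor_type = sensor_type,
                     value = val,
                     stringsAsFactors = FALSE)
  }

  bad <- which(!is.finite(df$value) | !is.finite(df$time_ms))
  if (length(bad)) {
    abort_parse("missing or non-finite reading value", file = path,
                line = bad[1L] + 1L)
  }
  if (any(df$time_ms < 0) || any(df$time_ms != trunc(df$time_ms))) {
    abort_parse("time_ms must be non-negative integer milliseconds", file = path)
  }
  df$time_ms <- as.integer(df$time_ms)
  # per-patient monotonicity (per sensor)
  key <- paste(df$patient_id, df$sensor_type, sep = "\r")
  for (k in unique(key)) {
    t <- df$time_ms[key == k]
    if (is.unsorted(t)) {
      row <- which(key == k)[which(diff(t) < 0)[1L] + 1L]
      abort_parse(sprintf("time_ms decreases for patient %s",
                          df$patient_id[row]), file = path, line = row + 1L)
    }
  }

  if (downsample != "none") {
    bucket <- (df$time_ms %/% 1000L) * 1000L
    g <- split(seq_len(nrow(df)), list(key, bucket), drop = TRUE)
    pick <- lapply(g, function(idx) {
      row <- df[idx[1L], , drop = FALSE]
      row$time_ms <- bucket[idx[1L]]
      row$value <- switch(downsample,
                          first = df$value[idx[1L]],
                          last = df$value[idx[length(idx)]],
                          mean = mean(df$value[idx]))
      row
    })
    df <- do.call(rbind, pick)
    df <- df[order(df$time_ms, df$patient_id), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Write a readings data.frame as stream CSV
#'
#' @param readings Data.frame as returned by [read_readings()] or
#'   [generate_stream()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_readings <- function(readings, path) {
  write.table(readings[c("time_ms", "patient_id", "sensor_type", "value")],
              path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an experiment configuration file
#'
#' YAML (or JSON, by extension) with three sections: `experiment`
#' (ward/patient/sensor counts, `sensors_reading_interval`,
#' `number_of_readings`), `thresholds` (list of `{patient_id, sensor_type,
#' min, max}`), and `policy` (`{mni_ms, d_beta_ms}`).
#'
#' @param path Config file.
#' @return An [experiment_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("config file not found: %s", path))
  raw <- tryCatch(
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    } else {
      yaml::read_yaml(path)
    },
    error = function(e) abort_config(sprintf("cannot parse config %s: %s",
                                             path, conditionMessage(e))))
  for (sec in c("experiment", "thresholds", "policy")) {
    if (is.null(raw[[sec]])) abort_config(sprintf("config is missing section '%s'", sec))
  }
  ex <- raw$experiment
  thresholds <- lapply(raw$thresholds, function(th) {
    if (is.null(th$patient_id) || is.null(th$sensor_type) ||
        is.null(th$min) || is.null(th$max)) {
      abort_config("each threshold needs patient_id, sensor_type, min, max")
    }
    threshold_config(th$patient_id, th$sensor_type, th$min, th$max)
  })
  pol <- notification_policy(raw$policy$mni_ms %||% 300000L,
                             raw$policy$d_beta_ms %||% 0L)
  experiment_config(thresholds, pol,
                    number_of_wards = ex$number_of_wards %||% 1L,
                    number_of_patients = ex$number_of_patients %||% 1L,
                    number_of_sensors = ex$number_of_sensors %||% 1L,
                    sensors_reading_interval = ex$sensors_reading_interval %||% 1000L,
                    number_of_readings = ex$number_of_readings %||% 60000L)
}

#' Write an experiment configuration file
#'
#' @param cfg An [experiment_config()] (must use a single shared policy).
#' @param path Output path; `.json` selects JSON, anything else YAML.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "experiment_config"),
            inherits(cfg$policy, "notification_policy"))
  out <- list(
    experiment = list(number_of_wards = cfg$number_of_wards,
                      number_of_patients = cfg$number_of_patients,
                      number_of_sensors = cfg$number_of_sensors,
                      sensors_reading_interval = cfg$sensors_reading_interval,
                      number_of_readings = cfg$number_of_readings),
    thresholds = lapply(cfg$thresholds, function(th) {
      list(patient_id = th$patient_id, sensor_type = th$sensor_type,
           min = th$v_min, max = th$v_max)
    }),
    policy = list(mni_ms = cfg$policy$mni, d_beta_ms = cfg$policy$d_beta_default))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  } else {
    yaml::write_yaml(out, path)
  }
  invisible(path)
}

#' Write an event log as JSON lines
#'
#' One JSON object per record with stable key order; vector fields of
#' notification records (`alarm_ids`, `t_betas`, `delays`) are always arrays.
#'
#' @param log A `quietward_log` from [run_replay()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(log, path) {
  stopifnot(inherits(log, "quietward_log"))
  lines <- vapply(log$events, function(rec) {
    for (f in c("alarm_ids", "t_betas", "delays")) {
      if (!is.null(rec[[f]])) rec[[f]] <- I(rec[[f]])
    }
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an event log written by [write_event_log()]
#'
#' @param path JSON-lines file.
#' @return A `quietward_log` (without the originating config).
#' @export
read_event_log <- function(path) {
  if (!file.exists(path)) abort_parse("event log not found", file = path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  events <- lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                    error = function(e) abort_parse(conditionMessage(e),
                                                    file = path, line = i))
    for (f in c("time", "alarm_id", "t_alpha", "t_beta", "d_beta",
                "notification_id", "t_mu", "n_alarms", "alarm_ids",
                "t_betas", "delays")) {
      if (!is.null(rec[[f]])) rec[[f]] <- as.integer(rec[[f]])
    }
    if (!is.null(rec$value)) rec$value <- as.numeric(rec$value)
    rec
  })
  event_log(events)
}

#' Assemble an event log object from records
#'
#' Used by [read_event_log()] and by tests that forge logs; [run_replay()]
#' builds its logs internally. Records are validated for monotone
#' non-decreasing times.
#'
#' @param events List of event records (`kind` one of `"reading"`,
#'   `"anomaly"`, `"alarm"`, `"notification"`).
#' @param config Optional originating [experiment_config()].
#' @param flushed Whether residual buffers were flushed at end of stream.
#' @return An object of class `"quietward_log"`.
#' @export
event_log <- function(events, config = NULL, flushed = FALSE) {
  times <- vapply(events, function(r) as.integer(r$time), integer(1))
  if (is.unsorted(times)) stop("event log times must be non-decreasing")
  structure(list(events = events,
                 n_readings = sum(vapply(events, function(r) r$kind == "reading",
                                         logical(1))),
                 config = config,
                 flushed = flushed),
            class = "quietward_log")
}

#' Write the per-notification companion CSV
#'
#' One row per delivered notification
#' (`notification_id,patient_id,event_type,t_mu,n_alarms,first_t_beta,last_t_beta`),
#' convenient for timeline plots of triggering versus delivery times.
#'
#' @param log A `quietward_log`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_notifications_csv <- function(log, path) {
  nt <- notification_table(log)
  write.table(nt, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
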