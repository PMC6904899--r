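# Domain types: readings, thresholds, events, policies, experiment configs,
# and the anomaly lifecycle state machine.

#' Anomaly lifecycle states
#'
#' An anomaly instance moves along
#' `NO_ANOMALY -> ANOMALY_ALERTED -> (ANOMALY_ALERTED_UNDER_REASONING) ->
#' ANOMALY_NOTIFIED`. The reasoning state is entered only when the alarm is
#' buffered rather than delivered immediately.
#'
#' @format Character vector of the four state names, in lifecycle order.
#' @seealso [next_state()]
#' @export
anomaly_states <- c("NO_ANOMALY",
                    "ANOMALY_ALERTED",
                    "ANOMALY_ALERTED_UNDER_REASONING",
                    "ANOMALY_NOTIFIED")

#' Advance the anomaly lifecycle state machine
#'
#' @param current Current state, one of [anomaly_states].
#' @param event Transition label: `"anomaly_detected"`, `"alarm_buffered"` or
#'   `"alarm_notified"`.
#' @return The successor state. Pairs not on the machine raise an
#'   invalid-transition error; in particular no transition leaves
#'   `ANOMALY_NOTIFIED`, so one anomaly instance can never be re-alerted or
#'   re-notified.
#' @examples
#' next_state("NO_ANOMALY", "anomaly_detected")
#' next_state("ANOMALY_ALERTED", "alarm_buffered")
#' @export
next_state <- function(current, event) {
  current <- match.arg(current, anomaly_states)
  event <- match.arg(event, c("anomaly_detected", "alarm_buffered", "alarm_notified"))
  nxt <- switch(paste(current, event, sep = "+"),
    "NO_ANOMALY+anomaly_detected"                      = "ANOMALY_ALERTED",
    "ANOMALY_ALERTED+alarm_buffered"                   = "ANOMALY_ALERTED_UNDER_REASONING",
    "ANOMALY_ALERTED+alarm_notified"                   = "ANOMALY_NOTIFIED",
    "ANOMALY_ALERTED_UNDER_REASONING+alarm_notified"   = "ANOMALY_NOTIFIED",
    NULL)
  if (is.null(nxt)) {
    abort_state(sprintf("invalid anomaly state transition: %s + %s", current, event))
  }
  nxt
}

# time validation shared by every event constructor: non-negative integer ms
as_time_ms <- function(x, what = "time") {
  if (length(x) != 1L || !is.finite(x) || x < 0 || x != trunc(x)) {
    stop(sprintf("%s must be a single non-negative integer (milliseconds)", what))
  }
  as.integer(x)
}

#' One timestamped sensor value for one patient
#'
#' @param patient_id Patient identifier (coerced to character).
#' @param sensor_type Vital-sign name, e.g. `"heart_rate"`; non-empty.
#' @param value Sensor reading in the sensor's clinical units (beats/min for
#'   heart rate); must be finite.
#' @param time Non-negative integer milliseconds from the stream epoch.
#' @return An object of class `"reading"`.
#' @export
reading <- function(patient_id, sensor_type, value, time) {
  if (!nzchar(sensor_type)) stop("sensor_type must be non-empty")
  if (!is.finite(value)) stop("reading value must be finite")
  structure(list(patient_id = as.character(patient_id),
                 sensor_type = as.character(sensor_type),
                 value = as.numeric(value),
                 time = as_time_ms(time)),
            class = "reading")
}

#' Per-(patient, sensor) normal limits
#'
#' A reading is anomalous when strictly below `v_min` or strictly above
#' `v_max`; values equal to either limit are normal. Inverted bounds are
#' representable (so that [validate_config()] can report them) but rejected
#' by [is_anomalous()].
#'
#' @param patient_id Patient identifier.
#' @param sensor_type Sensor name.
#' @param v_min,v_max Lower / upper normal limits, same units as the readings.
#' @return An object of class `"threshold_config"`.
#' @export
threshold_config <- function(patient_id, sensor_type, v_min, v_max) {
  structure(list(patient_id = as.character(patient_id),
                 sensor_type = as.character(sensor_type),
                 v_min = as.numeric(v_min),
                 v_max = as.numeric(v_max)),
            class = "threshold_config")
}

#' Anomaly-detected event (alpha)
#'
#' @param patient_id,sensor_type Stream key.
#' @param value The anomalous reading.
#' @param t_alpha Detection time, integer ms.
#' @param direction `"low"` or `"high"`: which limit the value crossed.
#' @return An object of class `"anomaly_event"`.
#' @export
anomaly_event <- function(patient_id, sensor_type, value, t_alpha,
                          direction = c("low", "high")) {
  direction <- match.arg(direction)
  structure(list(event_type = "anomaly_detected",
                 patient_id = as.character(patient_id),
                 sensor_type = as.character(sensor_type),
                 value = as.numeric(value),
                 direction = direction,
                 t_alpha = as_time_ms(t_alpha, "t_alpha")),
            class = "anomaly_event")
}

#' Alarm-triggering event (beta)
#'
#' Wraps the anomaly it indicates. The alarm type is the sensor parameter
#' (e.g. `"heart_rate"`); the crossing direction is kept as metadata on the
#' anomaly, so low and high alarms of one parameter share a notification
#' stream.
#'
#' @param alarm_id Unique integer identifier.
#' @param anomaly The causing [anomaly_event()].
#' @param t_beta Triggering time, integer ms; must be `>= anomaly$t_alpha`.
#' @return An object of class `"alarm_event"` with `d_beta = t_beta - t_alpha`.
#' @export
alarm_event <- function(alarm_id, anomaly, t_beta) {
  stopifnot(inherits(anomaly, "anomaly_event"))
  t_beta <- as_time_ms(t_beta, "t_beta")
  if (t_beta < anomaly$t_alpha) stop("t_beta must be >= t_alpha of the causing anomaly")
  structure(list(alarm_id = as.integer(alarm_id),
                 event_type = anomaly$sensor_type,
                 patient_id = anomaly$patient_id,
                 anomaly = anomaly,
                 t_beta = t_beta,
                 d_beta = t_beta - anomaly$t_alpha),
            class = "alarm_event")
}

#' Notification event (mu)
#'
#' A delivered message carrying one alarm or a grouped set of same-type,
#' same-patient alarms. The per-alarm notification delay is
#' `d_mu[i] = t_mu - t_beta[i]`.
#'
#' @param notification_id Sequential integer per (patient, type).
#' @param t_mu Delivery time, integer ms.
#' @param alarms Non-empty list of [alarm_event()]s sharing patient and type,
#'   in triggering order; `t_mu` must be `>=` every `t_beta`.
#' @return An object of class `"notification_event"`.
#' @export
notification_event <- function(notification_id, t_mu, alarms) {
  if (length(alarms) == 0L) stop("a notification must carry at least one alarm")
  t_mu <- as_time_ms(t_mu, "t_mu")
  pid <- alarms[[1L]]$patient_id
  typ <- alarms[[1L]]$event_type
  t_betas <- vapply(alarms, function(a) {
    if (!identical(a$patient_id, pid) || !identical(a$event_type, typ)) {
      stop("all alarms in one notification must share patient_id and event_type")
    }
    a$t_beta
  }, integer(1))
  if (any(t_mu < t_betas)) stop("t_mu must be >= every contained t_beta")
  structure(list(notification_id = as.integer(notification_id),
                 event_type = typ,
                 patient_id = pid,
                 t_mu = t_mu,
                 data = alarms,
                 per_alarm_delay = as.integer(t_mu - t_betas)),
            class = "notification_event")
}

#' Notification delivery policy
#'
#' @param mni_ms Minimum Notification Interval in ms: the smallest allowed
#'   gap between two delivered notifications of the same type for the same
#'   patient. Must be positive to pass [validate_config()] (a zero MNI would
#'   leave no admissible buffering period). Default 300,000 ms (5 min).
#' @param d_beta_ms Alarm-triggering delay in ms added between anomaly
#'   detection and alarm triggering; default 0 (alarm fires at detection
#'   time).
#' @return An object of class `"notification_policy"`.
#' @export
notification_policy <- function(mni_ms = 300000L, d_beta_ms = 0L) {
  mni_ms <- as_time_ms(mni_ms, "mni_ms")
  d_beta_ms <- as_time_ms(d_beta_ms, "d_beta_ms")
  structure(list(mni = mni_ms, d_beta_default = d_beta_ms),
            class = "notification_policy")
}

#' Experiment configuration
#'
#' Scaffold of a monitoring scenario: ward/patient/sensor counts, the
#' sampling interval and stream length, one [threshold_config()] per
#' (patient, sensor), and the notification policy (one shared policy, or a
#' named list of per-patient policies keyed by patient id).
#'
#' @param thresholds A list of [threshold_config()] objects or a data.frame
#'   with columns `patient_id`, `sensor_type`, `v_min`, `v_max`.
#' @param policy A [notification_policy()], or a named list of them keyed by
#'   patient id.
#' @param number_of_wards,number_of_patients,number_of_sensors Positive counts.
#' @param sensors_reading_interval Sampling interval in ms.
#' @param number_of_readings Stream length per sensor.
#' @return An object of class `"experiment_config"`.
#' @export
experiment_config <- function(thresholds, policy,
                              number_of_wards = 1L,
                              number_of_patients = 1L,
                              number_of_sensors = 1L,
                              sensors_reading_interval = 1000L,
                              number_of_readings = 60000L) {
  if (inherits(thresholds, "threshold_config")) thresholds <- list(thresholds)
  if (is.data.frame(thresholds)) {
    thresholds <- lapply(seq_len(nrow(thresholds)), function(i) {
      threshold_config(thresholds$patient_id[i], thresholds$sensor_type[i],
                       thresholds$v_min[i], thresholds$v_max[i])
    })
  }
  structure(list(number_of_wards = as.integer(number_of_wards),
                 number_of_patients = as.integer(number_of_patients),
                 number_of_sensors = as.integer(number_of_sensors),
                 sensors_reading_interval = as.integer(sensors_reading_interval),
                 number_of_readings = as.integer(number_of_readings),
                 thresholds = thresholds,
                 policy = policy),
            class = "experiment_config")
}

# Resolve the policy for a patient (shared policy or per-patient list).
get_policy <- function(cfg, patient_id) {
  pol <- cfg$policy
  if (inherits(pol, "notification_policy")) return(pol)
  pol[[as.character(patient_id)]]
}

# Threshold lookup; NULL when the (patient, sensor) pair is unconfigured.
lookup_threshold <- function(cfg, patient_id, sensor_type) {
  patient_id <- as.character(patient_id)
  for (th in cfg$thresholds) {
    if (th$patient_id == patient_id && th$sensor_type == sensor_type) return(th)
  }
  NULL
}

#' Validate an experiment configuration
#'
#' Checks every threshold for `v_min < v_max`, every policy for a positive
#' MNI, uniqueness of (patient, sensor) threshold pairs, and that every
#' patient with a threshold has a resolvable policy. Violations are returned,
#' not raised.
#'
#' @param cfg An [experiment_config()].
#' @return Character vector of human-readable violations; empty when valid.
#' @examples
#' cfg <- experiment_config(threshold_config(1, "heart_rate", 60, 100),
#'                          notification_policy(300000))
#' validate_config(cfg)  # character(0)
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  bad <- character(0)
  counts <- c(cfg$number_of_wards, cfg$number_of_patients,
              cfg$number_of_sensors, cfg$sensors_reading_interval,
              cfg$number_of_readings)
  if (any(!is.finite(counts) | counts <= 0)) {
    bad <- c(bad, "all experiment counts and the reading interval must be positive")
  }
  keys <- character(0)
  for (th in cfg$thresholds) {
    key <- paste(th$patient_id, th$sensor_type, sep = "/")
    if (key %in% keys) bad <- c(bad, sprintf("duplicate threshold for (%s)", key))
    keys <- c(keys, key)
    if (!(th$v_min < th$v_max)) {
      bad <- c(bad, sprintf("threshold for (%s): v_min (%g) must be < v_max (%g)",
                            key, th$v_min, th$v_max))
    }
    pol <- get_policy(cfg, th$patient_id)
    if (is.null(pol)) {
      bad <- c(bad, sprintf("no notification policy for patient %s", th$patient_id))
    } else if (!inherits(pol, "notification_policy") || pol$mni <= 0L) {
      bad <- c(bad, sprintf("policy for patient %s: mni must be > 0", th$patient_id))
    }
  }
  bad
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("<experiment_config> %d ward(s), %d patient(s), %d sensor(s)\n",
              x$number_of_wards, x$number_of_patients, x$number_of_sensors))
  cat(sprintf("  interval %d ms, %d readings, %d threshold(s)\n",
              x$sensors_reading_interval, x$number_of_readings,
              length(x$thresholds)))
  for (th in x$thresholds) {
    pol <- get_policy(x, th$patient_id)
    cat(sprintf("  patient %s %s in (%g, %g), MNI %s ms\n",
                th$patient_id, th$sensor_type, th$v_min, th$v_max,
                if (is.null(pol)) "<missing>" else format(pol$mni)))
  }
  invisible(x)
}
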