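# Threshold detection: classify readings and trigger alarms.

#' Classify a value against per-patient thresholds
#'
#' A value is anomalous when strictly below `v_min` or strictly above
#' `v_max`; values equal to either limit are normal.
#'
#' @param value Finite numeric sensor value.
#' @param threshold A validated [threshold_config()] (`v_min < v_max`).
#' @return List with `anomalous` (logical) and `direction` (`"low"`, `"high"`
#'   or `"none"`); `anomalous` is `TRUE` iff `direction != "none"`.
#' @examples
#' is_anomalous(55, threshold_config(1, "heart_rate", 60, 100))   # low
#' is_anomalous(60, threshold_config(1, "heart_rate", 60, 100))   # boundary: normal
#' @export
is_anomalous <- function(value, threshold) {
  if (!is.finite(value)) stop("value must be finite")
  if (!(threshold$v_min < threshold$v_max)) {
    abort_config(sprintf("threshold for (%s/%s) is not validated: v_min >= v_max",
                         threshold$patient_id, threshold$sensor_type))
  }
  direction <- if (value < threshold$v_min) "low"
               else if (value > threshold$v_max) "high"
               else "none"
  list(anomalous = direction != "none", direction = direction)
}

#' Detect an anomaly in a single reading
#'
#' Evaluates a reading against the threshold configured for its
#' (patient, sensor) pair. Non-anomalous readings are ignored (return
#' `NULL`); an anomalous reading yields an anomaly event with
#' `t_alpha = reading$time`.
#'
#' @param x A [reading()].
#' @param cfg An [experiment_config()] holding the thresholds.
#' @return An [anomaly_event()] or `NULL`. A missing threshold for the pair
#'   is a configuration error.
#' @export
detect <- function(x, cfg) {
  stopifnot(inherits(x, "reading"))
  th <- lookup_threshold(cfg, x$patient_id, x$sensor_type)
  if (is.null(th)) {
    abort_config(sprintf("no threshold configured for (%s/%s)",
                         x$patient_id, x$sensor_type))
  }
  out <- is_anomalous(x$value, th)
  if (!out$anomalous) return(NULL)
  anomaly_event(x$patient_id, x$sensor_type, x$value, x$time, out$direction)
}

#' Trigger an alarm for a detected anomaly
#'
#' The alarm fires `d_beta_ms` after detection (`t_beta = t_alpha +
#' policy$d_beta_default`); with the default zero delay the alarm is
#' simultaneous with the anomaly.
#'
#' @param anomaly An [anomaly_event()].
#' @param policy A [notification_policy()] supplying the triggering delay.
#' @param alarm_id Fresh unique integer id for the alarm.
#' @return An [alarm_event()].
#' @export
trigger_alarm <- function(anomaly, policy, alarm_id = 1L) {
  stopifnot(inherits(anomaly, "anomaly_event"),
            inherits(policy, "notification_policy"))
  alarm_event(alarm_id, anomaly, anomaly$t_alpha + policy$d_beta_default)
}
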