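# Tidy views of an event log.

filter_kind <- function(log, kind) {
  Filter(function(r) r$kind == kind, log$events)
}

#' Alarm table of an event log
#'
#' @param log A `quietward_log`.
#' @return Data.frame, one row per triggered alarm: `alarm_id`, `patient_id`,
#'   `event_type`, `value`, `direction`, `t_alpha`, `t_beta`, `d_beta`.
#' @export
alarm_table <- function(log) {
  recs <- filter_kind(log, "alarm")
  data.frame(
    alarm_id   = vapply(recs, function(r) as.integer(r$alarm_id), integer(1)),
    patient_id = vapply(recs, function(r) r$patient_id, character(1)),
    event_type = vapply(recs, function(r) r$event_type, character(1)),
    value      = vapply(recs, function(r) as.numeric(r$value), numeric(1)),
    direction  = vapply(recs, function(r) r$direction, character(1)),
    t_alpha    = vapply(recs, function(r) as.integer(r$t_alpha), integer(1)),
    t_beta     = vapply(recs, function(r) as.integer(r$t_beta), integer(1)),
    d_beta     = vapply(recs, function(r) as.integer(r$d_beta), integer(1)),
    stringsAsFactors = FALSE)
}

#' Notification table of an event log
#'
#' @param log A `quietward_log`.
#' @return Data.frame, one row per delivered notification:
#'   `notification_id`, `patient_id`, `event_type`, `t_mu`, `n_alarms`,
#'   `first_t_beta`, `last_t_beta`.
#' @export
notification_table <- function(log) {
  recs <- filter_kind(log, "notification")
  data.frame(
    notification_id = vapply(recs, function(r) as.integer(r$notification_id), integer(1)),
    patient_id   = vapply(recs, function(r) r$patient_id, character(1)),
    event_type   = vapply(recs, function(r) r$event_type, character(1)),
    t_mu         = vapply(recs, function(r) as.integer(r$t_mu), integer(1)),
    n_alarms     = vapply(recs, function(r) as.integer(r$n_alarms), integer(1)),
    first_t_beta = vapply(recs, function(r) as.integer(min(r$t_betas)), integer(1)),
    last_t_beta  = vapply(recs, function(r) as.integer(max(r$t_betas)), integer(1)),
    stringsAsFactors = FALSE)
}

#' Per-alarm delivery table of an event log
#'
#' One row for every alarm contained in every notification, with the
#' per-alarm notification delay `d_mu = t_mu - t_beta`.
#'
#' @param log A `quietward_log`.
#' @return Data.frame with `notification_id`, `patient_id`, `event_type`,
#'   `alarm_id`, `t_beta`, `t_mu`, `d_mu`.
#' @export
delivery_table <- function(log) {
  recs <- filter_kind(log, "notification")
  if (!length(recs)) {
    return(data.frame(notification_id = integer(0), patient_id = character(0),
                      event_type = character(0), alarm_id = integer(0),
                      t_beta = integer(0), t_mu = integer(0), d_mu = integer(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(recs, function(r) {
    data.frame(notification_id = as.integer(r$notification_id),
               patient_id = r$patient_id, event_type = r$event_type,
               alarm_id = as.integer(r$alarm_ids),
               t_beta = as.integer(r$t_betas),
               t_mu = as.integer(r$t_mu),
               d_mu = as.integer(r$delays),
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.quietward_log <- function(x, ...) {
  kinds <- vapply(x$events, `[[`, character(1), "kind")
  cat(sprintf("<quietward_log> %d events: %d readings, %d anomalies, %d alarms, %d notifications\n",
              length(kinds), sum(kinds == "reading"), sum(kinds == "anomaly"),
              sum(kinds == "alarm"), sum(kinds == "notification")))
  if (length(kinds)) {
    times <- vapply(x$events, function(r) as.integer(r$time), integer(1))
    cat(sprintf("  horizon: %d..%d ms%s\n", min(times), max(times),
                if (isTRUE(x$flushed)) " (residual buffers flushed at end)" else ""))
  }
  invisible(x)
}

#' Timeline plot of alarm triggering versus notification delivery
#'
#' Plots each delivered alarm at (triggering time, delivery time), in the
#' style of per-experiment delivery timelines: immediately delivered alarms
#' sit on the diagonal, buffered alarms stack horizontally at their grouped
#' notification's delivery time.
#'
#' @param x A `quietward_log`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.quietward_log <- function(x, ...) {
  d <- delivery_table(x)
  if (!nrow(d)) {
    plot(0, 0, type = "n", xlab = "alarm triggering time (s)",
         ylab = "notification time (s)", main = "no notifications")
    return(invisible(x))
  }
  grouped <- d$d_mu > 0L
  plot(d$t_beta / 1000, d$t_mu / 1000,
       col = ifelse(grouped, "#d95f02", "#1b9e77"),
       pch = ifelse(grouped, 1L, 19L),
       xlab = "alarm triggering time (s)", ylab = "notification time (s)", ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  graphics::legend("bottomright", pch = c(19L, 1L),
                   col = c("#1b9e77", "#d95f02"),
                   legend = c("delivered immediately", "grouped after delay"),
                   bty = "n")
  invisible(x)
}
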