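# The notification reasoner: per (patient, alarm-type) it decides whether to
# deliver an alarm immediately or buffer it for grouped delivery, enforcing
# the rule that consecutive same-type, same-patient notifications are spaced
# at least one Minimum Notification Interval (MNI) apart.
#
# State updates are functional: every operation returns the updated state.

#' Create an empty reasoner state for one (patient, alarm-type) key
#'
#' Holds the last notification time (absent until the first delivery), the
#' open alarm buffer (at most one per key), and the next notification id.
#'
#' @param patient_id,event_type The stream key.
#' @return An object of class `"reasoner_state"`.
#' @export
reasoner_state <- function(patient_id, event_type) {
  structure(list(patient_id = as.character(patient_id),
                 event_type = as.character(event_type),
                 t_mu_k = NULL,
                 buffer = NULL,
                 next_notification_id = 1L),
            class = "reasoner_state")
}

#' Last Notification Period
#'
#' Time elapsed between the current alarm's triggering and the last same-type
#' notification delivered for that patient: `LNP = t_beta_r - t_mu_k`. When
#' no notification has ever been delivered (`t_mu_k = NULL`), the LNP equals
#' `t_beta_r` itself — absence is explicit rather than a zero sentinel, so a
#' genuine notification at epoch 0 is not mistaken for "never notified".
#'
#' @param t_beta_r Triggering time of the current alarm, integer ms.
#' @param t_mu_k Last notification time for the key, integer ms or `NULL`.
#' @return Integer ms. `t_mu_k > t_beta_r` is a causality error.
#' @export
compute_lnp <- function(t_beta_r, t_mu_k = NULL) {
  t_beta_r <- as_time_ms(t_beta_r, "t_beta_r")
  if (is.null(t_mu_k)) return(t_beta_r)
  t_mu_k <- as_time_ms(t_mu_k, "t_mu_k")
  if (t_mu_k > t_beta_r) {
    abort_state("t_mu_k is later than t_beta_r: notifications cannot precede their alarms")
  }
  t_beta_r - t_mu_k
}

#' Decide whether to notify immediately or buffer
#'
#' Immediate delivery (`NOTIFY_NOW`) happens iff no same-type notification
#' was ever delivered for the patient, or the last one is at least one MNI
#' old (`LNP >= MNI`, inclusive boundary) — and no buffer is currently open.
#' While a buffer is open every further alarm joins it (by construction
#' `LNP < MNI` whenever a buffer is open).
#'
#' @param alarm An [alarm_event()] matching the state's key.
#' @param state A [reasoner_state()].
#' @param policy A [notification_policy()].
#' @return List with `action` (`"NOTIFY_NOW"` or `"BUFFER"`) and `lnp`.
#' @export
decide <- function(alarm, state, policy) {
  check_key(alarm, state)
  lnp <- compute_lnp(alarm$t_beta, state$t_mu_k)
  action <- if (!is.null(state$buffer)) {
    "BUFFER"
  } else if (is.null(state$t_mu_k) || lnp >= policy$mni) {
    "NOTIFY_NOW"
  } else {
    "BUFFER"
  }
  list(action = action, lnp = lnp)
}

#' Buffer an alarm for grouped delivery
#'
#' The first buffered alarm opens the buffer and fixes its release time at
#' `t_mu_k + MNI` (one MNI after the last delivered notification), which
#' makes consecutive notification times at least MNI apart by construction
#' and bounds every buffered alarm's holding time strictly below the MNI.
#' Later alarms append without moving the release time.
#'
#' @inheritParams decide
#' @return List with the updated `state` and `release_time` (integer ms when
#'   this call opened the buffer and a release must be scheduled, else
#'   `NULL`).
#' @export
buffer_alarm <- function(alarm, state, policy) {
  check_key(alarm, state)
  if (is.null(state$buffer)) {
    if (is.null(state$t_mu_k)) {
      abort_state("cannot open a buffer before any notification was delivered")
    }
    release_time <- state$t_mu_k + policy$mni
    if (release_time <= alarm$t_beta) {
      abort_state("internal scheduling contradiction: release_time <= t_beta")
    }
    state$buffer <- list(starting_time = alarm$t_beta,
                         release_time = as.integer(release_time),
                         alarms = list(alarm))
    list(state = state, release_time = state$buffer$release_time)
  } else {
    state$buffer$alarms[[length(state$buffer$alarms) + 1L]] <- alarm
    list(state = state, release_time = NULL)
  }
}

#' Release an open buffer as one grouped notification
#'
#' Wraps every buffered alarm into a single [notification_event()] delivered
#' at `now`, records `now` as the key's last notification time, clears the
#' buffer and advances the notification counter.
#'
#' @param state A [reasoner_state()] with an open buffer.
#' @param now Current time; must equal the buffer's scheduled release time
#'   unless `allow_early = TRUE` (used by end-of-stream flushing).
#' @param allow_early Permit release before the scheduled time.
#' @return List with `notification` and the updated `state`.
#' @export
release_buffer <- function(state, now, allow_early = FALSE) {
  if (is.null(state$buffer) || length(state$buffer$alarms) == 0L) {
    abort_state("release_buffer called without an open buffer")
  }
  now <- as_time_ms(now, "now")
  if (!allow_early && now != state$buffer$release_time) {
    abort_state("buffer released at a time other than its scheduled release_time")
  }
  notification <- notification_event(state$next_notification_id, now,
                                     state$buffer$alarms)
  state$t_mu_k <- now
  state$buffer <- NULL
  state$next_notification_id <- state$next_notification_id + 1L
  list(notification = notification, state = state)
}

#' Deliver a single alarm immediately
#'
#' Emits a one-alarm notification at `t_mu = t_beta` (zero notification
#' delay) and records it as the key's last notification.
#'
#' @inheritParams decide
#' @return List with `notification` and the updated `state`.
#' @export
notify_now <- function(alarm, state) {
  check_key(alarm, state)
  notification <- notification_event(state$next_notification_id, alarm$t_beta,
                                     list(alarm))
  state$t_mu_k <- alarm$t_beta
  state$next_notification_id <- state$next_notification_id + 1L
  list(notification = notification, state = state)
}

check_key <- function(alarm, state) {
  if (!identical(alarm$patient_id, state$patient_id) ||
      !identical(alarm$event_type, state$event_type)) {
    abort_state(sprintf("alarm key (%s/%s) does not match reasoner state key (%s/%s)",
                        alarm$patient_id, alarm$event_type,
                        state$patient_id, state$event_type))
  }
  invisible(TRUE)
}
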