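# Evaluation metrics: alarm/notification counts, reduction percentages, and
# invariant audits of an event log.

# Published percentage cells are floor-truncated, not rounded (4/586 -> 0.6%,
# 420/423 -> 99.2%). Computed on integer counts so the truncation boundary is
# exact.
trunc_pct <- function(num, den, digits = 1L) {
  floor(10^digits * 100 * num / den) / 10^digits
}

#' Summary of one experiment's event log
#'
#' Counts triggered alarms and delivered notifications and derives the
#' notified / reduction percentages, both floor-truncated to one decimal
#' (`pct_notified = trunc1(100 * n_notifications / n_alarms)`,
#' `pct_reduction = trunc1(100 * (n_alarms - n_notifications) / n_alarms)`).
#' With zero alarms the percentages are `NA` rather than a division error.
#' `max_delay_ms` is the largest per-alarm notification delay, and
#' `mni_violations` counts consecutive same-key notifications closer than the
#' MNI (always 0 for engine-produced logs; `NA` when no MNI is known).
#'
#' @param log A `quietward_log`.
#' @param experiment_id Optional label carried into the summary.
#' @return An object of class `"experiment_summary"`.
#' @seealso [summary_from_counts()] for summaries of printed count pairs.
#' @export
summarize_log <- function(log, experiment_id = NA) {
  stopifnot(inherits(log, "quietward_log"))
  at <- alarm_table(log)
  dt <- delivery_table(log)
  n_alarms <- nrow(at)
  n_notifications <- length(filter_kind(log, "notification"))
  mni <- NULL
  if (!is.null(log$config)) {
    pols <- if (inherits(log$config$policy, "notification_policy")) {
      list(log$config$policy)
    } else log$config$policy
    mni <- unique(vapply(pols, `[[`, integer(1), "mni"))
    mni <- if (length(mni) == 1L) mni else NULL  # per-patient MNIs: audit per key instead
  }
  viol <- if (is.null(mni)) NA_integer_ else {
    audit_log(log, mni)$spacing_violations
  }
  summary_from_counts(n_alarms, n_notifications, experiment_id = experiment_id,
                      max_delay_ms = if (nrow(dt)) max(dt$d_mu) else NA_integer_,
                      mni_violations = viol)
}

#' @export
summary.quietward_log <- function(object, ...) summarize_log(object, ...)

#' Experiment summary from printed count pairs
#'
#' Builds an [summarize_log()]-style summary directly from an
#' (alarms, notifications) count pair, e.g. when checking published result
#' tables.
#'
#' @param n_alarms,n_notifications Non-negative integer counts,
#'   `n_notifications <= n_alarms`.
#' @param experiment_id Optional label.
#' @param max_delay_ms,mni_violations Optional log-derived fields.
#' @return An object of class `"experiment_summary"`.
#' @export
summary_from_counts <- function(n_alarms, n_notifications, experiment_id = NA,
                                max_delay_ms = NA_integer_,
                                mni_violations = NA_integer_) {
  n_alarms <- as.integer(n_alarms)
  n_notifications <- as.integer(n_notifications)
  stopifnot(n_alarms >= 0L, n_notifications >= 0L, n_notifications <= n_alarms)
  if (n_alarms == 0L) {
    pn <- NA_real_; pr <- NA_real_
  } else {
    pn <- trunc_pct(n_notifications, n_alarms)
    pr <- trunc_pct(n_alarms - n_notifications, n_alarms)
  }
  structure(list(experiment_id = experiment_id,
                 n_alarms = n_alarms,
                 n_notifications = n_notifications,
                 pct_notified = pn,
                 pct_reduction = pr,
                 max_delay_ms = max_delay_ms,
                 mni_violations = mni_violations),
            class = "experiment_summary")
}

#' @export
print.experiment_summary <- function(x, ...) {
  cat(sprintf("<experiment_summary>%s\n",
              if (is.na(x$experiment_id)) "" else paste0(" experiment ", x$experiment_id)))
  cat(sprintf("  alarms: %d, notifications: %d\n", x$n_alarms, x$n_notifications))
  if (is.na(x$pct_notified)) {
    cat("  percentages: not applicable (no alarms)\n")
  } else {
    cat(sprintf("  notified: %.1f%% of alarms, reduction: %.1f%%\n",
                x$pct_notified, x$pct_reduction))
  }
  if (!is.na(x$max_delay_ms)) {
    cat(sprintf("  max notification delay: %d ms\n", x$max_delay_ms))
  }
  if (!is.na(x$mni_violations)) {
    cat(sprintf("  MNI spacing violations: %d\n", x$mni_violations))
  }
  invisible(x)
}

#' Pooled mean reduction across experiments
#'
#' Pools alarms and notifications over all summaries and truncates
#' `100 * (sum alarms - sum notifications) / sum alarms` to two decimals.
#' Pooling (rather than averaging per-experiment percentages) matches how a
#' combined reduction over several experiments is conventionally reported:
#' e.g. five experiments totalling 1928 alarms and 16 notifications give
#' 1912/1928 = 99.17%.
#'
#' @param summaries Non-empty list of [summary_from_counts()] /
#'   [summarize_log()] objects.
#' @return Pooled reduction percentage, truncated to two decimals.
#' @export
mean_reduction <- function(summaries) {
  if (inherits(summaries, "experiment_summary")) summaries <- list(summaries)
  if (length(summaries) == 0L) stop("mean_reduction needs at least one summary")
  a <- sum(vapply(summaries, `[[`, integer(1), "n_alarms"))
  b <- sum(vapply(summaries, `[[`, integer(1), "n_notifications"))
  if (a == 0L) return(NA_real_)
  trunc_pct(a - b, a, digits = 2L)
}

#' Audit an event log against the notification invariants
#'
#' A pure function of the log. Checks four safety/conservation properties:
#' consecutive same-(patient, type) notifications spaced at least one MNI
#' apart; every alarm contained in exactly one notification (none missing,
#' none duplicated); and every per-alarm delay in `[0, MNI)`. All four counts
#' are zero for any log produced by [run_replay()] without end-of-stream
#' flushing.
#'
#' @param log A `quietward_log`.
#' @param mni MNI in ms; defaults to the shared policy of the log's config.
#' @return An object of class `"quietward_audit"`: counts
#'   `spacing_violations`, `missing_alarms`, `duplicated_alarms`,
#'   `delay_violations`.
#' @export
audit_log <- function(log, mni = NULL) {
  stopifnot(inherits(log, "quietward_log"))
  if (is.null(mni)) {
    if (is.null(log$config) || !inherits(log$config$policy, "notification_policy")) {
      stop("supply `mni` when the log carries no shared policy")
    }
    mni <- log$config$policy$mni
  }
  at <- alarm_table(log)
  nt <- notification_table(log)
  dt <- delivery_table(log)

  spacing <- 0L
  if (nrow(nt)) {
    for (k in unique(paste(nt$patient_id, nt$event_type, sep = "\r"))) {
      tm <- sort(nt$t_mu[paste(nt$patient_id, nt$event_type, sep = "\r") == k])
      if (length(tm) > 1L) spacing <- spacing + sum(diff(tm) < mni)
    }
  }
  delivered <- dt$alarm_id
  missing <- sum(!(at$alarm_id %in% delivered))
  dup <- sum(duplicated(delivered)) +
    sum(!(delivered %in% at$alarm_id))  # orphan deliveries count as duplication
  delay_bad <- sum(dt$d_mu < 0L | dt$d_mu >= mni)

  structure(list(spacing_violations = as.integer(spacing),
                 missing_alarms = as.integer(missing),
                 duplicated_alarms = as.integer(dup),
                 delay_violations = as.integer(delay_bad),
                 mni = as.integer(mni)),
            class = "quietward_audit")
}

#' @export
print.quietward_audit <- function(x, ...) {
  clean <- x$spacing_violations + x$missing_alarms + x$duplicated_alarms +
    x$delay_violations == 0L
  cat(sprintf("<quietward_audit> MNI = %d ms — %s\n", x$mni,
              if (clean) "clean" else "VIOLATIONS FOUND"))
  cat(sprintf("  spacing violations:  %d\n", x$spacing_violations))
  cat(sprintf("  alarms not delivered: %d\n", x$missing_alarms))
  cat(sprintf("  duplicated alarms:    %d\n", x$duplicated_alarms))
  cat(sprintf("  delay bound breaches: %d\n", x$delay_violations))
  invisible(x)
}
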