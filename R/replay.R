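# Deterministic replay engine: advances a virtual clock over readings and
# scheduled events (buffer releases, delayed alarms), wires detection to the
# reasoner, and records an ordered event log. An in-process replacement for a
# broker-based producer/queue/consumer deployment: identical inputs always
# yield identical logs.

# ---- shared record constructors (fixed field order => stable JSONL keys) ----

rec_reading <- function(time, patient_id, sensor_type, value) {
  list(kind = "reading", time = as.integer(time), patient_id = patient_id,
       sensor_type = sensor_type, value = as.numeric(value))
}

rec_anomaly <- function(time, patient_id, sensor_type, value, direction) {
  list(kind = "anomaly", time = as.integer(time), patient_id = patient_id,
       sensor_type = sensor_type, value = as.numeric(value),
       direction = direction)
}

rec_alarm <- function(alarm_id, patient_id, event_type, value, direction,
                      t_alpha, t_beta) {
  list(kind = "alarm", time = as.integer(t_beta), alarm_id = as.integer(alarm_id),
       patient_id = patient_id, event_type = event_type,
       value = as.numeric(value), direction = direction,
       t_alpha = as.integer(t_alpha), t_beta = as.integer(t_beta),
       d_beta = as.integer(t_beta - t_alpha))
}

rec_notification <- function(notification_id, patient_id, event_type, t_mu,
                             alarm_ids, t_betas) {
  t_mu <- as.integer(t_mu)
  list(kind = "notification", time = t_mu,
       notification_id = as.integer(notification_id),
       patient_id = patient_id, event_type = event_type, t_mu = t_mu,
       n_alarms = length(alarm_ids), alarm_ids = as.integer(alarm_ids),
       t_betas = as.integer(t_betas), delays = as.integer(t_mu - t_betas))
}

# O(1)-append record accumulator: records live in a hashed environment keyed
# by sequence number (list-in-environment assignment would copy the whole
# list on every append)
new_recorder <- function(capacity = 256L) {
  env <- new.env(parent = emptyenv())
  env$store <- new.env(parent = emptyenv(), hash = TRUE, size = capacity)
  env$n <- 0L
  env
}
record <- function(rec_env, rec) {
  n <- rec_env$n + 1L
  rec_env$n <- n
  assign(as.character(n), rec, envir = rec_env$store)
}
collect_records <- function(rec_env) {
  if (rec_env$n == 0L) return(list())
  unname(mget(as.character(seq_len(rec_env$n)), envir = rec_env$store))
}

# Validate config + stream, return sorted column vectors and lookup tables.
prepare_replay <- function(readings, config) {
  if (is.character(readings)) {
    readings <- do.call(rbind, lapply(readings, read_readings))
  }
  stopifnot(is.data.frame(readings), inherits(config, "experiment_config"))
  viol <- validate_config(config)
  if (length(viol)) {
    abort_config(paste0("invalid configuration:\n  ", paste(viol, collapse = "\n  ")))
  }
  pairs <- unique(readings[c("patient_id", "sensor_type")])
  for (i in seq_len(nrow(pairs))) {
    if (is.null(lookup_threshold(config, pairs$patient_id[i], pairs$sensor_type[i]))) {
      abort_config(sprintf("no threshold configured for (%s/%s)",
                           pairs$patient_id[i], pairs$sensor_type[i]))
    }
  }
  ord <- order(readings$time_ms, as.character(readings$patient_id),
               method = "radix")
  keys <- paste(readings$patient_id, readings$sensor_type, sep = "\r")[ord]
  ukeys <- unique(keys)
  thr <- lapply(ukeys, function(k) {
    i <- match(k, keys)
    lookup_threshold(config, readings$patient_id[ord][i],
                     readings$sensor_type[ord][i])
  })
  names(thr) <- ukeys
  pol <- lapply(ukeys, function(k) get_policy(config, thr[[k]]$patient_id))
  names(pol) <- ukeys
  list(time = as.integer(readings$time_ms[ord]),
       patient_id = as.character(readings$patient_id[ord]),
       sensor_type = as.character(readings$sensor_type[ord]),
       value = as.numeric(readings$value[ord]),
       key = keys, thresholds = thr, policies = pol)
}

#' Replay a vital-sign stream through detection and reasoning
#'
#' Reads the stream in time order (patient id breaks ties), evaluates each
#' reading against its thresholds, triggers one alarm per anomalous sample,
#' and routes every alarm through the per-(patient, type) notification
#' reasoner. Scheduled events live on a virtual clock; at equal times delayed
#' alarms are processed first, then readings, then scheduled buffer releases,
#' so an alarm triggered exactly at a release time joins the departing buffer
#' and is delivered with zero delay — keeping every alarm's notification
#' delay strictly below the MNI. After the last reading all scheduled
#' releases still fire
#' (the clock drains past the end of the stream), unless `flush_at_end`
#' delivers residual buffers at the last reading's time instead.
#'
#' The run is fully deterministic: identical inputs yield identical logs.
#'
#' @param readings A readings data.frame (see [read_readings()]) or one or
#'   more stream file paths.
#' @param config An [experiment_config()]; validated before any processing.
#' @param flush_at_end Deliver residual buffers at the final event time
#'   instead of at their scheduled release times. Off by default.
#' @return A `quietward_log`: ordered records of every reading consumed,
#'   anomaly, alarm and notification.
#' @examples
#' cfg <- experiment_config(threshold_config("p1", "heart_rate", 60, 100),
#'                          notification_policy(300000))
#' stream <- data.frame(time_ms = c(0L, 1000L, 2000L), patient_id = "p1",
#'                      sensor_type = "heart_rate", value = c(80, 120, 125))
#' log <- run_replay(stream, cfg)
#' summary(log)
#' @export
run_replay <- function(readings, config, flush_at_end = FALSE) {
  s <- prepare_replay(readings, config)
  n <- length(s$time)
  rec <- new_recorder(2L * n + 64L)
  states <- new.env(parent = emptyenv())

  # pending scheduled events: parallel vectors + payload list
  p_time <- integer(0); p_kind <- integer(0); p_seq <- integer(0)
  p_payload <- list()
  pseq <- 0L
  push <- function(time, kind, payload) {
    pseq <<- pseq + 1L
    p_time <<- c(p_time, as.integer(time))
    p_kind <<- c(p_kind, kind)          # 0 = delayed alarm, 2 = buffer release
                                        # (readings rank 1: alarms before
                                        # readings before releases at a tie)
    p_seq <<- c(p_seq, pseq)
    p_payload[[length(p_payload) + 1L]] <<- payload
  }
  pop_at <- function(i) {
    out <- list(time = p_time[i], kind = p_kind[i], payload = p_payload[[i]])
    p_time <<- p_time[-i]; p_kind <<- p_kind[-i]; p_seq <<- p_seq[-i]
    p_payload[[i]] <<- NULL
    out
  }
  best_pending <- function() {
    if (!length(p_time)) return(0L)
    i <- which(p_time == min(p_time))
    if (length(i) > 1L) i <- i[p_kind[i] == min(p_kind[i])]
    if (length(i) > 1L) i <- i[which.min(p_seq[i])]
    i[1L]
  }

  get_state <- function(key, pid, typ) {
    st <- states[[key]]
    if (is.null(st)) st <- reasoner_state(pid, typ)
    st
  }

  alarm_counter <- 0L

  handle_alarm <- function(alarm, key) {
    record(rec, rec_alarm(alarm$alarm_id, alarm$patient_id, alarm$event_type,
                          alarm$anomaly$value, alarm$anomaly$direction,
                          alarm$anomaly$t_alpha, alarm$t_beta))
    st <- get_state(key, alarm$patient_id, alarm$event_type)
    pol <- s$policies[[key]]
    d <- decide(alarm, st, pol)
    lifecycle <- next_state("NO_ANOMALY", "anomaly_detected")
    if (d$action == "NOTIFY_NOW") {
      out <- notify_now(alarm, st)
      states[[key]] <- out$state
      next_state(lifecycle, "alarm_notified")
      nt <- out$notification
      record(rec, rec_notification(nt$notification_id, nt$patient_id,
                                   nt$event_type, nt$t_mu,
                                   vapply(nt$data, `[[`, integer(1), "alarm_id"),
                                   vapply(nt$data, `[[`, integer(1), "t_beta")))
    } else {
      out <- buffer_alarm(alarm, st, pol)
      states[[key]] <- out$state
      next_state(lifecycle, "alarm_buffered")
      if (!is.null(out$release_time)) push(out$release_time, 2L, key)
    }
  }

  handle_release <- function(key, now) {
    st <- states[[key]]
    out <- release_buffer(st, now)
    states[[key]] <- out$state
    nt <- out$notification
    record(rec, rec_notification(nt$notification_id, nt$patient_id,
                                 nt$event_type, nt$t_mu,
                                 vapply(nt$data, `[[`, integer(1), "alarm_id"),
                                 vapply(nt$data, `[[`, integer(1), "t_beta")))
  }

  handle_reading <- function(i) {
    record(rec, rec_reading(s$time[i], s$patient_id[i], s$sensor_type[i],
                            s$value[i]))
    out <- is_anomalous(s$value[i], s$thresholds[[s$key[i]]])
    if (!out$anomalous) return(invisible())
    record(rec, rec_anomaly(s$time[i], s$patient_id[i], s$sensor_type[i],
                            s$value[i], out$direction))
    alarm_counter <<- alarm_counter + 1L
    an <- anomaly_event(s$patient_id[i], s$sensor_type[i], s$value[i],
                        s$time[i], out$direction)
    alarm <- trigger_alarm(an, s$policies[[s$key[i]]], alarm_counter)
    if (alarm$d_beta == 0L) {
      handle_alarm(alarm, s$key[i])
    } else {
      push(alarm$t_beta, 0L, list(alarm = alarm, key = s$key[i]))
    }
  }

  dispatch_pending <- function(i) {
    ev <- pop_at(i)
    if (ev$kind == 2L) handle_release(ev$payload, ev$time)
    else handle_alarm(ev$payload$alarm, ev$payload$key)
  }

  ri <- 1L
  while (ri <= n) {
    i <- best_pending()
    # at a tied time: delayed alarms precede the reading, releases follow it
    if (i > 0L && (p_time[i] < s$time[ri] ||
                   (p_time[i] == s$time[ri] && p_kind[i] < 1L))) {
      dispatch_pending(i)
    } else {
      handle_reading(ri)
      ri <- ri + 1L
    }
  }
  if (flush_at_end) {
    last_time <- if (n > 0L) s$time[n] else 0L
    # delayed alarms still trigger at their own t_beta, then residual buffers
    # are flushed at the final clock time
    while (any(p_kind == 0L)) {
      cand <- which(p_kind == 0L)
      i <- cand[order(p_time[cand], p_seq[cand])][1L]
      last_time <- max(last_time, p_time[i])
      dispatch_pending(i)
    }
    flush_keys <- order(p_time, p_seq)
    for (key in p_payload[flush_keys]) {
      st <- states[[key]]
      out <- release_buffer(st, last_time, allow_early = TRUE)
      states[[key]] <- out$state
      nt <- out$notification
      record(rec, rec_notification(nt$notification_id, nt$patient_id,
                                   nt$event_type, nt$t_mu,
                                   vapply(nt$data, `[[`, integer(1), "alarm_id"),
                                   vapply(nt$data, `[[`, integer(1), "t_beta")))
    }
  } else {
    while ((i <- best_pending()) > 0L) dispatch_pending(i)
  }

  structure(list(events = collect_records(rec),
                 n_readings = n,
                 config = config,
                 flushed = flush_at_end),
            class = "quietward_log")
}

#' Brute-force per-millisecond reference simulator
#'
#' Steps the clock one millisecond at a time over the whole horizon,
#' re-deciding everything literally at each tick: due delayed alarms first,
#' then the readings stamped at that millisecond (patient id order), then
#' pending buffer releases. The buffering rule is re-implemented here
#' directly — immediate delivery iff no buffer is open and either no prior
#' same-type notification exists or the last one is at least MNI old,
#' otherwise queue, opening the buffer with release time `t_mu_k + MNI` —
#' independently of the reasoner module,
#' so agreement between [run_replay()] and this simulator is a genuine
#' cross-check. Intended for tests on small streams only.
#'
#' @inheritParams run_replay
#' @param horizon_guard_ms Refuse streams whose last reading is later than
#'   this (default 10^6 ms), guarding against accidental long runs.
#' @return A `quietward_log` with records identical to [run_replay()]'s.
#' @export
replay_oracle <- function(readings, config, horizon_guard_ms = 1e6) {
  s <- prepare_replay(readings, config)
  n <- length(s$time)
  if (n > 0L && max(s$time) > horizon_guard_ms) {
    stop(sprintf("replay_oracle horizon exceeds %d ms; use run_replay()",
                 as.integer(horizon_guard_ms)))
  }
  rec <- new_recorder(2L * n + 64L)

  t_mu_k <- list()      # key -> last notification time (absent = never)
  nid <- list()         # key -> next notification id
  buffers <- list()     # creation order; each: key, release_time, ids, t_betas, values...
  due <- list()         # delayed alarms: t_beta, key, fields (creation order)
  alarm_counter <- 0L

  next_nid <- function(key) {
    id <- nid[[key]] %||% 1L
    nid[[key]] <<- id + 1L
    id
  }

  oracle_alarm <- function(id, key, pid, typ, value, direction, t_alpha, t_beta) {
    record(rec, rec_alarm(id, pid, typ, value, direction, t_alpha, t_beta))
    last <- t_mu_k[[key]]
    lnp <- if (is.null(last)) t_beta else t_beta - last
    mni <- s$policies[[key]]$mni
    j <- which(vapply(buffers, function(b) b$key == key, logical(1)))
    if (length(j) == 0L && (is.null(last) || lnp >= mni)) {
      record(rec, rec_notification(next_nid(key), pid, typ, t_beta, id, t_beta))
      t_mu_k[[key]] <<- t_beta
    } else {
      if (length(j) == 0L) {
        buffers[[length(buffers) + 1L]] <<- list(
          key = key, pid = pid, typ = typ,
          release_time = last + mni,
          ids = id, t_betas = t_beta)
      } else {
        buffers[[j[1L]]]$ids <<- c(buffers[[j[1L]]]$ids, id)
        buffers[[j[1L]]]$t_betas <<- c(buffers[[j[1L]]]$t_betas, t_beta)
      }
    }
  }

  t <- 0L
  ri <- 1L
  repeat {
    if (ri > n && length(buffers) == 0L && length(due) == 0L) break
    # 1. delayed alarms due at this millisecond, in detection order
    if (length(due)) {
      hit <- which(vapply(due, function(d) d$t_beta == t, logical(1)))
      for (j in hit) {
        d <- due[[j]]
        oracle_alarm(d$id, d$key, d$pid, d$typ, d$value, d$direction,
                     d$t_alpha, d$t_beta)
      }
      if (length(hit)) due <- due[-hit]
    }
    # 2. readings stamped at this millisecond (already patient-ordered)
    while (ri <= n && s$time[ri] == t) {
      record(rec, rec_reading(t, s$patient_id[ri], s$sensor_type[ri],
                              s$value[ri]))
      th <- s$thresholds[[s$key[ri]]]
      v <- s$value[ri]
      direction <- if (v < th$v_min) "low" else if (v > th$v_max) "high" else "none"
      if (direction != "none") {
        record(rec, rec_anomaly(t, s$patient_id[ri], s$sensor_type[ri], v,
                                direction))
        alarm_counter <- alarm_counter + 1L
        d_beta <- s$policies[[s$key[ri]]]$d_beta_default
        if (d_beta == 0L) {
          oracle_alarm(alarm_counter, s$key[ri], s$patient_id[ri],
                       s$sensor_type[ri], v, direction, t, t)
        } else {
          due[[length(due) + 1L]] <- list(
            key = s$key[ri], pid = s$patient_id[ri], typ = s$sensor_type[ri],
            value = v, direction = direction, t_alpha = t,
            t_beta = t + d_beta, id = alarm_counter)
        }
      }
      ri <- ri + 1L
    }
    # 3. releases scheduled for this millisecond, in buffer creation order:
    # an alarm triggered exactly at the release time (above) has already
    # joined the buffer and leaves with zero delay
    if (length(buffers)) {
      hit <- vapply(buffers, function(b) b$release_time == t, logical(1))
      for (b in buffers[hit]) {
        record(rec, rec_notification(next_nid(b$key), b$pid, b$typ, t,
                                     b$ids, b$t_betas))
        t_mu_k[[b$key]] <- t
      }
      buffers <- buffers[!hit]
    }
    t <- t + 1L
  }

  structure(list(events = collect_records(rec),
                 n_readings = n,
                 config = config,
                 flushed = FALSE),
            class = "quietward_log")
}
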