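test_that("the last-notification period handles absence explicitly", {
  expect_identical(compute_lnp(700000, 300000), 400000L)
  expect_identical(compute_lnp(100000, NULL), 100000L)   # never notified
  expect_identical(compute_lnp(300000, 300000), 0L)      # simultaneous
  expect_error(compute_lnp(100, 200), class = "quietward_state_error")
})

test_that("decide notifies immediately only on idle keys at least one MNI quiet", {
  pol <- notification_policy(300000L)
  st <- reasoner_state("p1", "heart_rate")

  # first-ever alarm for the key
  d <- decide(mk_alarm(5000), st, pol)
  expect_identical(d$action, "NOTIFY_NOW")
  expect_identical(d$lnp, 5000L)

  st_notified <- notify_now(mk_alarm(0), st)$state
  expect_identical(decide(mk_alarm(120000, 2L), st_notified, pol)$action, "BUFFER")
  # the >= boundary is inclusive: exactly MNI after the last delivery is allowed
  expect_identical(decide(mk_alarm(300000, 2L), st_notified, pol)$action,
                   "NOTIFY_NOW")
  # an open buffer captures everything, regardless of LNP
  st_buf <- buffer_alarm(mk_alarm(10000, 2L), st_notified, pol)$state
  expect_identical(decide(mk_alarm(10001, 3L), st_buf, pol)$action, "BUFFER")

  expect_error(decide(mk_alarm(5000, patient = "p2"), st, pol),
               class = "quietward_state_error")
})

test_that("the first buffered alarm fixes the release at t_mu_k + MNI", {
  pol <- notification_policy(300000L)
  st <- notify_now(mk_alarm(0), reasoner_state("p1", "heart_rate"))$state

  out <- buffer_alarm(mk_alarm(10000, 2L), st, pol)
  expect_identical(out$release_time, 300000L)
  expect_identical(out$state$buffer$starting_time, 10000L)

  # appending a second alarm neither reschedules nor reorders
  out2 <- buffer_alarm(mk_alarm(20000, 3L), out$state, pol)
  expect_null(out2$release_time)
  expect_identical(out2$state$buffer$release_time, 300000L)
  expect_identical(vapply(out2$state$buffer$alarms, `[[`, integer(1), "alarm_id"),
                   c(2L, 3L))

  # buffering without any prior notification is a contract breach
  expect_error(buffer_alarm(mk_alarm(10000), reasoner_state("p1", "heart_rate"), pol),
               class = "quietward_state_error")
})

test_that("release wraps the buffered set into one notification and restarts the clock", {
  pol <- notification_policy(300000L)
  st <- notify_now(mk_alarm(0), reasoner_state("p1", "heart_rate"))$state
  for (i in 1:9) st <- buffer_alarm(mk_alarm(i * 10000L, i + 1L), st, pol)$state

  rel <- release_buffer(st, 300000)
  expect_identical(rel$notification$t_mu, 300000L)
  expect_length(rel$notification$data, 9L)
  expect_identical(rel$notification$notification_id, 2L)
  # earliest buffered alarm is held strictly less than one MNI
  expect_lt(max(rel$notification$per_alarm_delay), pol$mni)
  expect_null(rel$state$buffer)
  expect_identical(rel$state$t_mu_k, 300000L)

  # the next alarm after the release starts a fresh buffer one MNI later
  nxt <- buffer_alarm(mk_alarm(300001, 11L), rel$state, pol)
  expect_identical(nxt$release_time, 600000L)

  # releasing without a buffer, or off-schedule, is an error
  expect_error(release_buffer(rel$state, 600000), class = "quietward_state_error")
  st2 <- buffer_alarm(mk_alarm(310000, 12L), rel$state, pol)$state
  expect_error(release_buffer(st2, 599999), class = "quietward_state_error")
  expect_identical(release_buffer(st2, 599999, allow_early = TRUE)$notification$t_mu,
                   599999L)
})

test_that("immediate delivery carries one alarm with zero delay", {
  st <- reasoner_state("p1", "heart_rate")
  out <- notify_now(mk_alarm(0), st)
  expect_identical(out$notification$t_mu, 0L)
  expect_identical(out$notification$per_alarm_delay, 0L)
  expect_identical(out$notification$notification_id, 1L)
  expect_identical(out$state$t_mu_k, 0L)

  # an alarm exactly MNI after the last delivery goes out alone, immediately
  pol <- notification_policy(300000L)
  d <- decide(mk_alarm(300000, 2L), out$state, pol)
  expect_identical(d$action, "NOTIFY_NOW")
  out2 <- notify_now(mk_alarm(300000, 2L), out$state)
  expect_identical(out2$notification$t_mu, 300000L)
  expect_length(out2$notification$data, 1L)
  expect_identical(out2$notification$event_type, "heart_rate")
})
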