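---
title: "Rate-limited, grouped alarm notification: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rate-limited, grouped alarm notification: model, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quietward)
```

## The model and its assumptions

quietward separates *alarm generation* from *notification delivery*.
Detection is deliberately naive — a reading is anomalous iff it falls
strictly outside the per-(sensor, patient) normal range `(v_min, v_max)`,
and every anomalous sample triggers its own alarm, with no run-length
merging, filtering or artifact rejection. All intelligence lives in the
delivery layer, which enforces a single rule: at most one notification per
(patient, alarm type) key within one Minimum Notification Interval (MNI).

The assumptions this rests on:

- **Delayability.** Every alarm type routed through the reasoner can
  tolerate delivery delays up to the MNI without endangering the patient.
  The MNI is therefore a clinical parameter, set per patient from alarm
  sources and criticality — not a tuning knob. The packaged scenarios use
  5 min (300,000 ms) for heart-rate alarms.
- **Keyed independence.** Alarms of different types or patients never
  interact; each (patient, type) key has its own last-notification time and
  at most one open buffer. Low and high threshold crossings of one
  parameter share a key (the crossing direction is kept as metadata), so a
  patient oscillating around a limit still produces one notification
  stream.
- **A single logical clock.** Times are integer milliseconds from a
  stream-local epoch, so every delay identity (`D_β = T_β − T_α`,
  `D_μ = T_μ − T_β`, `LNP = T_βr − T_μk`) is exact integer arithmetic.

## The reasoning rule

For an incoming alarm at `T_βr`: deliver immediately (alone, `D_μ = 0`)
iff the key has never been notified, or `LNP ≥ MNI` (boundary inclusive),
and no buffer is open. Otherwise buffer. The first buffered alarm opens
the buffer and fixes its release time at `T_μk + MNI`; later alarms
append without rescheduling. At release, the buffered set leaves as one
grouped notification and the key's clock restarts.

Anchoring the release to the *last delivered notification* rather than to
the first buffered alarm is the load-bearing choice: it makes consecutive
same-key notification times at least MNI apart *by construction*, and
bounds every buffered alarm's holding time by `MNI − LNP_first < MNI`. A
fixed-length buffer measured from the first buffered alarm would satisfy
the holding bound but could violate the spacing rule.

A useful consequence for sanity-checking: a contiguous run of per-sample
alarms spanning `D` ms on an idle key produces exactly
`1 + ceiling(D / MNI)` notifications — one immediate, then one grouped
release per MNI window. The test suite verifies this closed form against
the brute-force simulator rather than assuming it.

## Numerical and edge-case choices

- **Strict threshold comparisons.** Values equal to a limit are normal.
  Pinned from the set-theoretic definition of the anomalous range; the
  boundary behaviour is test-pinned in both directions.
- **"Never notified" is explicit absence**, not a zero sentinel. A
  pseudocode formulation that encodes absence as `LNP == T_βr` would
  misclassify a genuine notification delivered at epoch 0; the package
  carries `T_μk = NULL` until the first delivery.
- **Tie-breaking at equal timestamps.** At one instant the engine
  processes delayed alarms, then readings, then scheduled releases. An
  alarm triggered exactly at a release time therefore joins the departing
  buffer and is delivered with zero delay. The alternative —
  release first, with the boundary alarm opening a fresh buffer at
  `LNP = 0` — forces that alarm to wait exactly one MNI, breaching the
  strict safety bound `D_μ < MNI`; we chose the ordering that keeps the
  bound strict everywhere. Grouped-notification counts in the packaged
  scenarios are identical under either rule.
- **End of stream.** Scheduled releases still fire after the last reading
  (the virtual clock drains), so every alarm is delivered and conservation
  holds. A `flush_at_end` option instead emits residual buffers at the
  final event time; it is off by default because early flushing can place
  the last notification closer than MNI to its predecessor.
- **Degenerate inputs.** Inverted thresholds, a zero MNI, or a missing
  per-patient policy are reported by `validate_config()` as a list of
  violations and abort a replay before any processing; non-finite or
  missing reading values and backwards per-patient timestamps are parse
  errors, not anomalies.
- **Percentage truncation.** Summary percentages are floor-truncated (one
  decimal per experiment, two for the pooled mean) on integer counts —
  4/586 notified is reported as 0.6%, not the rounded 0.7%. Truncation is
  the convention that reproduces every published cell of the evaluation
  this package packages as fixtures.

## The synthetic generator

No real monitoring recordings ship with the package. `generate_stream()`
emulates the structure that matters to the reasoner: a Gaussian baseline
clipped strictly inside the normal range (clip margin 1% of the threshold
span, so baseline readings never alarm) punctuated by contiguous anomalous
episodes placed at `threshold ± magnitude` with uniform jitter bounded at
`±0.4 × magnitude`, so episode readings never cross back in range. At 1 Hz
with grid-aligned episodes, the alarm count equals the episode seconds
exactly — generation is verified by running detection, not assumed.

`make_experiment_fixture(1..5)` packages five scenarios on the standard
scaffold (1 ward, 1 patient, 1 heart-rate sensor, 1000 ms interval, 60,000
readings, 5-min MNI) with per-patient normal ranges of (60, 100), (55,
100), (50, 105), (50, 100) and (50, 102) beats/min and episode layouts of
300 + 107, 423, 308, 300 + 286 and 204 s. The layouts reproduce the
published alarm and notification counts (407→4, 423→3, 308→3, 586→4,
204→2); the episode *positions* are the package's own choice, since the
source recordings' anomaly timing is unpublished. The fixtures are
count-faithful synthetic stand-ins, not waveforms: passing tests show the
reasoner's arithmetic and invariants, not fidelity to any patient's
physiology. Defaults the generator does not take from the evaluation
scaffold — baseline at the mid-range with SD 5 beats/min, episode
magnitude 15 beats/min above the limit — were chosen once as clinically
unremarkable values for an adult heart-rate stream.

What the generator deliberately does not model: heart-rate variability and
trends, sensor dropout and artifacts, multi-parameter correlation, and
sub-second sampling (a `downsample` reader option exists for 10-ms-style
recordings, taking the first, mean or last value per second; which rule a
given real deployment should use is an open question).

## Verification strategy and problem sizes

`replay_oracle()` re-implements the delivery rule by stepping the clock
one millisecond at a time with its own bookkeeping, independently of the
reasoner module, and must produce an event-for-event identical log — the
suite checks this on 100 randomized small streams (≤ 300 readings,
sub-second intervals, MNIs of 2–10 s) plus directed edge cases. The two
delivery guarantees (MNI spacing; strict latency bound with zero-delay
first alarms) and alarm conservation are audited over 200 randomized
scenarios of 150–600 readings with 0–3 episodes, MNIs from 30 s to 5 min,
and occasional two-patient interleaving; the five packaged 60,000-reading
scenarios run end-to-end. These sizes keep the whole suite around half a
minute while exercising every boundary the engine distinguishes.

## Known limitations

- The reasoner never re-examines buffered alarms: a buffered episode that
  escalates clinically still waits for its scheduled release. Escalation
  and acknowledgment semantics are out of scope.
- No false-alarm-probability labelling and no recipient selection; a
  notification goes to "the caregivers" as a unit.
- Message-broker transport (delivery guarantees, acknowledgment, retry) is
  replaced by an in-process deterministic dispatch; the routing-key input
  format (`<patientID>.<value>`) is kept only as a reader convenience.
- Threshold detection is static per patient; adaptive thresholds and
  signal-quality filtering are other layers' concerns.
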