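Package: quietward
Title: Alarm-Fatigue-Aware Notification Reasoning for Patient Monitoring
    Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Threshold-based anomaly detection, alarm triggering and
    rate-limited notification delivery for per-patient vital-sign streams.
    Implements a reasoning rule that limits caregivers to at most one
    notification per alarm type, patient and minimum notification interval
    (MNI) by buffering same-type alarms and releasing them as a single
    grouped notification, together with a deterministic replay engine over
    a virtual event clock, a millisecond-resolution reference simulator
    used as a testing oracle, a synthetic vital-sign stream generator, and
    notification-reduction metrics and invariant audits.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
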