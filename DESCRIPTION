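Package: phenoday
Title: Daily Behavioral Features and Anomaly Screening for Smartphone
    Passive Sensing
Version: 0.1.0
Authors@R:
    person("Marta", "Ferri", email = "marta.ferri@example.org",
           role = c("aut", "cre"))
Description: Server-side processing core for smartphone passive-sensing
    (digital phenotyping) studies. Reads per-sensor raw text logs
    (accelerometer, GPS, call registry, screen on/off events, per-app
    traffic), detects acquisition gaps and quantifies data integrity under
    manufacturer power-saving policies, extracts daily behavioral features
    (call aggregates, screen-use sessions, app traffic by category, GPS
    place clustering with location variance and entropy, hourly
    accelerometer activity), and ranks anomalous days with a k-nearest
    neighbor global anomaly score after a principal-component feature
    screen. Includes a synthetic single-user stream simulator with known
    ground truth (day regimes, visited places, power-saving gap structure)
    so the full pipeline is testable without real participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
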