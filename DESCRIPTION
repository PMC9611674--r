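Package: cooltwin
Title: Event-Driven Digital Twins for Cool-Chain Sensor Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale digital-twin runtime for streaming sensor analytics.
    Provides an ordered in-memory publish/subscribe topic log with JSON message
    codec, a configuration-driven wrapper framework that attaches updateable
    mathematical models to enriched event streams with life-cycle phase
    machines, sampling checks and gap filling, and a suite of cool-chain
    models for refrigerated banana transport: first-order cooling-parameter
    estimation, future box-temperature prediction, ripening-heat observation
    and Q10 green-life prediction, including what-if setpoint scenarios.
    A synthetic scenario generator and accelerated playback make the whole
    chain testable without external infrastructure or recorded voyage data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
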