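Package: nmbtender
Title: Net Monetary Benefit Scoring for Medical Device Tenders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores and ranks competing medical-device offers in a tender lot
    with a simplified three-endpoint net monetary benefit (NMB) model.
    Expected quality-adjusted survival over the analysis horizon is computed in
    quality-adjusted life days (QALDs), event disutilities are time-normalized
    to the horizon, the net QALDs are monetized at a willingness-to-pay
    threshold per QALY, and expected event costs plus the offered price are
    subtracted to give each device its NMB. Devices are ranked by decreasing
    NMB; an optional two-scale presentation maps results onto the 0-30 price /
    0-70 quality convention of public procurement. Includes readers and
    writers for lot configurations (JSON) and device offers (CSV), report
    generation, a packaged carotid-stent worked example, and a seeded
    synthetic-tender generator for property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
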