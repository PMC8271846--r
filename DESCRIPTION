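Package: armuse
Title: Posture-Gated Arm-Use Outcomes from Wrist-Worn Accelerometers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how whole-body movements inflate arm-use outcomes
    measured with wrist-worn accelerometers in stroke rehabilitation.
    Simulates longitudinal three-sensor epoch streams (paretic wrist,
    nonparetic wrist, thigh), applies waking-hour, non-wear and valid-day
    rules, computes daily arm use with the all-postures-and-movements (P&M)
    method and the sitting/standing-only method, and compares the two with
    Bland-Altman statistics, Spearman correlations against daily walking
    time, and generalized estimating equations for longitudinal contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    dplyr,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
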