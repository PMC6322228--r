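Package: nimargin
Title: Decision-Model Based Non-Inferiority Margins and Trial Sizing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sets the non-inferiority margin of de-escalation trials with a
    decision-analytic tipping-point analysis. A deterministic cohort
    state-transition model maps an assumed cumulative event rate under each
    intervention arm to lifetime life-years, quality-adjusted life-years
    (QALYs) and costs; a bracketed root finder locates the event rate in the
    de-escalated arm at which total QALYs (or net monetary benefit at a given
    willingness-to-pay) are equal across arms; the resulting margin feeds a
    standard two-proportion non-inferiority sample-size formula with a
    Monte-Carlo power check. Includes one-way uncertainty sweeps over
    procedure disutility and test-sensitivity assumptions, a worked
    colonoscopy-surveillance scenario, YAML scenario configuration and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
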