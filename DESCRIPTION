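Package: pvsignal
Title: Age-Stratified Disproportionality Signal Detection for Spontaneous
    Adverse Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for case/non-case pharmacovigilance analysis of
    individual case safety reports (ICSRs), with a focus on pediatric age
    stratification. Provides a minimal ICSR data model with JSON Lines
    readers and writers, preferred-term (PT) querying with infant / child /
    adolescent age bands, descriptive cohort summaries, and
    disproportionality statistics: the reporting odds ratio (ROR) with
    Woolf 95% confidence intervals and the Bayesian information component
    (IC) with its IC025 credibility bound, combined into the dual signal
    criterion used in spontaneous-report screening. Includes a synthetic
    spontaneous-report database generator with age-band-dependent drug
    exposure and planted drug-reaction associations of known strength, for
    calibration and parameter-recovery studies.
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
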