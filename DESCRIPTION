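Package: pvsignal
Title: Disproportionality Signal Detection for Spontaneous Adverse-Event
    Reports with the BCPNN Information Component
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Case-based disproportionality analysis for spontaneous
    adverse-drug-reaction reporting databases laid out as four linked CSV
    tables (demographics, drug exposures, adverse events, medical history),
    the layout used by the Japanese Adverse Drug Event Report (JADER)
    database. Builds deduplicated case-level 2x2 contingency tables for
    drugs and drug classes against a Standardized MedDRA Query (SMQ) event
    definition, and scores them with the Bayesian Confidence Propagation
    Neural Network (BCPNN) information component (IC), including the 95
    percent credible interval and signal/inverse-signal classification. A
    reporting-odds-ratio comparator, a calibration routine that recovers an
    unpublished contingency margin from published IC values, and a
    synthetic four-table report generator with known ground truth are
    included for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
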