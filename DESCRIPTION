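Package: pvsignal
Title: Pharmacovigilance Signal Detection and Time-to-Onset Analysis for
    Spontaneous-Report Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Case/non-case pharmacovigilance analysis of spontaneous
    adverse-event report databases in the four-table JADER layout:
    ingestion, de-duplication and exclusion of reports; construction of
    binary exposure/event/covariate analysis datasets; crude reporting
    odds ratio (ROR) signal screening with Wald confidence intervals and
    Fisher's exact tests; multivariate adjusted RORs from a logistic
    model with interaction terms fitted by maximum likelihood; and
    Weibull time-to-onset analysis with hazard-shape classification.
    Includes a synthetic-report generator with known ground truth so the
    whole pipeline is testable without access to a licensed database
    extract.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
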