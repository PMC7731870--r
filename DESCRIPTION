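Package: csqca
Title: Crisp-Set Configurational Analysis of Implementation Conditions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Crisp-set qualitative comparative analysis (QCA) and
    coincidence-analysis style tooling for small-N implementation studies:
    case tables over crisp and multivalue factors, derivation of binary
    improvement outcomes from pre/during rate pairs, enumeration of
    minimally sufficient conditions under a consistency-threshold schedule,
    truth-table construction, Quine-McCluskey Boolean minimization with
    exhaustive irredundant-cover (Petrick) enumeration, solution consistency,
    coverage and unique-coverage metrics, a two-stage data-reduction and
    model-development pipeline with dual-outcome selection criteria, a
    synthetic case-table generator with a planted Boolean ground truth for
    validation, and text/JSON reporting including solution-path partition
    summaries. Ships the 19-facility nursing-home hospitalization-reduction
    analytic dataset as a worked fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
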