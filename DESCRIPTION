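Package: codysan
Title: Rule-Based Diagnostic Support for Congenital Dyserythropoietic Anemia
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements the CoDysAn staged diagnostic algorithm for congenital
    dyserythropoietic anemia (CDA) as a testable library and command-line tool.
    Provides age- and sex-stratified hematological reference intervals, clinical
    laboratory unit canonicalization, an externalized first-match rule engine
    returning a traced CDA-type suspicion or a reasoned rejection, a seeded
    synthetic patient cohort simulator, and a sensitivity/specificity
    evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
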