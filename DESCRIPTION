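Package: inclmon
Title: Individual-Level Disability Inclusion Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for monitoring disability inclusion from individual-level
    survey microdata. Classifies disability severity from the Washington Group
    Short Set of six functioning questions and psychosocial (affect) severity
    from the Extended Set anxiety and depression items; scores survey responses
    on a configurable set of inclusion indicators into an ordered trichotomy
    (excluded, in between, included); aggregates indicators to domain-level
    inclusion categories with dual cut-off k-of-n rules; computes design base
    weights and rakes them to external population margins by iterative
    proportional fitting; compares groups with design-effect-corrected
    chi-squared tests under Bonferroni adjustment; and summarises gender gaps,
    severity patterns and domain prioritisation rankings. Includes a synthetic
    microdata generator emulating a stratified two-stage household survey so
    the full pipeline is testable without restricted survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
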