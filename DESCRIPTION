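Package: acumine
Title: Association Rule and Network Mining of Acupoint Prescriptions
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Frequency analysis, Apriori association-rule mining, co-occurrence
    matrices and co-usage network analysis for acupoint prescription data, as
    used in evidence-synthesis studies of acupuncture for chronic stable
    angina pectoris. Ships a constraint-reconstructed 27-prescription
    reference dataset whose marginal and joint counts reproduce the published
    frequency and association-rule tables, a verifier for those constraints,
    and a seeded random-transaction generator for property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
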