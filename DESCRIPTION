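Package: artcea
Title: Cost-Effectiveness Modelling of Assisted Reproduction Treatment Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Markov cohort decision model for comparing assisted reproductive
    technology (ART) treatment strategies in women of advanced maternal age
    (35-45 years): standard autologous ART, autologous ART with preimplantation
    genetic testing for aneuploidy (PGT-A), elective oocyte cryopreservation at
    a younger age ('social freezing'), and donor-oocyte ART. Computes cumulative
    live-birth rates, expected treatment costs from societal and patient
    perspectives, incremental cost-effectiveness ratios with dominance
    classification, and probabilistic sensitivity analysis with beta-distributed
    probabilities and gamma-distributed costs, including cost-effectiveness
    plane and acceptability-curve outputs. Ships the published model inputs as a
    built-in fixture, supports user-supplied YAML configurations, and includes a
    synthetic-scenario generator and exhaustive pathway-enumeration oracles for
    verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
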