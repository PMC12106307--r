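Package: gdcea
Title: Markov Cohort Cost-Effectiveness Analysis of Ambroxol Add-On Therapy
    for Gaucher Disease
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An eight-state Markov cohort model evaluating the
    cost-effectiveness of combining the pharmacological chaperone ambroxol
    with imiglucerase enzyme replacement therapy against imiglucerase
    monotherapy in neuronopathic Gaucher disease, from the Chinese healthcare
    system perspective. Provides the cohort engine (monthly cycles, half-cycle
    correction, discounting), base-case incremental cost-effectiveness ratios
    and net monetary benefit, one-way deterministic sensitivity analysis with
    tornado ordering, probabilistic sensitivity analysis with
    cost-effectiveness plane summaries and acceptability curves, a
    synthetic-parameter generator, calibration of transition hazards to
    published endpoints, and YAML/JSON model configuration with schema
    validation.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
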