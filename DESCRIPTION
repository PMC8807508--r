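Package: olapbpk
Title: Whole-Body Pharmacokinetic Modeling of Olanzapine in Pregnancy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Physiologically based pharmacokinetic (PBPK) model of the
    antipsychotic olanzapine with gestational scaling of plasma protein
    binding and drug-metabolizing enzyme activities (CYP1A2, CYP3A4,
    CYP2C8, FMO3, UGT1A4). Provides a whole-body perfusion-limited ODE
    engine with first-order oral absorption, composition-based tissue
    partitioning, non-compartmental analysis, virtual-population
    simulation, local sensitivity analysis and fold-error model
    evaluation, to ask whether maternal steady-state exposure under
    10 mg daily dosing changes enough during pregnancy to warrant dose
    adjustment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2
Config/testthat/edition: 3
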