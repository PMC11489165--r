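Package: phthalrisk
Title: Exposure Reconstruction and Risk Assessment for Di-n-Hexyl Phthalate
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for assessing human exposure to di-n-hexyl phthalate
    (DnHexP) from urinary levels of its monoester metabolite (MnHexP) and
    from consumer-product scenarios. Implements reverse dosimetry from
    urinary biomarker concentrations to daily intake, systemic exposure
    dose (SED) calculations for dermal, oral, spray-inhalation (2-Box) and
    migration-contact routes following SCCS cosmetics guidance, forward
    dosimetry back to urine concentrations, continuous-endpoint benchmark
    dose modelling with AIC-weighted model averaging and parametric
    bootstrap intervals, derivation of a tolerable daily intake by the
    WHO/IPCS approximate probabilistic approach, and risk characterisation
    (fraction of TDI, margin of safety, DEHP-equivalent potency weighting).
    Includes synthetic-data generators that emulate the statistical
    structure of child biomonitoring surveys and developmental-toxicity
    dose-response designs, so the whole chain is testable without access
    to restricted survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
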