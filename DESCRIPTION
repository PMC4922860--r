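Package: pkdclamp
Title: Gating, Permeation and Calcium Accounting for the PKD2-L1 Channel
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative toolkit for the biophysics of the PKD2-L1
    (polycystin-2 L1, TRPP) ion channel: a four-state gating model
    (closed, open, open-blocked by outward Ca2+, long-term inactivated)
    simulated deterministically and stochastically; bi-ionic
    Goldman-Hodgkin-Katz relative-permeability and Nernst calculators with
    Debye-Hueckel activity corrections; conversion of integrated tail-current
    charge to intracellular Ca2+ load with BAPTA/EGTA chelator equilibria and
    small-compartment (cilium, dendritic knob) increments; and the standard
    patch-clamp analysis operations (exponential and Hill fits, half-amplitude
    idealization, open probability, ensemble averaging, I-V extraction,
    quality-control filters). Includes a seeded synthetic-data module that
    generates solutions, voltage protocols, macroscopic and single-channel
    current traces, and dose-response tables so every analysis can be
    exercised without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    Matrix,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
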