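Package: ucicross
Title: Exact Cross Prediction and Simulation for Maize Unilateral
    Cross-Incompatibility Loci
Version: 1.0.0
Authors@R:
    person("ucicross", "developers", email = "maintainer@example.com",
           role = c("aut", "cre"))
Description: Transmission-genetics engine for gametophyte-factor type
    unilateral cross-incompatibility (UCI) loci in maize (Ga1, Ga2, Tcb1
    and transgene surrogates).  Models pollen-silk compatibility as a
    per-system rule combining a gametophytically acting male determinant
    (P) with a sporophytic, dose-dependent female determinant (F), and
    enumerates exact gamete and offspring distributions under pollen
    selection and recombination.  Ships an executable catalog of the
    classical Ga2 segregation, transmission, transgenic-validation and
    locus-pyramiding experiments, goodness-of-fit and exact multinomial
    tests with power calculations for segregation ratios, simulators for
    selection-based fine-mapping screens and marker-assisted backcross
    programs, and a seeded synthetic-data generator for every readout.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
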