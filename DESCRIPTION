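Package: endosim
Title: Stochastic Lattice Simulation of Postsynaptic AMPA Receptor
    Endosomal Trafficking
Version: 0.1.0
Authors@R:
    person("Endosim", "Developers", email = "endosim@example.org",
           role = c("aut", "cre"))
Description: A stochastic, spatially resolved model of constitutive AMPA
    receptor recycling at a single postsynapse and its disruption during
    cerebellar long-term depression (LTD). The surface membrane and the
    early endosome (EE) are 50 x 50 site lattices coupled by delayed
    endocytic and exocytic vesicle transport; Rab5 accumulates on the EE
    with an autocatalytic, state-dependent lifetime, and a soft-threshold
    switch stochastically commits the Rab5-positive (vacuolar) portion of
    the EE to late-endosomal sorting. The package provides the per-step
    trafficking kernels, a fast compiled simulation engine, stimulus
    (endocytosis-profile) construction, ensemble drivers with reproducible
    seeding, and the ensemble statistics used to quantify baseline
    stability, LTD amount, sorting occurrence and sorting-time
    variability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
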