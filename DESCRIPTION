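Package: tumordrugsim
Title: Coupled Drug Transport and Apoptosis Dynamics in a Krogh-Cylinder Tumour
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic simulator of anticancer drug transport and drug
    effect in an idealised solid tumour: a single leaky blood vessel surrounded
    by a cylindrical interstitium. Couples steady vascular (Poiseuille with
    distributed leakage) and interstitial (Darcy) flow through Starling's law,
    three-compartment doxorubicin transport (vascular, extracellular,
    intracellular) with a Kedem-Katchalsky transvascular flux, coarse-grained
    bistable or irreversible monostable apoptosis signalling, and logistic
    tumour-cell-density dynamics. Provides finite-volume discretisation with
    operator splitting, mass-balance auditing, and in-silico experiment
    drivers for pulse injections, dose fractionation and parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
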