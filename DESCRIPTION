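Package: celldose
Title: Cellular-Scale Dosimetry for Proton-Boron Fusion and Boron Neutron
    Capture Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cellular-scale dosimetry and assay analysis for boron-based
    binary radiotherapies. Implements two-body capture-reaction kinematics
    for the 10B(n,alpha)7Li reaction, a condensed-history CSDA Monte Carlo
    transport simulator for protons and alpha particles over a
    concentric-sphere MIRD cell with nanometric shell scoring, the two-step
    alpha-source procedure for proton-boron fusion dose enhancement with its
    yield formula, a thermal-neutron kerma dose-component calculator across
    10B loadings, and analysis stages for boron uptake, viability, clonogenic
    survival, proliferation, ROS kinetics and IC50 estimation, together with
    synthetic generators for every input so all stages run without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
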