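Package: angiosprout
Title: Agent-Based Simulation of Endothelial Cell Rearrangement in
    Angiogenic Sprouts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lattice-based multicellular simulator of an angiogenic vessel
    sprout in which glycolytic ATP availability modulates three effectors of
    endothelial cell rearrangement: filopodia extension, junctional cortex
    protrusion formation, and VE-cadherin-dependent intercellular adhesion.
    Couples discrete-time VEGF-VEGFR2-Dll4-Notch lateral-inhibition signalling
    with Cellular-Potts-style differential-adhesion dynamics on an unrolled
    cylindrical vessel surface. Includes quantification of tip-cell
    competition in mosaic knockdown sprouts, cell-cell overtakes, migration,
    adhesive-strength classification, salt-and-pepper pattern scoring, an
    exact Fisher test on tip counts, effector-constant calibration sweeps
    against in vitro spheroid competition data, and ready-made scenario
    definitions for Notch inhibition (DAPT), elevated VEGF, and VEGFR2
    blockade (SU5416) experiments.
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
    optparse
Config/testthat/edition: 3
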