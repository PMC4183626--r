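Package: pepaffinity
Title: Kinase-Peptide Substrate Affinity from Snapshot Ensembles with MM/GBSA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for predicting and explaining differential
    affinity between the cAMP-dependent protein kinase (PKA) and peptide
    substrates derived from Kemptide (LRRASLG). Converts steady-state kinetic
    constants (Vmax, KM) into experimental binding and catalysis free-energy
    shifts via a thermodynamic cycle; computes ensemble MM/GBSA binding free
    energies (molecular-mechanics terms, OBC generalized-Born polar solvation,
    Shrake-Rupley SASA nonpolar solvation) with full component decomposition
    under the single-trajectory protocol; analyses snapshot ensembles for
    backbone RMSD, hydrogen-bond occupancy with conditional distance
    statistics, and hydrophobic contacts; and fits the linear correlation
    model linking calculated binding shifts to experimental catalytic
    shifts, including histidine-tautomer selection by R-squared maximisation.
    A synthetic-data generator produces fully parameterised toy complexes and
    ensembles with prescribed hydrogen-bond occupancy schedules so every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
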