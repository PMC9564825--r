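Package: mtlattice
Title: Microtubule Lattice Geometry and Seam-Register Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative geometry of microtubule lattices and their inner
    proteins (MIPs). Reads and writes atomic models (PDB and mmCIF),
    generates synthetic singlet and doublet microtubule lattices with known
    ground truth, annotates protofilaments and detects the lattice seam,
    and measures longitudinal dimer spacings, interprotofilament rotation
    angles, MIP tilt angles, Shrake-Rupley buried interface areas,
    decoration periodicity, spiral handedness and copy counts. Includes a
    seam-register utility that removes pseudo-helical rotation and monomer
    shift ambiguities from cryo-EM particle orientation tables (STAR
    format).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
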