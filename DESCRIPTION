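Package: pntbiophys
Title: Biophysical Interface Analysis for Self-Associating PNT Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing protein self-association interfaces of
    SAM-family PNT domains from solution biophysics and simulation data.
    Implements combined amide chemical-shift-perturbation mapping, amide
    hydrogen-exchange protection-factor analysis with intrinsic-rate
    prediction from poly-DL-alanine reference data and censoring of too-fast
    and too-slow exchangers, surface plasmon resonance 1:1 Langmuir kinetic
    simulation and global fitting with alanine-scan delta-delta-G hot-spot
    classification, and molecular-dynamics trajectory statistics (RMSD, RMSF,
    delta-RMSF, principal components, backbone hydrogen-bond persistence).
    Synthetic-data generators emulate the corresponding instrument outputs
    for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    bio3d,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
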