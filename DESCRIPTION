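Package: epibind
Title: In Silico Antibody Epitope Mapping, Interface Dynamics and Binding Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Post-processing and analysis toolkit for in-silico characterization of
    antibody-antigen complexes. Reads predicted structure models (PDB with per-residue
    confidence in the B-factor column plus JSON pTM/PAE score files), trims low-confidence
    termini and ranks models; performs rigid-body superposition, interface epitope mapping
    and steric-clash based competition assessment between binding poses; computes
    replica-ensemble trajectory metrics (antigen-fitted RMSD with standard errors,
    per-residue center-of-mass RMSF, heavy-atom contacts and geometric hydrogen bonds);
    and simulates and globally fits surface plasmon resonance sensorgrams under bivalent
    and heterogeneous two-site binding models with equilibrium constant derivation.
    Seeded synthetic-data generators with analytically known ground truth make every
    stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    optparse
Config/testthat/edition: 3
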