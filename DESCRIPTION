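Package: phdock
Title: pH-Sensitive Monte Carlo Protein-Protein Docking with Dynamic
    Protonation States
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multi-stage Monte Carlo rigid-body protein-protein docking
    that samples side-chain protonation states of the five ionizable
    residue types (Asp, Glu, His, Tyr, Lys) on the fly at a user-supplied
    solution pH. Implements a Henderson-Hasselbalch protonation potential,
    a weighted multi-term energy (van der Waals, Lazaridis-Karplus
    solvation, hydrogen bonding, distance-dependent-dielectric Coulomb
    electrostatics, rotamer probability, pH), simulated-annealing
    side-chain packing over rotamer-by-protonation states, interface
    scoring with post-separation repacking, CAPRI docking metrics,
    docking-funnel statistics (discrimination score, N5, bootstrap), and
    a pH-scan binding-affinity analysis. Ships a deterministic synthetic
    structure generator so the full pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    glmnet,
    stats,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
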