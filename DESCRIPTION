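Package: waterpharm
Title: Water-Based Pharmacophore Models from Explicit-Solvent Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Derives structure-based pharmacophore models for a protein
    binding site purely from explicit-water molecular dynamics sampling,
    with no knowledge of active ligands. Water oxygens observed in the
    pocket are clustered into hydration sites (1 Angstrom spheres retained
    above twice bulk density); each site is scored with interaction
    enthalpy, translational and orientational entropy estimates, and
    hydrogen-bond donor/acceptor statistics; a threshold decision tree maps
    sites to pharmacophore features (acceptor, donor, hydrophobic, aromatic,
    negative, positive); models are reduced to at most eight features and
    positions polished by rigid chemical probes. A pharmacophore screening
    engine (distance-consistent correspondence search plus Kabsch
    superposition) and enrichment-factor analysis validate models against
    active/decoy libraries. Deterministic synthetic-scene generators make
    the whole pipeline testable without running molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils,
    yaml
Suggests:
    ChemmineR,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
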