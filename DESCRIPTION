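Package: aptaface
Title: Structural Analysis of Protein-RNA Aptamer Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing protein-RNA aptamer complexes from 3D
    coordinates: Shrake-Rupley solvent-accessible surface area and buried
    surface area, interface residue identification, crystal-symmetry
    interface enumeration, heavy-atom hydrogen-bond and base-stacking
    detection (including 2'-fluoro ribose acceptors and water-mediated
    bridges), Leontis-Westhof base-pair classification with stem/loop and
    flipped-out base annotation, apo/holo conformational comparison by
    matched-atom RMSD, energy-filtered neighbor-count centroid clustering
    of conformational ensembles, and batch survey statistics over sets of
    complexes. Includes deterministic synthetic-structure generators
    (ideal A-form duplexes and hairpins, toy complexes with planted
    contacts, toy crystals, planted-cluster ensembles) so that every
    analysis stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
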