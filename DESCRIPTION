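Package: septinAH
Title: Trajectory Analysis of Amphipathic-Helix Membrane Binding
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for molecular-dynamics trajectories of
    amphipathic-helix (AH) peptides on planar lipid bilayers, modelled on the
    septin Cdc12 extended AH domain. Provides helix bending-angle and
    radius-of-curvature profiles with a PCA-plane circle fit, leaflet
    assignment, periodic-Voronoi area-per-lipid maps and lipid-tail nematic
    order parameters, residue- and domain-level contact maps, salt-bridge
    occupancy and lifetime statistics, and an antiparallel/parallel peptide
    orientation classifier. A synthetic-scene generator builds ideal and
    arc-bent helices, lattice bilayers with prescribed tail-tilt
    distributions, two-peptide scenes with known inter-axis angle and contact
    counts, and telegraph on/off contact series, so every analysis stage has
    a ground-truth oracle without running molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, Biostrings, jsonlite
Suggests: testthat (>= 3.0.0), deldir, withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
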