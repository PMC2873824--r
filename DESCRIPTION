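Package: confpath
Title: Sampling-Based Planning of Protein Conformational Transition Pathways
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Traces large-scale conformational transitions between two states
    of a protein modeled at the backbone plus C-beta level. Secondary structure
    elements are treated as rigid bodies articulated by loop dihedral degrees
    of freedom, and low-energy pathways from a start to a goal conformation are
    searched with a path-directed subdivision tree (PDST) planner guided by a
    feature-vector distance over inter-element angles and distances, under a
    coarse-grained energy gate. Includes a Metropolis random-walk comparator,
    cyclic-symmetry support for ring complexes, reaction-coordinate analysis of
    pathways (least RMSD, delta-D-RMSD, inter-domain hinge angle, binned
    pseudo-free-energy profiles) and generators for synthetic articulated test
    structures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
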