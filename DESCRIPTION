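Package: geobuild
Title: Geometric Build-Up Solvers for the Molecular Distance Geometry Problem
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs 3D molecular structures from sparse sets of exact
    inter-atomic distances using geometric build-up algorithms: the general
    build-up (GB), the updated build-up (UGB) that re-initializes each
    four-atom metric base from original distances to control rounding-error
    accumulation, and the revised updated build-up (RUGB) that relaxes the
    base to three atoms plus a disambiguating atom and searches bases through
    per-atom adjacency arrays. Includes cutoff distance-graph construction
    from PDB coordinates, rigid superposition and aligned-RMSD evaluation
    (with optional reflection), a synthetic generator of protein-like chains
    and clouds with solvable cutoff graphs, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
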