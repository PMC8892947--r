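Package: ionbridge
Title: Reduced-Alphabet Protein Library Design, Selection Analysis, and
    Protein-RNA Interface Characterization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying protein-RNA recognition with reduced
    amino-acid alphabets. Designs degenerate-codon combinatorial libraries
    over a restricted residue set with exact diversity accounting, analyses
    multi-round in vitro selection read sets (abundance ranking, position
    frequency matrices, information-content logos, enrichment trajectories,
    consensus motifs), simulates and globally fits 1:1 Langmuir binding
    kinetics to surface plasmon resonance sensorgrams, and characterizes
    protein-RNA interfaces in structural ensembles: direct hydrogen bonds,
    water bridges, metal-ion bridges, volumetric occupancy grids, and
    secondary-structure-restricted backbone RMSD. A synthetic-data module
    generates library samples, selection rounds, sensorgrams, and toy
    ensembles with planted interactions at known occupancies for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
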