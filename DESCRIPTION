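Package: rnatopo
Title: Contact-Map Topology Analysis for RNA Structure Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify and manipulate the topology of RNA contact maps
    used as distance restraints in three-dimensional structure prediction.
    Extracts contact maps from PDB/mmCIF structures under the N1/N9 nitrogen
    (9.5 Angstrom) or closest-heavy-atom (10 Angstrom) contact definitions,
    scores contact dispersion with a Gaussian-kernel inverse-density score
    (the Gauss score Omega), builds clustered, random and Gaussian-optimized
    contact selections, injects false contacts at a controlled error rate,
    and evaluates selections with PPV, the Hopkins clustering-tendency
    statistic and the beneficial fraction of restrained-folding RMSD tables.
    Selected contacts export as SimRNA-style distance restraints.  Synthetic
    generators for toy RNA structures, planted-cluster contact maps and RMSD
    tables make every operation testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
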