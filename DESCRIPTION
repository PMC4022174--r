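Package: mipclass
Title: Classification of Major Intrinsic Proteins by Motif, Selectivity
    Filter and Phylogeny
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for classifying major intrinsic proteins (MIPs,
    aquaporins) into subfamilies from protein sequence alone. Detects the
    two NPA-box motifs and their variants (NPM, NPG, NGA), extracts the
    four ar/R selectivity-filter residues (H2, H5, LE1, LE2) by alignment
    to annotated reference proteins, computes pairwise maximum-likelihood
    distances under the Jones-Taylor-Thornton amino-acid substitution
    model, builds neighbour-joining trees with bootstrap clade supports,
    and combines motif, filter, C-terminal and tree evidence into
    subfamily calls, including the LIP (large intrinsic protein)
    subfamily of heterokont algae. A sequence simulator with planted,
    fully recorded truth (motifs, filter residues, true alignments,
    subfamily structure) makes every stage testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    Matrix
Config/testthat/edition: 3
RoxygenNote: 7.3.3
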