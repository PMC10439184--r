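Package: pprscope
Title: Diversity, Spectral Tuning and Expression of Proton-Pump Rhodopsins
    in Size-Fractionated Metatranscriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of microbial rhodopsin diversity and
    expression in mixed prokaryote/eukaryote marine metatranscriptomes.
    Identifies rhodopsin unigenes by pairwise homology search against a
    bundled reference panel, assigns rhodopsin family and best-hit taxonomy,
    calls the blue/green spectral-tuning residue at the canonical
    proteorhodopsin position 105, merges size-fraction expression with an
    RNA-yield-weighted formula, decomposes the rhodopsin transcript pool
    into lineage contributions per water sample, and relates community
    distance matrices to environmental factors with Mantel and partial
    Mantel permutation tests. A seeded synthetic-community generator with
    planted ground truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    vegan,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
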