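Package: salsar
Title: Structurally Aligned Local Sites of Activity for Enzyme Function Annotation
Version: 0.1.0
Authors@R: person("SALSA", "Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Compares predicted catalytic sites across related protein
    structures to confirm, reject, or re-assign putative enzyme function
    annotations. Per-residue functional-likelihood rankings (POOL-style)
    are cut at a top fraction to define a predicted site for each
    structure; predicted sites are brought into spatial correspondence by
    sequence-seeded iterative rigid-body superposition (or an imported
    multiple alignment) and laid out as a table whose rows are structures
    and whose columns are spatially aligned positions. A majority-rule
    consensus signature summarises a functional subclass, and a query
    site is scored against it with BLOSUM62, reported as a raw score and
    as a percentage of the signature's perfect self-match. Includes a
    synthetic family generator with known ground truth, packaged
    worked-example tables, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
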