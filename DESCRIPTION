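Package: mmm2
Title: Exact Detection of Protein Coevolution by Maximum Compatible Cliques
Version: 1.0.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects coevolution between two families of homologous proteins
    from their phylogenetic distance matrices. Candidate one-to-one protein
    pairings are scored by searching for the largest set of pairings whose
    ratios of paired distances (RPDs) are mutually compatible within a
    tolerance alpha; the size of that set is the coevolution (MMM) score.
    The search is exact: every edge of a compatibility graph is treated in
    turn as the minimum-RPD anchor of a candidate match and the induced
    forward-compatible subgraph is solved with an Ostergard-style
    branch-and-bound maximum-clique engine, modified to enumerate all
    maximum cliques. Includes a PHYLIP square distance-matrix reader and
    writer, a brute-force reference solver, a synthetic fixture generator
    based on random additive trees, and a command-line front end for single
    pairs and batch manifests.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
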