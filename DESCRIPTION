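Package: gtctree
Title: Time-Consistent Species Trees from Event-Labeled Gene Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decides, for a gene tree whose internal vertices are labeled as
    speciations, duplications or horizontal-transfer origins (with flagged
    transfer edges), whether a time-consistent species tree exists, and
    constructs a binary one when it does. Implements informative species
    triplet extraction, the auxiliary timing digraph with its maximal
    topological sort, good split refinements of almost binary species trees,
    the cubic-time solver for the gene tree consistency problem, and the
    reconciliation and time-map construction with independent constraint
    checkers. Includes a duplication-transfer-loss instance simulator, a
    rooted-triplet BUILD implementation and a brute-force species-tree
    enumerator for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), igraph, ape, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
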