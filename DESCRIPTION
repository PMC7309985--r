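Package: svlineage
Title: Multi-Caller Structural Variant Consensus and Phylogenetic
    Gain-Loss Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative structural-variant (SV) analysis across
    related species mapped to a common reference: per-caller quality
    filtering (Breakdancer, Delly, Pindel conventions), within-tool and
    two-tool consensus merging by reciprocal overlap, size-conditional
    cross-species merging, Dollo-parsimony gain/loss reconstruction on a
    dated phylogeny with per-branch net gain rates, permutation-based
    genomic interval enrichment, GO term enrichment with elim
    decorrelation, repeat divergence landscapes inside and outside SV
    space, and deletion concordance plus coordinate liftover through
    whole-genome alignment blocks. A synthetic-data generator simulates SV
    evolution along a tree together with noisy multi-caller call sets,
    annotations and alignments, with known ground truth for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
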