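Package: lgtaudit
Title: Auditing Composition- and Phylogeny-Based Detection of Lateral Gene Transfer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable, fully tested implementation of the standard toolbox
    for detecting lateral (horizontal) gene transfer in eukaryotic genomes, and
    of the audit that measures how much statistical power that toolbox actually
    has. Composition metrics (GC, GC3, Codon Adaptation Index, Wright's
    effective number of codons, tetranucleotide frequencies) with
    distribution-overlap and unsupervised clustering analyses; reciprocal best
    hit orthology from tabular similarity files; gene-tree/species-tree
    topology comparison (support filtering, normalized Robinson-Foulds
    distance, bipartition frequencies, supertree bootstrap, leaf-shuffle
    null); a constrained-topology likelihood/AIC test; and a parsimony
    duplication-transfer-loss reconciliation engine with a transfer-cost
    sweep. A synthetic-data generator with planted transfer events provides
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    phangorn,
    phytools,
    Biostrings,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
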