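Package: consenet
Title: Consensus Signed Co-Expression Networks and lncRNA Function Assignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds signed weighted topological overlap (wTO) gene
    co-expression networks from RNA-seq count matrices, integrates
    same-region networks from independent datasets into sign-consistent
    consensus networks, classifies links between two conditions into
    conserved, condition-specific and reversed categories, identifies core
    hub genes by k-core decomposition and gene clusters by Louvain
    modularity, performs over-representation analysis of clusters against
    functional gene sets, and assigns long non-coding RNAs (lncRNAs) to
    enriched categories by random walk with restart with leave-one-out
    validation. Ships a seeded synthetic-data generator that emulates a
    multi-dataset two-condition brain transcriptome study with planted
    modules, planted rewiring and known lncRNA category truth, so the whole
    pipeline can be exercised against a recoverable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    DESeq2,
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
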