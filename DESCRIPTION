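Package: degnet
Title: Multi-Dataset Differential-Expression Meta-Analysis and
    Network-Proximity Core-Gene Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for cross-dataset transcriptomic
    meta-analysis and weighted protein-protein interaction (PPI) network
    mining.  Expression matrices from several studies are filtered
    (absent-call and low-variance filters), quantile normalized, collapsed
    from probes to genes, and screened for outlier samples with an
    inter-sample correlation statistic (Number-SD).  Differential
    expression uses an empirical-Bayes moderated t-test with
    Benjamini-Hochberg correction; per-class DEG sets are combined by
    direction-consistent intersection across test datasets and validated
    against independent datasets.  The resulting core gene set seeds a
    network analysis: a STRING-style weighted PPI graph is reduced to its
    giant component, converted to a topological-overlap (TOM) distance,
    and every node is scored by its shortest-path proximity to the core
    genes (Dj); positive-scoring nodes form the extracted core network.
    A synthetic-data module generates multi-dataset studies and PPI edge
    lists with planted ground truth so the whole chain is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    tools
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
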