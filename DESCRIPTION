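Package: gscomod
Title: Gene-Set-Based Scoring of Disease Comorbidity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the comorbidity of a disease pair from the similarity of
    their gene-set over-representation profiles. Each disease gene list is
    profiled against a collection of functional gene sets with one-sided
    Fisher (hypergeometric) tests; the Pearson correlation of the two
    transformed p-value profiles is the comorbidity score (GS.sim).
    Benchmark measures (Jaccard index, overlap coefficient, and the
    network-separation score Sab on a protein-protein interaction graph),
    a two-component mixture-of-regressions decomposition that extracts the
    core gene sets driving a comorbid pair, a split-versus-null simulation
    study, relative-risk gold standards built from cohort diagnosis
    matrices, and rank-based AUC / logistic-regression evaluation are
    included, together with a synthetic-data generator for fixtures and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
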