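Package: gorank
Title: Ranking Gene Ontology Terms by Multi-Group Classification Power
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Functional class scoring for normalised expression data with
    predefined sample groups. Every gene feature is scored by its capacity to
    classify the groups, either by random-forest mean decrease in Gini index
    or by the one-way ANOVA F ratio. Scores are summarised over gene ontology
    terms by averaging gene ranks (or scores) across all annotated genes,
    with annotated-but-unmeasured genes penalised at the worst rank, and each
    term receives a permutation-based P-value. Includes term filtering and
    export, per-gene and per-term visualisation, a synthetic-data generator
    with planted discriminative gene sets, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    ggplot2,
    optparse,
    pheatmap,
    randomForest,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
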