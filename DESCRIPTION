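Package: netrank
Title: Network-Based Ranking of Prognostic Marker Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: PageRank-style prioritization of prognostic marker genes from
    tumor gene expression profiles. Genes are seeded with the absolute
    correlation of their expression with patient survival time and the scores
    are propagated through a gene-gene network (transcription factor-target,
    protein-protein interaction, or thresholded co-expression) with a tunable
    damping factor. Includes the standard baseline rankers (fold change,
    Student's t, Pearson/Spearman correlation, SAM, random), a three-stage
    probe filtering cascade with probe-set collapse, a balanced Monte Carlo
    cross-validation engine with nested damping-factor selection and support
    vector machine evaluation, leave-one-out backward elimination for
    immunohistochemistry marker signatures, and a synthetic-data generator
    with planted prognostic modules on scale-free networks for end-to-end
    testing without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    e1071,
    generics,
    ggplot2,
    igraph,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
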