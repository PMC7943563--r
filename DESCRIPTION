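Package: nescore
Title: Neuroendocrine Scoring and Immune Program Analysis for Small Cell
    Lung Cancer Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the neuroendocrine (NE) identity of expression profiles
    against a 50-gene two-centroid signature (NE score = half the difference
    of Pearson correlations with the NE and non-NE centroids), and
    characterizes gene programs coupled to that score: correlation screens
    with Benjamini-Hochberg adjustment, pre-ranked gene set enrichment
    analysis with a seeded gene-label permutation null, single-sample GSEA
    (ssGSEA) immune-infiltration and MHC class I scores, and sign-proportion
    chi-squared enrichment of gene categories. Includes the normalization
    steps the workflow assumes (quantile normalization, log2 transform,
    library-size normalization, z-score standardization, cluster-average
    min-max pseudobulk), deterministic arithmetic for immunohistochemistry
    H-scores, per-area T-cell densities and qPCR relative expression, and a
    seeded synthetic-data generator with planted gene programs for
    end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    limma,
    fgsea,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
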