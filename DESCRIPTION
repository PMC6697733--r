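Package: aneulmm
Title: Linear Mixed-Model Association Testing Between Gene Expression and Tumor Aneuploidy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Association testing between per-gene expression and a genome-wide
    copy-number burden phenotype (the integrated copy number alteration, ICNA,
    score) in tumor cohorts. Implements ICNA scoring from segmented copy-number
    (SEG) data, an inter-sample covariance ("expression kinship") matrix built
    from standardized expression, maximum-likelihood variance-component fitting
    with a single eigendecomposition, generalized least squares Wald tests that
    correct for tumor-purity and co-regulation confounding, pre-ranked gene set
    enrichment with permutation FDR and LOESS q-value extrapolation, a
    synthetic-data generator with known ground truth, and an end-to-end
    pipeline with a subsampling experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
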