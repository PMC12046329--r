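Package: ctclineage
Title: Lineage Phenotyping of Circulating Tumor Cell RNA-seq in Metastatic
    Prostate Cancer
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for transcriptional lineage phenotyping of circulating
    tumor cell (CTC) RNA-seq samples from patients with metastatic prostate
    cancer. Implements single-sample gene-set enrichment (ssGSEA-style
    weighted rank statistics and AUCell-style rank-AUC scores), tumor-purity
    inference with a control-anchored cosine conversion recalibration, a
    multi-criterion purity gate, non-negative least-squares immune
    deconvolution, consensus k-means clustering of scaled pathway scores
    into luminal-A-like, luminal-B-like, low-proliferation and
    neuroendocrine phenotypes, k-nearest-neighbor phenotype transfer to
    low-purity and tissue cohorts, longitudinal androgen-receptor /
    neuroendocrine trajectory slopes, single-cell immunofluorescence
    positivity calling, and survival / clinical-endpoint association.
    Ships a synthetic-data generator emulating the study design so the full
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    survival,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    class
Config/testthat/edition: 3
RoxygenNote: 7.3.3
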