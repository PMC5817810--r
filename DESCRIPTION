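Package: npcmiR
Title: miRNA-Based Molecular Subtyping and Metastasis-Risk Modelling for
    Nasopharyngeal Carcinoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Consensus-clustering discovery of miRNA expression subtypes in
    nasopharyngeal carcinoma and a Cox proportional-hazards model of
    distant-metastasis risk built from a compact miRNA signature. Implements
    subsampled hierarchical consensus clustering with gap-statistic model
    selection and silhouette-based core-sample filtering, SAM permutation
    statistics with an AUC filter for signature selection, an SVM subtype
    classifier, moderated differential expression, Kaplan-Meier/log-rank and
    Cox risk stratification, and a synthetic-cohort generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    survival,
    e1071,
    limma,
    sva,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
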