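Package: photomics
Title: Integrative Methylation-Transcriptome Analysis of the Epidermal UV Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the integrative analysis of paired (control versus
    UV-irradiated) DNA methylation and gene expression profiles from human
    epidermis. Implements paired differential statistics on M values and
    log2(TPM+1) with Benjamini-Hochberg correction, selection of
    differentially expressed and methylated genes (DEMGs), regional
    methylation aggregation and expression-methylation correlation,
    sample-wise z-score gene-set enrichment, cross-validated lasso
    prediction of the minimal erythema dose (MED) from molecular features,
    similarity network fusion with spectral clustering into molecular
    phototypes, per-pathway SVM predictivity mapping, and a fully
    parameterised synthetic paired multi-omics cohort generator with
    ground-truth bookkeeping for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
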