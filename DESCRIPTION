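Package: matrisig
Title: Matrisome Signatures from Label-Free Proteomics and Their Immune and
    Survival Correlates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, reproducible pipeline for deriving extracellular
    matrix (matrisome) protein signatures from label-free quantitative
    proteomics of tumour models and relating them to immune infiltration and
    patient survival. Reads protein-level quantification tables (generic TSV
    or MaxQuant proteinGroups dialect), annotates proteins against a matrisome
    reference (core matrisome vs matrisome-associated divisions and six
    categories), applies identification filters and a k-of-n replicate
    detection rule to build per-model and per-tumour-type matrisome profiles,
    derives exclusive and shared signatures by set algebra, performs
    normalised-intensity differential abundance testing (Student/Welch t,
    ratio thresholds) to build combined signatures, scores expression cohorts
    with single-sample gene set enrichment analysis (ssGSEA), and runs
    quartile-stratified Kaplan-Meier, log-rank and stroma-adjusted Cox
    proportional-hazards survival analysis. Seeded synthetic-data generators
    with ground-truth manifests support recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
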