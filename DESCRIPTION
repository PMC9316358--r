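Package: coralfront
Title: Frontloading and Transcriptomic Plasticity Analysis for Coral
    Chimera Multi-Omics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for comparing stress responses of chimeric
    and non-chimeric coral colonies from count-level multi-omic data:
    negative-binomial differential expression with a maternal-colony
    covariate, classification of stress-responsive genes into frontloaded
    and higher-plasticity categories, rank-based gene-ontology enrichment
    with adaptive term clustering and delta-rank comparison, quantification
    of transcriptomic plasticity by discriminant analysis of principal
    components (fit on one entity, project the other), validation of
    chimeric status from microsatellite genotypes and multiallelic MNP
    calls, microbiome alpha/beta diversity, and field survival and
    environmental-logger statistics. A synthetic-data module generates
    every input with known ground truth so all stages are testable without
    the original sequencing reads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    limma,
    stats,
    utils,
    vcfR,
    vegan,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
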