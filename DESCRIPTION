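Package: microphen
Title: Metabolic Phenotype Profiling and Cross-Cohort Biomarker Discovery
    from 16S Amplicon Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts community metabolic phenotype profiles from 16S rRNA
    amplicon sequence variant (ASV) tables using a reference collection of
    genomes with curated binary phenotype annotations. ASVs are assigned to
    reference genomes and taxonomic lineages by an interval-based top-hit
    selection rule (multi-taxonomic assignment, MTA), from which a Community
    Phenotype Index (CPI, the expected fraction of community cells carrying a
    phenotype) and a Phenotype Alpha Diversity (PAD, Faith's phylogenetic
    diversity of phenotype carriers) are derived. Random-forest classifiers of
    clinical status are trained under single-cohort, mixed and
    leave-one-dataset-out strategies, with per-iteration feature filtration and
    extraction; stable predictors are identified across classifier variants and
    their partial-dependence-plot forms are classified into sharp/smooth
    increasing/decreasing categories. A seeded synthetic-data generator
    produces reference collections, phylogenies, binary phenotype matrices and
    multi-cohort case/control ASV datasets with planted effects for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    Matrix,
    phangorn,
    pROC,
    ranger,
    stats,
    utils
Suggests:
    jsonlite,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
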