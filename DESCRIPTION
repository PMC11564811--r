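Package: shapegwas
Title: Statistical Shape Atlases and Genetic Analysis of Biventricular Heart Morphology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds statistical shape atlases of corresponded biventricular
    surface meshes (generalized Procrustes alignment followed by principal
    component analysis), derives per-subject principal-component Z-score
    phenotypes with shape-based quality control, and carries those phenotypes
    through a population-genetics workflow: variant quality control, additive
    dosage association scans with genomic-inflation diagnostics, locus and
    signal definition with conditional secondary-signal analysis,
    Haseman-Elston heritability and genetic correlation, lead-variant
    polygenic risk scores, and bidirectional two-sample Mendelian
    randomization (inverse-variance weighted, weighted median, Egger). A
    seedable synthetic-data module generates mesh populations with latent
    shape modes under genetic control, LD-structured genotype dosages,
    covariates and binary cardiometabolic outcomes, and exposure/outcome
    summary statistics, so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
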