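Package: poolnet
Title: Multi-Omics Network Analysis of Pooled Hybrid-Grass Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis toolkit for multi-omics network inference and
    phenotype integration in family-pool breeding designs. Builds
    allele-frequency genomic relationship matrices for polyploid family
    pools, corrects omics layers for population stratification, estimates
    class-specific sparse Gaussian graphical models by a fused joint
    graphical lasso with BIC penalty selection, extracts network modules
    and conserved hub features, links hub features to field phenotypes by
    bivariate REML with boundary likelihood-ratio tests, and benchmarks
    omics-assisted random-forest prediction. Includes a synthetic-data
    generator emulating connected sparse diallels of tetraploid families
    so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    igraph,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4
Config/testthat/edition: 3
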