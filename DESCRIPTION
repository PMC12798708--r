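Package: mmpscreen
Title: Pooled Barcode Screen Deconvolution and Mitochondrial Membrane
    Potential Analytics for Yeast Aging Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing pooled FACS-sorted deletion screens of
    yeast mitochondrial membrane potential (MMP) and the single-cell and
    bulk assays that accompany them. Implements paired-end barcode calling
    with quality-based consensus and k-mer cosine-similarity catalog
    assignment, sorted-bin enrichment statistics with exact binomial tests
    and Deming errors-in-variables regression, single-cell MMP-trajectory
    filtering and lifespan correlation, exponential fluorescence-decay
    correction and mitochondrial-mass adjustment, and Gaussian-mixture
    deconvolution of aged-culture size distributions for bounded estimates
    of old-cell internal potassium. Seeded synthetic-data generators
    emulate every input so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    rlang,
    Biostrings,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr
Config/testthat/edition: 3
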