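Package: structAM
Title: Association Mapping with Structure, Kinship and Epistasis Scans
    for Inbred Germplasm
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Association-mapping workflow for structured panels of inbred
    crop accessions genotyped with biallelic markers on a genetic (cM) map.
    Provides marker quality-control and recoding filters, population
    structure covariates by principal components, Loiselle relative-kinship
    estimation with negative flooring, four nested single-marker association
    models (fixed marker effects with optional structure covariates and a
    kinship random polygenic effect fitted by maximum likelihood), an
    FDR-gated all-pairs two-marker interaction scan by likelihood-ratio
    test with perfect-prediction detection and competition ranking,
    linkage-disequilibrium decay-extent estimation from a loess fit against
    a Box-Cox parametric threshold, allele-type ("synthetic") marker
    construction from haplotype calls, and a founder-mosaic germplasm
    simulator with ground-truth labels for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
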