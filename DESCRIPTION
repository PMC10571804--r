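Package: tadaDiff
Title: Targeted DamID Analysis of RNA Polymerase II Occupancy
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of targeted DamID (TaDa) RNA polymerase II occupancy
    experiments with a four-genotype Dam-only subtraction design. Converts
    per-GATC-fragment read counts into Dam-only-normalized log2 occupancy
    tracks, aggregates occupancy to gene level with a permutation false
    discovery rate, performs replicate quality control by correlation
    clustering, and calls condition-altered genes with an orthogonal (PCA)
    regression residual z-score. Includes a negative-binomial simulator of
    complete TaDa experiments (GATC fragment map, gene annotation with
    biotypes, four genotype groups with replicates and ground truth), a
    biotype composition and lncRNA enrichment report, and scalar phenotype
    metrics for larval motion range and per-nucleus histone mark ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Epigenetics, FunctionalGenomics, Sequencing, Software
RoxygenNote: 7.3.3
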