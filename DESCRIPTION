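Package: mutscape
Title: Methylation- and Replication-Timing-Aware Modelling of Somatic CpG
    Mutations in Cancer Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for the joint influence of cytosine methylation
    and DNA replication timing on somatic mutation accumulation at CpG
    dinucleotides in cancer genomes. Ingests reference genomes, whole-genome
    bisulfite sequencing methylation tracks, Repli-seq replication-timing
    tracks and somatic single-base substitution tables; builds a genome-wide
    per-CpG annotation table; classifies tumour samples into microsatellite
    stable, microsatellite unstable and POLE-exonuclease-mutant subtypes via
    96-channel trinucleotide spectra; computes binned mutation-rate versus
    methylation associations with slope comparisons and replication-timing
    stratification; fits a binary logistic model of per-CpG mutation
    probability with a quadratic methylation term and a
    methylation-by-replication-timing interaction, with nested-model selection
    by likelihood-ratio test and AIC, AUC and log-odds vertex estimation;
    enumerates truncating C-to-T candidates at TCG trinucleotides in coding
    sequences; tests mutation strand asymmetry around replication origins; and
    simulates fully synthetic cohorts with known generating parameters so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    methods,
    jsonlite,
    lmtest,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
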