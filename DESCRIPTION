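Package: dinochrom
Title: Chromosome-Scale Hi-C Analysis of Rod-Like Dinoflagellate Chromosomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing binned Hi-C contact maps of genomes with
    rod-like, permanently condensed chromosomes such as those of the
    dinoflagellate Symbiodinium microadriaticum. Implements iterative-correction
    balancing, insulation-score profiles and domain-boundary calling,
    contact-probability scaling P(s) with regime segmentation and per-domain
    curves, Hi-C-assisted karyotyping and scaffolding (clustering, misjoin
    splitting, ordering/orienting), gene-orientation block and
    convergent/divergent site detection, genomic tracks (GC, gene density,
    repeats, stranded expression) with feature-centred and telomere-centred
    profiles, observed/expected aggregate pileups with condition comparison,
    and a fully seeded synthetic-data generator that plants ground-truth
    boundaries, gene blocks, telomeric compaction and a transcription-blocked
    condition for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    Matrix,
    Biostrings,
    BiocGenerics,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
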