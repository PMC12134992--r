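Package: scaffcurate
Title: Genome Assembly Curation Toolkit for Reptilian Chromosome-Scale Assemblies
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for the curation and evaluation of chromosome-scale genome
    assemblies of species with differentiated XY sex chromosomes and
    microchromosomes, as in many squamate reptiles. Implements k-mer based
    genome-size, depth and quality-value estimation; windowed GC and read-depth
    profiling; telomere-array detection with misjoin splitting at assembly
    gaps; de novo centromeric satellite monomer discovery with higher-order
    repeat testing; coverage-based sex-chromosome, rDNA and mitochondrial
    scaffold classification with pseudoautosomal boundary detection;
    contiguity statistics (N50/L50); and full-length ORF selection with greedy
    representative clustering. A truth-labeled synthetic genome generator
    plants every feature class so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
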