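Package: mirpipe
Title: MicroRNA Discovery, Target Prediction and SNP Effect Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for microRNA analysis in species with fragmentary
    genome resources, modelled on small-RNA studies of the common carp. Discovers
    miRNA precursors by homology against known mature miRNAs and from small RNA
    sequencing reads (adapter cleaning, contaminant annotation, read-stack locus
    discovery), validates hairpins with a restricted single-hairpin folding engine
    and six published structural criteria, characterizes the catalog (genomic
    clusters, phylogenetic conservation groups, expression statistics, 2^-ddCt
    profiling), predicts targets with two seed-based predictors and their
    consensus, and evaluates SNP effects on precursor folding energy (ddG with a
    biogenesis interpretation rule) and on target gain/loss in 3'UTRs. Seeded
    synthetic-data generators with machine-readable ground truth make every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    vcfR,
    jsonlite
Config/testthat/edition: 3
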