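Package: retrozymer
Title: Discovery and RNA-Population Analysis of Plant Retrozymes
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-wide discovery and structural annotation of retrozyme
    loci (nonautonomous LTR retroelements carrying hammerhead ribozymes),
    and analysis of their RNA populations. Provides a seed-and-extend
    homology scanner, LTR pairing with target-site-duplication, PBS and
    PPT detection, a descriptor-based Type III hammerhead ribozyme finder,
    a strict zero-mismatch overlap assembler with a capped per-merge
    extension, per-read mismatch classification against the closest
    genomic copy, small-RNA length and region profiling, bisulfite
    methylation calling with sequence context, and seeded simulators of
    retrozyme genomes, error-accumulating rolling-circle RNA replication,
    sequencing reads, small-RNA libraries and bisulfite clone sets with
    full ground-truth records.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'retrozymer-package.R'
    'AllClasses.R'
    'RcppExports.R'
    'accessors.R'
    'seq-io.R'
    'hammerhead.R'
    'homology-scan.R'
    'structural-annotation.R'
    'rna-population.R'
    'tagging.R'
    'smallrna-methylation.R'
    'synthetic-data.R'
    'pipeline.R'
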