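Package: asmforensics
Title: Forensics for Long-Read Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for diagnosing why long-read genome assemblies break and
    what their residual gaps contain. Implements repeat annotation with
    hierarchy-based overlap resolution (telomere motifs, centromeric
    satellite arrays, 5S/45S rDNA units, GA/TC and GAA/TTC low-complexity
    tracts, library elements), reference-size contiguity statistics (NGx),
    k-mer based consensus quality (QV) and completeness, contig-edge
    break-cause classification, scaffold-gap classification and
    flank-anchored gap patching, read-depth-normalized rDNA copy-number
    estimation, and primary/secondary allele pileup diagnostics for
    collapsed versus coverage-biased regions. A synthetic plant-like
    genome, read and assembly simulator with planted ground truth makes
    every stage verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rcpp,
    methods,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
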