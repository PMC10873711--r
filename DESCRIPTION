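Package: hapsoma
Title: Haplotype-Resolved Somatic Mutation Detection in Clonally Propagated Diploids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects somatic mutations in highly heterozygous diploid genomes by
    mapping short reads against both assembled haplotypes at once (a "dual
    reference"), so that germline heterozygosity disappears from the pileup and
    somatic mutations surface as near-fixed alleles on a single haplotype.
    Includes a synthetic diploid genome and paired-end read simulator with full
    ground truth, a minimal k-mer seeded read mapper and pileup engine, an
    anchor-based homology map between haplotypes with 150-bp flanking-sequence
    deduplication of homologous calls, a false-positive blacklist built from
    mutation-free simulations, population-level merging with a binomial window
    filter, outgroup-polarized derived-allele frequency spectra, Jukes-Cantor
    corrected dN/dS normalized against neutral simulations, allele-specific
    expression classification, and an evaluation harness comparing single- and
    dual-reference calling across coverages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    ape,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    rtracklayer,
    vcfR
LinkingTo: Rcpp
SystemRequirements: C++17
Config/testthat/edition: 3
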