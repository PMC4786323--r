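Package: radsnp
Title: De Novo RAD-Seq SNP Discovery and Domestication Diversity Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reference-free analysis pipeline for restriction
    site-associated DNA (RAD) sequencing of small diploid panels.
    Demultiplexes inline-barcoded single-end reads, clusters identical
    reads into stacks, merges stacks into RAD tag loci, calls genotypes
    with a depth-ratio rule, builds a cross-accession bi-allelic SNP
    catalog, and derives population-genetic summaries: genotype
    p-distances, neighbor-joining trees with bootstrap support,
    principal components, per-accession heterozygosity, within-group
    nucleotide diversity and a loss-of-diversity scan for loci fixed by
    domestication. Includes a RAD read simulator with recorded ground
    truth so every stage can be validated end to end, plus a simple
    transcript matcher and codon-level classifier for synonymous and
    non-synonymous SNPs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    rlang,
    stringr,
    ggplot2,
    generics,
    ape,
    Biostrings,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr,
    jsonlite
Config/testthat/edition: 3
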