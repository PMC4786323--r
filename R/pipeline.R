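# One-call pipeline from raw reads to the genotype matrix.

#' Run the de novo RAD genotyping pipeline
#'
#' Chains preprocessing ([preprocess_reads()]), per-accession stack assembly
#' and depth filtering ([build_stacks()], [filter_stacks()]), locus merging
#' ([merge_stacks_to_loci()]), depth-ratio genotyping
#' ([call_locus_genotypes()]), cross-accession cataloguing
#' ([match_loci_across_accessions()]) and the bi-allelic SNP filters
#' ([select_biallelic_snp_loci()]).
#'
#' @param reads Tibble of raw reads (`read_id`, `sequence`, `quality`).
#' @param barcodes Tibble (`accession`, `barcode`).
#' @param groups Optional group labels for [set_groups()].
#' @param min_stack_depth,max_stack_depth Stack depth filter bounds.
#' @param max_mismatch Mismatch allowance for stack merging and catalog
#'   matching.
#' @param min_accessions Completeness threshold for catalog loci.
#' @param min_total,hom_ratio,het_ratio Genotyper thresholds, see
#'   [call_site_genotype()].
#' @return List with the genotype matrix `genotypes` ([rad_genotypes]) and
#'   intermediates `tags`, `discards`, `stacks`, `stack_log`, `loci`,
#'   `site_calls`, `catalog`, `conflicts`.
#' @export
rad_pipeline <- function(reads, barcodes, groups = NULL,
                         min_stack_depth = 10L, max_stack_depth = 300L,
                         max_mismatch = 1L, min_accessions = 14L,
                         min_total = 10L, hom_ratio = 0.05, het_ratio = 0.1) {
  pre <- preprocess_reads(reads, barcodes)
  stacks <- build_stacks(pre$tags)
  fs <- filter_stacks(stacks, min_stack_depth, max_stack_depth)
  low <- fs$discarded[fs$discarded$reason == "low", , drop = FALSE]
  loci <- merge_stacks_to_loci(fs$retained, max_mismatch, secondary = low)
  calls <- call_locus_genotypes(loci, min_total, hom_ratio, het_ratio)
  matched <- match_loci_across_accessions(loci, max_mismatch)
  gm <- select_biallelic_snp_loci(matched, calls,
                                  accessions = sort(barcodes$accession),
                                  min_accessions = min_accessions)
  if (!is.null(groups)) gm <- set_groups(gm, groups)
  list(genotypes = gm, tags = pre$tags, discards = pre$discards,
       stacks = stacks, stack_log = fs$discarded, loci = loci,
       site_calls = calls, catalog = matched$catalog,
       conflicts = matched$conflicts)
}
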