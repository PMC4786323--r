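# Plain-text exporters for the catalog and popgen results.

#' Write the genotype matrix as TSV
#'
#' Rows are loci, columns accessions; calls are coded 0 (homozygous
#' reference), 1 (heterozygous), 2 (homozygous alternate), NA (missing),
#' preceded by the locus annotation columns.
#'
#' @param gm A [rad_genotypes] object.
#' @param path Output path.
#' @export
write_genotype_tsv <- function(gm, path) {
  codes <- gm$dosage * 2
  df <- cbind(gm$loci[, c("locus_id", "snp_pos", "a1", "a2")],
              as.data.frame(codes))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the genotype matrix as a minimal VCF
#'
#' One record per catalog locus: CHROM is the catalog id, POS the SNP offset
#' within the tag (1-based, per VCF convention), REF/ALT the catalog allele
#' pair, and a GT field per accession (`0/0`, `0/1`, `1/1` or `./.`).
#'
#' @param gm A [rad_genotypes] object.
#' @param path Output path.
#' @export
write_genotype_vcf <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=radsnp",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(gm$dosage)), collapse = "\t")
  ), con)
  gt_code <- function(d) {
    dplyr::case_when(is.na(d) ~ "./.", d == 0 ~ "0/0", d == 1 ~ "1/1",
                     .default = "0/1")
  }
  pos <- gm$loci$snp_pos
  pos[is.na(pos)] <- 0L
  for (i in seq_len(nrow(gm$loci))) {
    writeLines(paste(c(gm$loci$locus_id[i], pos[i] + 1L, ".",
                       gm$loci$a1[i], gm$loci$a2[i], ".", "PASS", ".",
                       "GT", gt_code(gm$dosage[i, ])), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a distance matrix
#'
#' @param d A `rad_dist` object.
#' @param path Output path.
#' @param format `"tsv"` (labelled square table) or `"phylip"` (square
#'   PHYLIP).
#' @export
write_distance_matrix <- function(d, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  m <- d$d
  if (format == "tsv") {
    write.table(data.frame(accession = rownames(m), m, check.names = FALSE),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", nrow(m)), con)
    for (i in seq_len(nrow(m))) {
      writeLines(paste(c(sprintf("%-10s", rownames(m)[i]),
                         sprintf("%.6f", m[i, ])), collapse = " "), con)
    }
  }
  invisible(path)
}

#' Write per-locus diversity / selection-scan records as TSV
#'
#' @param scan A `rad_lod_scan` tibble from [lod_selection_scan()].
#' @param path Output path.
#' @export
write_diversity_tsv <- function(scan, path) {
  write.table(as.data.frame(scan), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
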