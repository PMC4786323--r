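loc_row <- function(accession, consensus, depth, locus_id = NULL) {
  tibble::tibble(
    accession = accession,
    locus_id = locus_id %||% paste0(accession, "_1"),
    consensus = consensus, depth = depth, n_stacks = 1L,
    members = list(tibble::tibble(sequence = consensus, depth = depth)))
}

base_tag <- paste0("AATTC", strrep("A", 36))
swap <- function(seq, pos0, base) {       # pos0: 0-based tag position
  substr(seq, pos0 + 1, pos0 + 1) <- base
  seq
}

test_that("catalog matching groups consensus within one mismatch", {
  accs <- paste0("a", 1:18)
  loci <- dplyr::bind_rows(lapply(accs, function(a)
    loc_row(a, base_tag, 40L)))
  out <- match_loci_across_accessions(loci)
  expect_equal(nrow(out$catalog), 1)
  expect_equal(out$catalog$n_members, 18)

  # one subset differs at a single site: still one entry (candidate SNP)
  loci2 <- dplyr::bind_rows(
    lapply(accs[1:9], function(a) loc_row(a, base_tag, 40L)),
    lapply(accs[10:18], function(a) loc_row(a, swap(base_tag, 20, "G"), 35L)))
  out2 <- match_loci_across_accessions(loci2)
  expect_equal(nrow(out2$catalog), 1)

  # two mismatches -> separate entries
  loci3 <- dplyr::bind_rows(
    loc_row("a1", base_tag, 40L),
    loc_row("a2", swap(swap(base_tag, 20, "G"), 30, "C"), 35L))
  expect_equal(nrow(match_loci_across_accessions(loci3)$catalog), 2)

  # two loci of one accession near one seed: deeper kept, conflict logged
  loci4 <- dplyr::bind_rows(
    loc_row("a1", base_tag, 40L, "a1_1"),
    loc_row("a2", swap(base_tag, 20, "G"), 30L, "a2_1"),
    loc_row("a2", swap(base_tag, 22, "C"), 12L, "a2_2"))
  out4 <- match_loci_across_accessions(loci4)
  expect_equal(nrow(out4$catalog), 1)
  expect_equal(out4$conflicts$locus_id, "a2_2")
  expect_false("a2_2" %in% out4$catalog$members[[1]]$locus_id)
})

empty_calls <- tibble::tibble(
  accession = character(0), locus_id = character(0), pos = integer(0),
  status = character(0), a1 = character(0), a2 = character(0),
  depth_a1 = numeric(0), depth_a2 = numeric(0))

catalog_of <- function(genos, pos0 = 20, alt = "G") {
  # genos: vector of 0 (hom ref), 0.5 (het), 1 (hom alt), NA (absent)
  accs <- paste0("a", seq_along(genos))
  rows <- list()
  calls <- empty_calls
  for (i in seq_along(genos)) {
    if (is.na(genos[i])) next
    cons <- if (genos[i] == 1) swap(base_tag, pos0, alt) else base_tag
    rows[[length(rows) + 1L]] <- loc_row(accs[i], cons, 40L)
    if (genos[i] == 0.5) {
      calls <- dplyr::bind_rows(calls, tibble::tibble(
        accession = accs[i], locus_id = paste0(accs[i], "_1"),
        pos = pos0, status = "heterozygous", a1 = "A", a2 = alt,
        depth_a1 = 22, depth_a2 = 18))
    }
  }
  list(matched = match_loci_across_accessions(dplyr::bind_rows(rows)),
       calls = calls, accessions = accs)
}

test_that("bi-allelic single-SNP selection applies all four filters", {
  # 14 genotyped accessions with one A/G site: kept
  g14 <- c(rep(0, 6), rep(0.5, 4), rep(1, 4), NA, NA, NA, NA)
  cc <- catalog_of(g14)
  gm <- select_biallelic_snp_loci(cc$matched, cc$calls,
                                  accessions = cc$accessions)
  expect_equal(nrow(gm$loci), 1)
  expect_equal(gm$loci$snp_pos, 20)
  expect_equal(sort(c(gm$loci$a1, gm$loci$a2)), c("A", "G"))
  expect_equal(unname(gm$dosage[1, ]), g14)

  # 13 genotyped -> dropped
  g13 <- c(g14[-1], NA)
  cc13 <- catalog_of(g13)
  gm13 <- select_biallelic_snp_loci(cc13$matched, cc13$calls,
                                    accessions = cc13$accessions)
  expect_equal(nrow(gm13$loci), 0)
  expect_equal(attr(gm13, "n_filtered"), 1)

  # monomorphic entry: tallied, not kept
  g_mono <- rep(0, 18)
  ccm <- catalog_of(g_mono)
  gmm <- select_biallelic_snp_loci(ccm$matched, ccm$calls,
                                   accessions = ccm$accessions)
  expect_equal(nrow(gmm$loci), 0)
  expect_equal(attr(gmm, "n_monomorphic"), 1)
})

test_that("entries with two variant sites or remnant-region variants drop", {
  accs <- paste0("a", 1:18)
  # heterozygous calls at two distinct positions across members
  rows <- dplyr::bind_rows(lapply(accs, function(a) loc_row(a, base_tag, 40L)))
  calls2 <- dplyr::bind_rows(
    tibble::tibble(accession = "a1", locus_id = "a1_1", pos = 10L,
                   status = "heterozygous", a1 = "A", a2 = "G",
                   depth_a1 = 20, depth_a2 = 18),
    tibble::tibble(accession = "a2", locus_id = "a2_1", pos = 30L,
                   status = "heterozygous", a1 = "A", a2 = "C",
                   depth_a1 = 21, depth_a2 = 17))
  m <- match_loci_across_accessions(rows)
  gm2 <- select_biallelic_snp_loci(m, calls2, accessions = accs)
  expect_equal(nrow(gm2$loci), 0)

  # a lone variant inside the 5-nt remnant guards against corrupt input
  rows3 <- dplyr::bind_rows(
    lapply(accs[1:9], function(a) loc_row(a, base_tag, 40L)),
    lapply(accs[10:18], function(a) loc_row(a, swap(base_tag, 2, "G"), 40L)))
  gm3 <- select_biallelic_snp_loci(match_loci_across_accessions(rows3),
                                   empty_calls, accessions = accs)
  expect_equal(nrow(gm3$loci), 0)
})

test_that("completeness and single-SNP filters commute", {
  sim <- small_sim()
  pre <- preprocess_reads(sim$reads, sim$barcodes)
  st <- filter_stacks(build_stacks(pre$tags))
  loci <- merge_stacks_to_loci(
    st$retained, secondary = st$discarded[st$discarded$reason == "low", ])
  calls <- call_locus_genotypes(loci)
  matched <- match_loci_across_accessions(loci)
  accs <- sort(sim$barcodes$accession)
  # full filter vs completeness-last: relaxing completeness to 1 and then
  # dropping incomplete loci afterwards must give the same matrix
  gm_a <- select_biallelic_snp_loci(matched, calls, accessions = accs,
                                    min_accessions = 14)
  gm_b <- select_biallelic_snp_loci(matched, calls, accessions = accs,
                                    min_accessions = 1)
  keep <- rowSums(!is.na(gm_b$dosage)) >= 14
  expect_setequal(gm_a$loci$locus_id, gm_b$loci$locus_id[keep])
  m_b <- gm_b$dosage[keep, , drop = FALSE]
  expect_equal(gm_a$dosage, m_b[gm_a$loci$locus_id, , drop = FALSE])
  # every kept locus: exactly two alleles, >= 14 calls
  expect_true(all(rowSums(!is.na(gm_a$dosage)) >= 14))
  expect_true(all(gm_a$loci$a1 != gm_a$loci$a2))
})

test_that("substitution typing is exhaustive over the six unordered pairs", {
  expect_equal(classify_substitution("C", "T"), "transition")
  expect_equal(classify_substitution("A", "T"), "transversion")
  pairs <- t(utils::combn(c("A", "C", "G", "T"), 2))
  types <- classify_substitution(pairs[, 1], pairs[, 2])
  expect_equal(sum(types == "transition"), 2)
  expect_equal(sum(types == "transversion"), 4)
  # order-invariant
  expect_equal(classify_substitution(pairs[, 2], pairs[, 1]), types)
  expect_error(classify_substitution("A", "A"), "distinct")
})

test_that("SNP summaries count pairs, TI/TV and per-accession calls", {
  genos <- tibble::tibble(
    locus_id = rep(c("L1", "L2", "L3"), each = 2),
    accession = rep(c("x", "y"), 3),
    genotype = c("CT", "CC", "AG", "GG", "AT", NA))
  gm <- rad_genotypes(genos)
  s <- summarize_snps(gm)
  expect_equal(s$stats$n_transitions, 2)
  expect_equal(s$stats$n_transversions, 1)
  expect_equal(s$stats$ti_tv, 2)
  expect_equal(sum(s$spectrum$n), 3)
  expect_equal(s$per_accession$n_genotyped, c(3, 2))
  expect_equal(sum(s$per_accession$n_het[s$per_accession$accession == "x"]), 3)
  # TI-only matrix: ratio undefined
  only_ti <- rad_genotypes(tibble::tibble(
    locus_id = "L1", accession = c("x", "y"), genotype = c("CT", "CC")))
  expect_true(is.na(summarize_snps(only_ti)$stats$ti_tv))
})

test_that("recovered transition fraction tracks the planted fraction", {
  sim <- small_sim()
  res <- small_pipeline()
  s <- summarize_snps(res$genotypes)
  n <- s$stats$n_loci
  frac <- s$stats$n_transitions / n
  expect_lt(abs(frac - 0.6), 3 * sqrt(0.6 * 0.4 / n))
})

test_that("genotype TSV and VCF exports round-trip through readers", {
  sim <- small_sim()
  res <- small_pipeline()
  gm <- res$genotypes
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_tsv(gm, tsv)
  back <- utils::read.table(tsv, header = TRUE, sep = "\t",
                            check.names = FALSE)
  expect_equal(nrow(back), nrow(gm$loci))
  expect_equal(unname(as.matrix(back[, colnames(gm$dosage)])),
               unname(gm$dosage * 2))
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_genotype_vcf(gm, vcf)
  v <- VariantAnnotation::readVcf(vcf)
  expect_equal(nrow(v), nrow(gm$loci))
  gt <- VariantAnnotation::geno(v)$GT
  d <- gm$dosage[1, ]
  expected <- ifelse(is.na(d), "./.",
                     ifelse(d == 0, "0/0", ifelse(d == 1, "1/1", "0/1")))
  expect_equal(unname(gt[1, ]), unname(expected))
})
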