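test_that("p-distances follow the 0 / 0.5 / 1 genotype rule", {
  gm <- rad_genotypes(tibble::tibble(
    locus_id = "L1", accession = c("i", "j"), genotype = c("CC", "CT")))
  expect_equal(pairwise_distance_matrix(gm)$d["i", "j"], 0.5)

  # identical vectors -> 0; four loci with (1, 1, 0, 0) -> 0.5
  gm4 <- rad_genotypes(tibble::tibble(
    locus_id = rep(paste0("L", 1:4), each = 2),
    accession = rep(c("i", "j"), 4),
    genotype = c("CC", "TT",  "AA", "GG",  "CC", "CC",  "AT", "AT")))
  d4 <- pairwise_distance_matrix(gm4)
  expect_equal(d4$d["i", "j"], 0.5)
  expect_equal(d4$n_loci["i", "j"], 4L)
  ident <- rad_genotypes(tibble::tibble(
    locus_id = rep(c("L1", "L2"), each = 2), accession = rep(c("i", "j"), 2),
    genotype = c("CC", "CC", "CT", "CT")))
  expect_equal(pairwise_distance_matrix(ident)$d["i", "j"], 0)

  # missing overlap is a hard error naming the pair
  gm_miss <- rad_genotypes(tibble::tibble(
    locus_id = c("L1", "L1", "L2", "L2"),
    accession = c("i", "j", "i", "k"),
    genotype = c("CC", "CC", "CC", "CC")))
  expect_error(pairwise_distance_matrix(gm_miss), "j / k")

  # nucleotide scaling only changes the constant factor
  per_nt <- pairwise_distance_matrix(gm4, scale = "per_nt")
  expect_equal(per_nt$d["i", "j"] * 41, d4$d["i", "j"])
})

test_that("distance matrices are symmetric, bounded and label-stable", {
  sim <- small_sim()
  res <- small_pipeline()
  d <- pairwise_distance_matrix(res$genotypes)
  expect_equal(d$d, t(d$d))
  expect_true(all(diag(d$d) == 0))
  expect_true(all(d$d >= 0 & d$d <= 1))
  # permuting accessions permutes, but does not change, distances
  gm2 <- res$genotypes
  perm <- rev(seq_len(ncol(gm2$dosage)))
  gm2$dosage <- gm2$dosage[, perm]
  gm2$accessions <- gm2$accessions[perm, ]
  d2 <- pairwise_distance_matrix(gm2)
  expect_equal(d2$d[rownames(d$d), colnames(d$d)], d$d)
})

test_that("NJ solves the three-taxon closed form", {
  m <- matrix(c(0, 5, 9,
                5, 0, 8,
                9, 8, 0), 3, 3, dimnames = list(c("a", "b", "c"),
                                                c("a", "b", "c")))
  tr <- neighbor_joining(m)
  expect_setequal(tr$tip.label, c("a", "b", "c"))
  # closed form: v_a = (d_ab + d_ac - d_bc)/2 = 3, v_b = 2, v_c = 6
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[c("a", "b", "c")], c(a = 3, b = 2, c = 6))
  expect_error(neighbor_joining(m[1:2, 1:2]), "three")
})

test_that("NJ is exact on additive metrics from random trees", {
  set.seed(404)
  for (rep in 1:25) {
    n <- sample(8:12, 1)
    true <- ape::rtree(n)
    true$edge.length <- runif(nrow(true$edge), 0.05, 1)
    D <- ape::cophenetic.phylo(true)
    est <- neighbor_joining(D)
    # topology identical (RF distance 0) and path lengths recovered
    expect_equal(ape::dist.topo(ape::unroot(true), est), 0,
                 ignore_attr = TRUE)
    expect_lt(max(abs(ape::cophenetic.phylo(est)[rownames(D), colnames(D)] -
                        D)), 1e-9)
    # cross-check against the independent NJ in ape
    expect_equal(ape::dist.topo(ape::nj(D), est), 0, ignore_attr = TRUE)
  }
})

test_that("bootstrap supports are 0/100 in degenerate settings", {
  sim <- small_sim()
  res <- small_pipeline()
  gm <- res$genotypes
  b1 <- bootstrap_support(gm, n_reps = 1, seed = 1)
  expect_true(all(b1$supports$support %in% c(0, 100)))
  # a matrix of identical columns: every resample gives the same tree
  full <- which(rowSums(!is.na(gm$dosage)) == ncol(gm$dosage))[1]
  gm_dup <- gm
  gm_dup$dosage <- gm$dosage[rep(full, 200), ]
  gm_dup$loci <- gm$loci[rep(full, 200), ]
  rownames(gm_dup$dosage) <- gm_dup$loci$locus_id <- sprintf("D%03d", 1:200)
  b2 <- bootstrap_support(gm_dup, n_reps = 25, seed = 2)
  expect_true(all(b2$supports$support == 100))
  # locus order: reference tree unchanged, strong supports stay strong
  set.seed(33)
  gm_shuf <- gm
  ord <- sample(nrow(gm$dosage))
  gm_shuf$dosage <- gm$dosage[ord, ]
  gm_shuf$loci <- gm$loci[ord, ]
  b3 <- bootstrap_support(gm_shuf, n_reps = 50, seed = 7)
  b4 <- bootstrap_support(gm, n_reps = 50, seed = 7)
  expect_equal(ape::dist.topo(b3$tree, b4$tree), 0, ignore_attr = TRUE)
  s3 <- setNames(b3$supports$support, b3$supports$clade)
  s4 <- setNames(b4$supports$support, b4$supports$clade)
  strong <- names(s4)[s4 >= 95]
  expect_true(all(s3[strong] >= 85))
})

test_that("the deep planted split is monophyletic with strong support", {
  # at this scale (~150 loci) only the deep cultivated/wild divergence is
  # guaranteed to resolve; full six-clade recovery is exercised on the
  # 2,000-locus scenario in the end-to-end suite
  sim <- small_sim()
  res <- small_pipeline()
  boot <- bootstrap_support(res$genotypes, n_reps = 100, seed = 5)
  acc <- sim$config$accessions
  cult <- acc$accession[acc$status == "cultivated"]
  expect_true(ape::is.monophyletic(boot$tree, cult))
  expect_gte(clade_support(boot, cult), 90)
})

test_that("PCA satisfies its algebraic identities and separates clusters", {
  sim <- small_sim()
  res <- small_pipeline()
  p <- pca_coordinates(res$genotypes)
  # trace identity: eigenvalue sum equals total centred covariance
  G <- res$genotypes$dosage
  X <- G - rowMeans(G, na.rm = TRUE)
  X[is.na(X)] <- 0
  expect_equal(sum(p$values), sum(diag(crossprod(X) / (nrow(X) - 1))))
  # PC1 classifies cultivated vs wild (sign-invariant)
  td <- tidy(p)
  cult <- td$PC1[td$group == "cultivated"]
  wild <- td$PC1[td$group == "wild"]
  expect_true(max(cult) < min(wild) || max(wild) < min(cult))
  # rank-1 matrix: exactly one nonzero eigenvalue
  gm1 <- rad_genotypes(tibble::tibble(
    locus_id = "L1", accession = c("a", "b", "c"),
    genotype = c("AA", "AT", "TT")))
  p1 <- pca_coordinates(gm1)
  expect_equal(sum(abs(p1$values) > 1e-12), 1)
})

test_that("heterozygosity rates follow the per-Kb formula and its bounds", {
  genos <- tibble::tibble(
    locus_id = rep(sprintf("L%04d", 1:1000), each = 2),
    accession = rep(c("a", "b"), 1000),
    genotype = c(rbind(c(rep("AT", 100), rep("AA", 900)), rep("AT", 1000))))
  gm <- rad_genotypes(genos)
  h <- heterozygosity_rate(gm)
  # 100 het calls over 41,000 nt -> 2.44 per Kb
  expect_equal(h$het_per_kb[h$accession == "a"], 100 / 41000 * 1000)
  expect_equal(round(h$het_per_kb[h$accession == "a"], 2), 2.44)
  # all-het accession sits at the 1000/41 = 24.39 upper bound
  expect_equal(h$het_per_kb[h$accession == "b"], 1000 / 41)
  expect_error(heterozygosity_rate(gm, "nope"), "unknown")
})

test_that("group_pi matches the brute-force pair loop exhaustively", {
  # all genotype configurations (0, 0.5, 1, NA) of up to 6 members
  lv <- c(0, 0.5, 1, NA)
  for (m in 2:6) {
    grid <- do.call(expand.grid, rep(list(lv), m))
    gm <- new_test_gm(as.matrix(grid))
    got <- group_pi(gm, paste0("m", seq_len(m)), min_members = 3)$pi
    want <- apply(as.matrix(grid), 1, oracle_pi)
    expect_equal(got, unname(want))
  }
})

test_that("the LOD scan flags exactly the fixed-cultivated loci", {
  acc <- c(paste0("c", 1:9), paste0("w", 1:8))
  grp <- setNames(c(rep("cultivated", 9), rep("wild", 8)), acc)
  mk_locus <- function(id, cult, wild) {
    tibble::tibble(locus_id = id, accession = acc, genotype = c(cult, wild))
  }
  calls <- dplyr::bind_rows(
    mk_locus("fixed", rep("AA", 9), rep(c("AA", "TT"), 4)),
    mk_locus("balanced", c(rep("AA", 4), rep("TT", 4), NA),
             c(rep("AA", 4), rep("TT", 4))),
    mk_locus("partial", c(rep("AA", 8), "AT"), rep(c("AA", "TT"), 4)),
    mk_locus("wild_fixed", rep(c("AA", "TT"), c(4, 5)), rep("AA", 8)))
  gm <- rad_genotypes(calls, groups = grp)
  scan <- lod_selection_scan(gm)
  row <- function(id) scan[scan$locus_id == id, ]
  expect_equal(row("fixed")$lod, 1)
  expect_true(row("fixed")$selected)
  expect_equal(row("balanced")$lod, 0, tolerance = 1e-12)
  expect_false(row("balanced")$selected)
  # pi_c = 8 * 0.5 / 36, pi_w = 16/28: LOD = 1 - pi_c/pi_w
  expect_equal(row("partial")$lod, 1 - (4 / 36) / (16 / 28))
  expect_false(row("partial")$selected)
  expect_true(is.na(row("wild_fixed")$lod))
  expect_false(row("wild_fixed")$selected)
  expect_error(lod_selection_scan(gm, cultivated = acc[1:9],
                                  wild = acc[c(1, 10:17)]), "disjoint")
})

test_that("group resolution accepts labels and rejects unknowns", {
  gm <- rad_genotypes(
    tibble::tibble(locus_id = "L1", accession = c("a", "b", "c", "d"),
                   genotype = c("AA", "AT", "TT", "AA")),
    groups = c(a = "wild", b = "wild", c = "wild", d = "cultivated"))
  expect_equal(group_pi(gm, "wild", min_members = 2)$pi,
               group_pi(gm, c("a", "b", "c"), min_members = 2)$pi)
  expect_error(group_pi(gm, c("a", "zzz")), "unknown")
})
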