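# Independent brute-force oracles and small fixture builders used across the
# suite. Everything here is deliberately naive and separate from the package
# implementation paths it checks.

oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# brute-force restatement of the depth-ratio genotyping rule table
oracle_site_call <- function(d1, d2, min_total = 10, lo = 0.05, hi = 0.1) {
  if (d1 + d2 < min_total) return("insufficient_depth")
  if (d2 == 0) return("homozygous")
  r <- d2 / d1
  if (r < lo) return("homozygous")
  if (r > hi) return("heterozygous")
  "discarded_ambiguous"
}

# brute-force pi: explicit double loop over pairs of dosages (0, 0.5, 1, NA)
oracle_pi <- function(dos, min_members = 3) {
  dos <- dos[!is.na(dos)]
  m <- length(dos)
  if (m < max(min_members, 2)) return(NA_real_)
  tot <- 0
  np <- 0
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      tot <- tot + abs(dos[i] - dos[j])
      np <- np + 1
    }
  }
  tot / np
}

# brute-force single-linkage (transitive) clustering, as the alternative to
# star linkage, for quantifying the chain case
oracle_connected_components <- function(seqs, max_mismatch = 1) {
  n <- length(seqs)
  comp <- seq_len(n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (oracle_hamming(seqs[i], seqs[j]) <= max_mismatch) {
        comp[comp == comp[j]] <- comp[i]
      }
    }
  }
  match(comp, unique(comp))
}

# translate a codon with Biostrings' genetic code table (used as the
# enumeration oracle against classify_coding_effect)
oracle_translate <- function(codon) unname(Biostrings::GENETIC_CODE[codon])

# genotype tibble -> rad_genotypes helper for worked examples
make_gm <- function(genotypes, groups = NULL, locus_id = "L1") {
  calls <- tibble::tibble(
    locus_id = locus_id,
    accession = names(genotypes) %||% paste0("acc", seq_along(genotypes)),
    genotype = unname(genotypes)
  )
  radsnp::rad_genotypes(calls, groups = groups)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# dosage-configuration matrix (rows = loci, entries 0/0.5/1/NA) -> a
# rad_genotypes built through the public string constructor
new_test_gm <- function(dosmat) {
  m <- ncol(dosmat)
  accs <- paste0("m", seq_len(m))
  long <- expand.grid(locus = seq_len(nrow(dosmat)), acc = seq_len(m))
  d <- dosmat[cbind(long$locus, long$acc)]
  geno <- ifelse(is.na(d), NA_character_,
                 ifelse(d == 0, "AA", ifelse(d == 1, "TT", "AT")))
  radsnp::rad_genotypes(tibble::tibble(
    locus_id = sprintf("L%04d", long$locus),
    accession = accs[long$acc],
    genotype = geno))
}

# small cached simulation shared by several test files (built once per run)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- radsnp::sim_config(n_fragments = 150, seed = 421)
      cache <<- radsnp::simulate_rad_experiment(cfg, transcriptome = TRUE,
                                                n_embed = 40, seed = NULL)
    }
    cache
  }
})

# error-free, fully observed, regular-depth configuration for
# exact-recovery checks (Poisson depth: no stochastic coverage dropouts)
perfect_config <- function(n_fragments = 150, seed = 99) {
  radsnp::sim_config(
    n_fragments = n_fragments,
    error_rate = 0,
    missing_rate = 0,
    low_quality_read_fraction = 0,
    depth_dispersion = Inf,
    seed = seed
  )
}

run_pipeline_on <- function(sim) {
  grp <- stats::setNames(sim$config$accessions$status,
                         sim$config$accessions$accession)
  radsnp::rad_pipeline(sim$reads, sim$barcodes, groups = grp)
}

# memoised pipeline over small_sim(), shared across test files
small_pipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- run_pipeline_on(small_sim())
    cache
  }
})

# truth loci expected in a perfect-data catalog: non-repeat families whose
# realized genotypes segregate at exactly one planted variant
expected_catalog_families <- function(truth) {
  gt <- truth$genotypes
  poly <- tapply(gt$genotype, list(gt$locus_id, gt$variant),
                 function(g) length(unique(g)) > 1)
  n_poly <- rowSums(poly, na.rm = TRUE)
  names(n_poly)[n_poly == 1]
}

# map catalog loci back to truth families via exact window-piece keys: a
# catalog consensus differs from the reference window at no more than two
# positions (the SNP's major allele plus one fixed co-planted variant), and
# two corruptions can hit at most two of three disjoint pieces
catalog_to_family <- function(gm, fragments) {
  fam <- fragments[!duplicated(fragments$family_id), ]
  win <- stats::setNames(substr(fam$sequence, 1, 41), fam$family_id)
  # pieces cover only the 36 variable nt (the constant remnant carries no
  # identity); candidates are verified by full Hamming distance, so chance
  # piece collisions cannot mis-assign
  cuts <- list(c(6, 17), c(18, 29), c(30, 41))
  index <- new.env(parent = emptyenv())
  for (f in names(win)) {
    for (p in seq_along(cuts)) {
      key <- paste0(p, ":", substr(win[[f]], cuts[[p]][1], cuts[[p]][2]))
      index[[key]] <- c(index[[key]], f)
    }
  }
  vapply(gm$loci$consensus, function(cons) {
    cand <- unique(unlist(lapply(seq_along(cuts), function(p) {
      index[[paste0(p, ":", substr(cons, cuts[[p]][1], cuts[[p]][2]))]]
    })))
    if (is.null(cand)) return(NA_character_)
    d <- vapply(cand, function(f) oracle_hamming(cons, win[[f]]), numeric(1))
    if (min(d) > 2) return(NA_character_)
    cand[which.min(d)]
  }, character(1), USE.NAMES = FALSE)
}

# normalised unordered genotype string from truth h1/h2 alleles
norm_geno <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "/")
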