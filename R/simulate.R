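# Synthetic RAD-seq experiment generator.
#
# Emulates a reduced-representation study of a small diploid panel: EcoRI
# fragments, inline 4-8 nt barcodes, ~40-70x per-tag depth, sequencing error,
# repetitive high-depth tags, missing accessions, and a subset of loci fixed
# in the cultivated group but polymorphic in the wild group. Every random
# choice is recorded in a ground-truth table so downstream recovery can be
# scored exactly.

#' Default accession panel
#'
#' Eighteen diploid accessions in six clades: two cultivated clades
#' (`Css` x6, `Csa` x3), three wild clades (`Ccc` x4, `Ctl` x3, `Ctg` x1)
#' and one admixed semi-wild landrace (`Ctb`), mirroring a typical tea
#' domestication panel.
#'
#' @return A tibble with columns `accession`, `clade` and `status`
#'   (`cultivated`, `wild` or `admixed`).
#' @export
default_accessions <- function() {
  tibble(
    accession = c(paste0("Css-", 1:6), paste0("Csa-", 1:3),
                  paste0("Ccc-", 1:4), paste0("Ctl-", 1:3), "Ctg", "Ctb"),
    clade = c(rep("Css", 6), rep("Csa", 3),
              rep("Ccc", 4), rep("Ctl", 3), "Ctg", "Ctb"),
    status = c(rep("cultivated", 9), rep("wild", 8), "admixed")
  )
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic RAD experiment. Defaults describe the
#' study conditions the package is validated under: 18 accessions in six
#' clades, 2,000 EcoRI fragments, 50-bp single-end reads, negative-binomial
#' per-tag depth with mean 40, a low per-base error rate, a small repetitive
#' fraction producing >300x stacks, and 5% of loci fixed in the cultivated
#' group.
#'
#' @param accessions Accession table as from [default_accessions()].
#' @param n_fragments Number of distinct restriction fragments (= candidate
#'   RAD tag loci).
#' @param fragment_length Fragment length in nt; must exceed `read_length`.
#' @param read_length Read length in nt (single-end).
#' @param barcode_lengths Integer range of inline barcode lengths.
#' @param mean_depth Mean reads per tag per accession.
#' @param depth_dispersion Negative-binomial size parameter of the depth law;
#'   `Inf` gives Poisson depth.
#' @param error_rate Per-base substitution error probability.
#' @param het_rate_by_group Named heterozygote retention factors (1 - F_IS)
#'   applied to Hardy-Weinberg genotype draws, one per status level.
#' @param fixed_cultivated_fraction Fraction of clean loci forced to a fixed
#'   homozygous genotype across all cultivated accessions while the wild
#'   group remains polymorphic.
#' @param repeat_fraction Fraction of fragments duplicated near-identically
#'   elsewhere in the genome, inflating their stack depth past the
#'   repetitive-stack filter.
#' @param repeat_copies Integer range of genomic copy number for repeats.
#' @param multi_snp_fraction Fraction of clean loci carrying a second variant
#'   (exercises the single-SNP catalog filter).
#' @param missing_rate Probability an accession yields no reads at a locus.
#' @param low_quality_read_fraction Fraction of reads given a heavy Q<=5 tail
#'   to exercise the quality filter.
#' @param ti_fraction Probability a planted variant is a transition.
#' @param fst_split,fst_group Balding-Nichols differentiation at the
#'   cultivated/wild split and at the clade level.
#' @param seed Integer seed making the whole experiment reproducible.
#' @return A `rad_sim_config` list.
#' @export
sim_config <- function(accessions = default_accessions(),
                       n_fragments = 2000,
                       fragment_length = 300,
                       read_length = 50,
                       barcode_lengths = c(4L, 8L),
                       mean_depth = 40,
                       depth_dispersion = 20,
                       error_rate = 0.002,
                       het_rate_by_group = c(cultivated = 0.9, wild = 0.5,
                                             admixed = 1.0),
                       fixed_cultivated_fraction = 0.05,
                       repeat_fraction = 0.02,
                       repeat_copies = c(8L, 12L),
                       multi_snp_fraction = 0.03,
                       missing_rate = 0.005,
                       low_quality_read_fraction = 0.02,
                       ti_fraction = 0.6,
                       fst_split = 0.2,
                       fst_group = 0.2,
                       seed = 1L) {
  cfg <- list(
    accessions = as_tibble(accessions),
    n_fragments = as.integer(n_fragments),
    fragment_length = as.integer(fragment_length),
    read_length = as.integer(read_length),
    barcode_lengths = as.integer(barcode_lengths),
    mean_depth = mean_depth,
    depth_dispersion = depth_dispersion,
    error_rate = error_rate,
    het_rate_by_group = het_rate_by_group,
    fixed_cultivated_fraction = fixed_cultivated_fraction,
    repeat_fraction = repeat_fraction,
    repeat_copies = as.integer(repeat_copies),
    multi_snp_fraction = multi_snp_fraction,
    missing_rate = missing_rate,
    low_quality_read_fraction = low_quality_read_fraction,
    ti_fraction = ti_fraction,
    fst_split = fst_split,
    fst_group = fst_group,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "rad_sim_config")
}

validate_sim_config <- function(cfg) {
  acc <- cfg$accessions
  stopifnot(
    all(c("accession", "clade", "status") %in% names(acc)),
    !anyDuplicated(acc$accession)
  )
  if (!all(acc$status %in% c("cultivated", "wild", "admixed"))) {
    abort("accession status must be one of cultivated/wild/admixed")
  }
  probs <- c(cfg$error_rate, cfg$fixed_cultivated_fraction,
             cfg$repeat_fraction, cfg$multi_snp_fraction, cfg$missing_rate,
             cfg$low_quality_read_fraction, cfg$ti_fraction,
             cfg$het_rate_by_group)
  if (any(probs < 0 | probs > 1)) {
    abort("all probability parameters must lie in [0, 1]")
  }
  if (cfg$fragment_length <= cfg$read_length) {
    abort("fragment_length must exceed read_length")
  }
  if (cfg$n_fragments < 0) abort("n_fragments must be >= 0")
  invisible(cfg)
}

#' Generate a barcode set with a minimum pairwise Hamming distance
#'
#' Draws `n` inline barcodes over lengths in `length_range` such that any two
#' equal-length barcodes differ at `min_distance` or more positions, so a
#' single sequencing error cannot convert one barcode into another.
#'
#' @param n Number of barcodes.
#' @param length_range Two integers giving the inclusive barcode length range.
#' @param min_distance Minimum Hamming distance between equal-length barcodes.
#' @param seed Optional integer seed.
#' @param max_tries Rejection-sampling budget before declaring the request
#'   infeasible.
#' @return Character vector of `n` barcodes.
#' @export
make_barcode_set <- function(n, length_range = c(4L, 8L), min_distance = 2L,
                             seed = NULL, max_tries = 10000L) {
  if (n < 1) abort("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  lengths <- seq(length_range[1], length_range[2])
  # spread barcodes across the available lengths as evenly as possible
  len_of <- rep(lengths, length.out = n)
  out <- character(0)
  tries <- 0L
  while (length(out) < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      abort(sprintf(
        "cannot place %d barcodes of lengths %d-%d at Hamming distance >= %d",
        n, length_range[1], length_range[2], min_distance))
    }
    want <- len_of[length(out) + 1L]
    cand <- random_dna(1, want)
    same_len <- out[nchar(out) == want]
    if (all(vapply(same_len, function(b) hamming(b, cand) >= min_distance,
                   logical(1)))) {
      out <- c(out, cand)
    }
  }
  out
}

#' Generate reference restriction fragments
#'
#' Each fragment record begins with the EcoRI remnant `AATTC`, so a sequencing
#' read is `barcode + AATTC + insert`. A `repeat_fraction` of fragment
#' families is emitted in several near-identical genomic copies (identical
#' over the 41-nt tag window, lightly mutated elsewhere), which multiplies
#' their read depth and lets the repetitive-stack filter be exercised.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @return A tibble with columns `fragment_id`, `family_id`, `is_repeat`,
#'   `n_copies` and `sequence`.
#' @export
generate_reference_fragments <- function(config, seed = NULL) {
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_fragments
  if (n == 0) {
    return(tibble(fragment_id = character(0), family_id = character(0),
                  is_repeat = logical(0), n_copies = integer(0),
                  sequence = character(0)))
  }
  body_len <- config$fragment_length - nchar(ECORI_REMNANT)
  base <- paste0(ECORI_REMNANT, random_dna(n, body_len))
  fam <- sprintf("L%05d", seq_len(n))
  n_rep <- round(config$repeat_fraction * n)
  is_rep <- rep(FALSE, n)
  if (n_rep > 0) is_rep[sample.int(n, n_rep)] <- TRUE
  copies <- ifelse(is_rep,
                   sample(seq(config$repeat_copies[1], config$repeat_copies[2]),
                          n, replace = TRUE),
                   1L)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    k <- copies[i]
    seqs <- rep(base[i], k)
    if (k > 1) {
      # mutate copies outside the tag window so stacks still collapse
      for (j in 2:k) {
        s <- strsplit(seqs[j], "")[[1]]
        mut <- which(runif(length(s)) < 0.01)
        mut <- mut[mut > TAG_LENGTH]
        if (length(mut)) {
          s[mut] <- vapply(s[mut], function(b) {
            sample(setdiff(DNA_BASES, b), 1)
          }, character(1))
          seqs[j] <- paste(s, collapse = "")
        }
      }
    }
    rows[[i]] <- tibble(
      fragment_id = if (k == 1) fam[i] else paste0(fam[i], "c", seq_len(k)),
      family_id = fam[i],
      is_repeat = is_rep[i],
      n_copies = as.integer(k),
      sequence = seqs
    )
  }
  bind_rows(rows)
}

balding_nichols <- function(p, fst) {
  if (fst <= 0) return(p)
  a <- p * (1 - fst) / fst
  b <- (1 - p) * (1 - fst) / fst
  rbeta(length(p), a, b)
}

#' Plant variants and draw true diploid genotypes
#'
#' Places exactly one bi-allelic variant in the 36-nt variable window of each
#' clean tag (a configurable subset carries a second variant), draws per-clade
#' allele frequencies from a hierarchical Balding-Nichols model with a
#' cultivated/wild split, samples Hardy-Weinberg genotypes per accession with
#' group-specific heterozygote retention, and forces a
#' `fixed_cultivated_fraction` of loci to a single homozygous genotype across
#' all cultivated accessions while keeping the wild group polymorphic. The
#' admixed accession draws one haplotype from a cultivated-like and one from a
#' wild-like frequency.
#'
#' @param fragments Output of [generate_reference_fragments()].
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @return A list of class `rad_truth` with elements `loci` (one row per
#'   planted variant: `locus_id`, `fragment_id`, `variant`, `snp_pos` 0-based
#'   within the 41-nt tag, alleles `a1`/`a2`, `n_variants`, `is_repeat`,
#'   `planted_fixed`, `selected`), `genotypes` (long: `locus_id`, `variant`,
#'   `accession`, allele columns `h1`/`h2`, `genotype`, `missing`),
#'   `haplotype_windows` (per locus x accession tag windows) and `accessions`.
#' @export
plant_variants <- function(fragments, config, seed = NULL) {
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  acc <- config$accessions
  n_acc <- nrow(acc)
  fams <- fragments |>
    dplyr::distinct(.data$family_id, .data$is_repeat) |>
    left_join(
      fragments |> group_by(.data$family_id) |>
        summarise(sequence = .data$sequence[1], .groups = "drop"),
      by = "family_id"
    )
  clean <- fams$family_id[!fams$is_repeat]
  n_clean <- length(clean)
  if (n_clean == 0) abort("no clean (non-repeat) fragments to plant variants on")

  n_multi <- round(config$multi_snp_fraction * n_clean)
  multi <- if (n_multi > 0) sample(clean, n_multi) else character(0)
  n_fix <- round(config$fixed_cultivated_fraction * (n_clean - n_multi))
  fixable <- setdiff(clean, multi)
  fixed <- if (n_fix > 0) sample(fixable, n_fix) else character(0)

  cult <- acc$accession[acc$status == "cultivated"]
  wild <- acc$accession[acc$status == "wild"]
  clades <- split(acc$accession, acc$clade)
  cult_clades <- unique(acc$clade[acc$status == "cultivated"])
  wild_clades <- unique(acc$clade[acc$status == "wild"])
  admixed <- acc$accession[acc$status == "admixed"]
  retention <- config$het_rate_by_group

  window_of <- setNames(substr(fams$sequence, 1, TAG_LENGTH), fams$family_id)

  pick_alt <- function(ref) {
    ti <- c(A = "G", G = "A", C = "T", T = "C")[ref]
    if (runif(1) < config$ti_fraction) unname(ti)
    else sample(setdiff(DNA_BASES, c(ref, ti)), 1)
  }

  draw_genotypes <- function(p_clade, ctb_p) {
    # p_clade: named alt-allele frequency per clade; returns h1/h2 alt counts
    h1 <- h2 <- integer(n_acc)
    for (i in seq_len(n_acc)) {
      if (acc$status[i] == "admixed") {
        h1[i] <- rbinom(1, 1, ctb_p["cultivated"])
        h2[i] <- rbinom(1, 1, ctb_p["wild"])
      } else {
        p <- p_clade[acc$clade[i]]
        h1[i] <- rbinom(1, 1, p)
        h2[i] <- rbinom(1, 1, p)
      }
      if (h1[i] != h2[i]) {
        keep <- retention[acc$status[i]]
        if (runif(1) >= keep) {
          if (runif(1) < 0.5) h2[i] <- h1[i] else h1[i] <- h2[i]
        }
      }
    }
    list(h1 = h1, h2 = h2)
  }

  loci_rows <- list()
  geno_rows <- list()
  hap_rows <- list()
  for (fam in clean) {
    n_var <- if (fam %in% multi) 2L else 1L
    pos <- sort(sample(VARIABLE_REGION, n_var))
    win <- window_of[[fam]]
    alleles_h1 <- matrix("", nrow = n_acc, ncol = n_var)
    alleles_h2 <- matrix("", nrow = n_acc, ncol = n_var)
    for (v in seq_len(n_var)) {
      ref <- substr(win, pos[v] + 1L, pos[v] + 1L)
      alt <- pick_alt(ref)
      if (fam %in% fixed && v == 1L) {
        fixed_allele <- if (runif(1) < 0.5) 0L else 1L
        p_center <- runif(1, 0.3, 0.7)
        p_wild_clades <- setNames(
          balding_nichols(rep(p_center, length(wild_clades)), config$fst_group),
          wild_clades)
        repeat {
          h1 <- h2 <- integer(n_acc)
          for (i in seq_len(n_acc)) {
            st <- acc$status[i]
            if (st == "cultivated") {
              h1[i] <- h2[i] <- fixed_allele
            } else if (st == "wild") {
              p <- p_wild_clades[acc$clade[i]]
              h1[i] <- rbinom(1, 1, p)
              h2[i] <- rbinom(1, 1, p)
              if (h1[i] != h2[i] && runif(1) >= retention["wild"]) {
                if (runif(1) < 0.5) h2[i] <- h1[i] else h1[i] <- h2[i]
              }
            } else {
              # admixed: cultivated-like haplotype carries the fixed allele
              h1[i] <- fixed_allele
              h2[i] <- rbinom(1, 1, p_center)
            }
          }
          wg <- h1[acc$status == "wild"] + h2[acc$status == "wild"]
          if (length(unique(wg)) > 1 || any(wg == 1)) break
        }
        g <- list(h1 = h1, h2 = h2)
      } else {
        p_anc <- runif(1, 0.1, 0.9)
        p_cult <- balding_nichols(p_anc, config$fst_split)
        p_wild <- balding_nichols(p_anc, config$fst_split)
        p_clade <- c(
          setNames(balding_nichols(rep(p_cult, length(cult_clades)),
                                   config$fst_group), cult_clades),
          setNames(balding_nichols(rep(p_wild, length(wild_clades)),
                                   config$fst_group), wild_clades)
        )
        ctb_p <- c(cultivated = balding_nichols(p_cult, config$fst_group),
                   wild = balding_nichols(p_wild, config$fst_group))
        g <- draw_genotypes(p_clade, ctb_p)
      }
      ref_alt <- c(ref, alt)
      alleles_h1[, v] <- ref_alt[g$h1 + 1L]
      alleles_h2[, v] <- ref_alt[g$h2 + 1L]
      loci_rows[[length(loci_rows) + 1L]] <- tibble(
        locus_id = fam, fragment_id = fam, variant = v,
        snp_pos = pos[v], a1 = ref, a2 = alt, n_variants = n_var,
        is_repeat = FALSE, planted_fixed = fam %in% fixed && v == 1L
      )
    }
    missing <- runif(n_acc) < config$missing_rate
    h1_win <- h2_win <- rep(win, n_acc)
    for (v in seq_len(n_var)) {
      substr(h1_win, pos[v] + 1L, pos[v] + 1L) <- alleles_h1[, v]
      substr(h2_win, pos[v] + 1L, pos[v] + 1L) <- alleles_h2[, v]
    }
    geno_rows[[length(geno_rows) + 1L]] <- tibble(
      locus_id = fam,
      variant = rep(seq_len(n_var), each = n_acc),
      accession = rep(acc$accession, n_var),
      h1 = as.vector(alleles_h1), h2 = as.vector(alleles_h2),
      missing = rep(missing, n_var)
    )
    hap_rows[[length(hap_rows) + 1L]] <- tibble(
      locus_id = fam, accession = acc$accession,
      hap1 = h1_win, hap2 = h2_win, missing = missing
    )
  }
  # repeat families carry no variants but still produce (filtered) reads
  rep_fams <- fams$family_id[fams$is_repeat]
  for (fam in rep_fams) {
    win <- window_of[[fam]]
    hap_rows[[length(hap_rows) + 1L]] <- tibble(
      locus_id = fam, accession = acc$accession,
      hap1 = win, hap2 = win, missing = FALSE
    )
  }

  loci <- bind_rows(loci_rows)
  genotypes <- bind_rows(geno_rows) |>
    mutate(genotype = paste0(pmin(.data$h1, .data$h2),
                             "/", pmax(.data$h1, .data$h2)))
  haplotypes <- bind_rows(hap_rows)

  # selected flag from realized genotypes, at the locus level: exactly one
  # variant segregates in the panel, the cultivated group shares a single
  # homozygous genotype there, and the wild group is polymorphic there
  per_variant <- genotypes |>
    left_join(select(acc, "accession", "status"), by = "accession") |>
    group_by(.data$locus_id, .data$variant) |>
    summarise(
      segregating = dplyr::n_distinct(.data$genotype) > 1,
      cult_fixed = {
        g <- .data$genotype[.data$status == "cultivated"]
        all(g == g[1]) && substr(g[1], 1, 1) == substr(g[1], 3, 3)
      },
      wild_poly = dplyr::n_distinct(
        .data$genotype[.data$status == "wild"]) > 1 ||
        any(.data$h1[.data$status == "wild"] !=
              .data$h2[.data$status == "wild"]),
      .groups = "drop"
    )
  sel <- per_variant |>
    group_by(.data$locus_id) |>
    summarise(
      selected = sum(.data$segregating) == 1L &&
        any(.data$segregating & .data$cult_fixed & .data$wild_poly),
      .groups = "drop"
    )
  loci <- left_join(loci, sel, by = "locus_id")

  structure(
    list(loci = loci, genotypes = genotypes,
         haplotype_windows = haplotypes, accessions = acc,
         repeat_families = rep_fams),
    class = "rad_truth"
  )
}

#' Simulate barcoded RAD reads
#'
#' Draws per-locus, per-accession read counts from the configured depth law
#' (negative binomial; Poisson when `depth_dispersion = Inf`), splits reads
#' evenly between the two haplotypes, applies per-base substitution errors,
#' and emits Phred+33 qualities with a configurable fraction of reads carrying
#' a heavy low-quality (Q<=5) tail. Repetitive families emit reads for each
#' genomic copy, inflating their stack depth.
#'
#' @param truth A `rad_truth` from [plant_variants()].
#' @param barcodes Tibble with columns `accession` and `barcode` (or a bare
#'   character vector in accession order).
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @return A tibble of reads: `read_id`, `sequence`, `quality`.
#' @export
simulate_rad_reads <- function(truth, barcodes, config, seed = NULL) {
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  acc <- config$accessions
  if (is.character(barcodes)) {
    barcodes <- tibble(accession = acc$accession, barcode = barcodes)
  }
  stopifnot(all(acc$accession %in% barcodes$accession))
  bc_of <- setNames(barcodes$barcode, barcodes$accession)

  hw <- truth$haplotype_windows |> filter(!.data$missing)
  # genomic copy number inflates the expected depth of repetitive tags
  copies_of <- attr(truth, "copy_number")
  copies <- if (is.null(copies_of)) rep(1L, nrow(hw)) else copies_of[hw$locus_id]
  copies[is.na(copies)] <- 1L
  mu <- config$mean_depth * copies
  n_reads <- if (is.infinite(config$depth_dispersion)) {
    rpois(nrow(hw), mu)
  } else {
    rnbinom(nrow(hw), size = config$depth_dispersion, mu = mu)
  }
  n_h1 <- rbinom(nrow(hw), n_reads, 0.5)
  n_h2 <- n_reads - n_h1

  bc <- bc_of[hw$accession]
  ins_len <- config$read_length - nchar(bc)
  tmpl_h1 <- paste0(bc, substr(hw$hap1, 1, ins_len))
  tmpl_h2 <- paste0(bc, substr(hw$hap2, 1, ins_len))
  # haplotype windows are 41 nt; pad templates to read length from the
  # fragment body is unnecessary for analysis, but keep reads full length
  pad_len <- config$read_length - nchar(tmpl_h1)
  seqs <- c(rep(tmpl_h1, n_h1), rep(tmpl_h2, n_h2))
  pads <- c(rep(pad_len, n_h1), rep(pad_len, n_h2))
  if (any(pads > 0)) {
    need <- which(pads > 0)
    seqs[need] <- paste0(seqs[need], random_dna(length(need), max(pads))) |>
      substr(1, config$read_length)
  }
  n_total <- length(seqs)
  ids <- sprintf("read_%07d", seq_len(n_total))

  if (config$error_rate > 0 && n_total > 0) {
    p_any <- 1 - (1 - config$error_rate)^config$read_length
    hit <- which(runif(n_total) < p_any)
    n_err <- 1L + rbinom(length(hit), config$read_length - 1L,
                         config$error_rate)
    # single-error reads (the vast majority) are mutated vectorised
    one <- hit[n_err == 1L]
    if (length(one)) {
      pos <- sample.int(config$read_length, length(one), replace = TRUE)
      old <- substr(seqs[one], pos, pos)
      alt <- matrix(c("C", "G", "T", "A", "G", "T",
                      "A", "C", "T", "A", "C", "G"),
                    nrow = 4, byrow = TRUE, dimnames = list(DNA_BASES, NULL))
      new <- alt[cbind(match(old, DNA_BASES),
                       sample.int(3L, length(one), replace = TRUE))]
      s <- seqs[one]
      substr(s, pos, pos) <- new
      seqs[one] <- s
    }
    for (k in which(n_err > 1L)) {
      i <- hit[k]
      pos <- sample.int(config$read_length, n_err[k])
      s <- seqs[i]
      for (p in pos) {
        old <- substr(s, p, p)
        substr(s, p, p) <- sample(setdiff(DNA_BASES, old), 1)
      }
      seqs[i] <- s
    }
  }

  hi <- strrep("G", config$read_length)  # Q38
  quals <- rep(hi, n_total)
  if (config$low_quality_read_fraction > 0 && n_total > 0) {
    low <- which(runif(n_total) < config$low_quality_read_fraction)
    for (i in low) {
      mask <- runif(config$read_length) < 0.7
      q <- strsplit(quals[i], "")[[1]]
      q[mask] <- "#"  # Q2
      quals[i] <- paste(q, collapse = "")
    }
  }

  tibble(read_id = ids, sequence = seqs, quality = quals)
}

#' Generate a toy transcriptome with recorded coding effects
#'
#' Embeds the tag windows of a subset of clean loci into synthetic
#' transcripts (some reverse-complemented), assigns a CDS interval to a
#' configurable fraction, and records the true effect of each planted variant
#' (synonymous, non-synonymous or non-coding) by codon substitution under the
#' standard genetic code. This is a synthetic stand-in for a real assembled
#' transcriptome.
#'
#' @param truth A `rad_truth` from [plant_variants()].
#' @param n_embed Number of single-variant clean loci to embed.
#' @param coding_fraction Fraction of embedded loci whose variant falls inside
#'   a CDS.
#' @param minus_fraction Fraction of transcripts carrying the tag on the
#'   reverse strand.
#' @param n_decoys Number of transcripts containing no tag.
#' @param flank Flank length added on each side of the embedded tag.
#' @param seed Optional integer seed.
#' @return A list with `transcripts` (tibble `transcript_id`, `sequence`),
#'   `cds` (tibble `transcript_id`, `cds_start`, `cds_end`, `frame`; 0-based
#'   half-open) and `effects` (truth tibble per embedded locus).
#' @export
generate_toy_transcriptome <- function(truth, n_embed = 50,
                                       coding_fraction = 0.6,
                                       minus_fraction = 0.3,
                                       n_decoys = 10, flank = 60,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  loci <- truth$loci |> filter(.data$n_variants == 1L)
  n_embed <- min(n_embed, nrow(loci))
  pick <- loci[sample.int(nrow(loci), n_embed), ]
  win_of <- truth$haplotype_windows |>
    group_by(.data$locus_id) |>
    summarise(window = .data$hap1[1], .groups = "drop")
  # reference window carries the a1 allele at the SNP (hap1 may carry either);
  # rebuild from alleles to be explicit
  tx_rows <- cds_rows <- eff_rows <- list()
  n_coding <- round(coding_fraction * n_embed)
  coding <- rep(c(TRUE, FALSE), c(n_coding, n_embed - n_coding))
  coding <- sample(coding)
  for (i in seq_len(n_embed)) {
    li <- pick[i, ]
    win <- win_of$window[win_of$locus_id == li$locus_id]
    substr(win, li$snp_pos + 1L, li$snp_pos + 1L) <- li$a1
    strand <- if (runif(1) < minus_fraction) "-" else "+"
    left <- random_dna(1, flank)
    right <- random_dna(1, flank)
    ins <- if (strand == "+") win else revcomp(win)
    tx <- paste0(left, ins, right)
    tx_id <- sprintf("TX%04d", i)
    tx_rows[[i]] <- tibble(transcript_id = tx_id, sequence = tx)
    # transcript position of the SNP (0-based)
    snp_tx <- if (strand == "+") flank + li$snp_pos
              else flank + (TAG_LENGTH - 1L) - li$snp_pos
    a1_tx <- if (strand == "+") li$a1 else complement_base(li$a1)
    a2_tx <- if (strand == "+") li$a2 else complement_base(li$a2)
    if (coding[i]) {
      ph <- sample(0:2, 1)
      cds_start <- snp_tx - ph - 3L * sample(0:5, 1)
      if (cds_start < 0) cds_start <- snp_tx - ph
      if (cds_start < 0) cds_start <- snp_tx  # degenerate, keep in frame 0
      max_end <- nchar(tx)
      cds_end <- cds_start + 3L * ((max_end - cds_start) %/% 3L)
      cds_rows[[length(cds_rows) + 1L]] <- tibble(
        transcript_id = tx_id, cds_start = cds_start, cds_end = cds_end,
        frame = 0L)
      codon_start <- cds_start + 3L * ((snp_tx - cds_start) %/% 3L)
      codon <- substr(tx, codon_start + 1L, codon_start + 3L)
      pos_in <- snp_tx - codon_start
      codon_ref <- codon
      substr(codon_ref, pos_in + 1L, pos_in + 1L) <- a1_tx
      codon_alt <- codon
      substr(codon_alt, pos_in + 1L, pos_in + 1L) <- a2_tx
      aa_ref <- unname(Biostrings::GENETIC_CODE[codon_ref])
      aa_alt <- unname(Biostrings::GENETIC_CODE[codon_alt])
      effect <- if (aa_ref == aa_alt) "synonymous" else "non_synonymous"
    } else {
      codon_ref <- codon_alt <- aa_ref <- aa_alt <- NA_character_
      effect <- "non_coding"
    }
    eff_rows[[i]] <- tibble(
      locus_id = li$locus_id, transcript_id = tx_id, strand = strand,
      tx_offset = flank, snp_tx_pos = snp_tx, in_cds = coding[i],
      effect = effect, codon_ref = codon_ref, codon_alt = codon_alt,
      aa_ref = aa_ref, aa_alt = aa_alt)
  }
  if (n_decoys > 0) {
    tx_rows[[length(tx_rows) + 1L]] <- tibble(
      transcript_id = sprintf("DECOY%03d", seq_len(n_decoys)),
      sequence = random_dna(n_decoys, 2 * flank + TAG_LENGTH))
  }
  list(transcripts = bind_rows(tx_rows),
       cds = bind_rows(cds_rows),
       effects = bind_rows(eff_rows))
}

#' Run the whole synthetic experiment
#'
#' Convenience wrapper seeding the RNG once from `config$seed` and chaining
#' [make_barcode_set()], [generate_reference_fragments()],
#' [plant_variants()], [simulate_rad_reads()] and (optionally)
#' [generate_toy_transcriptome()].
#'
#' @param config A [sim_config()].
#' @param transcriptome Logical; also build the toy transcriptome?
#' @param ... Passed on to [generate_toy_transcriptome()].
#' @return A list of class `rad_sim` with elements `config`, `barcodes`,
#'   `fragments`, `truth`, `reads` and optionally `transcriptome`.
#' @export
simulate_rad_experiment <- function(config = sim_config(),
                                    transcriptome = FALSE, ...) {
  validate_sim_config(config)
  set.seed(config$seed)
  acc <- config$accessions
  bcs <- make_barcode_set(nrow(acc), config$barcode_lengths)
  barcodes <- tibble(accession = acc$accession, barcode = bcs)
  fragments <- generate_reference_fragments(config)
  truth <- plant_variants(fragments, config)
  copy_number <- fragments |>
    dplyr::distinct(.data$family_id, .data$n_copies)
  attr(truth, "copy_number") <- setNames(copy_number$n_copies,
                                         copy_number$family_id)
  reads <- simulate_rad_reads(truth, barcodes, config)
  out <- list(config = config, barcodes = barcodes, fragments = fragments,
              truth = truth, reads = reads)
  if (transcriptome) {
    out$transcriptome <- generate_toy_transcriptome(truth, ...)
  }
  structure(out, class = "rad_sim")
}
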