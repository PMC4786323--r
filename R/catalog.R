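# Cross-accession catalog: locus matching, bi-allelic SNP selection, and the
# genotype matrix container used by all downstream population-genetic code.

#' Match loci across accessions into a catalog
#'
#' Pools per-accession loci, visits them in decreasing depth order, and groups
#' loci whose consensus lies within `max_mismatch` of a catalog seed
#' consensus (the seed being the deepest locus of the entry). Each accession
#' contributes at most one locus per entry; shallower same-accession
#' candidates are logged as paralog conflicts rather than silently dropped.
#'
#' @param loci Tibble from [merge_stacks_to_loci()] (all accessions).
#' @param max_mismatch Maximum consensus mismatches against the entry seed.
#' @return List with `catalog` (tibble `catalog_id`, `consensus`, `n_members`,
#'   `members` list-column of `accession`, `locus_id`, `consensus`, `depth`)
#'   and `conflicts` (same columns plus `catalog_id`).
#' @export
match_loci_across_accessions <- function(loci, max_mismatch = 1L) {
  if (nrow(loci) == 0) {
    return(list(catalog = tibble(catalog_id = character(0),
                                 consensus = character(0),
                                 n_members = integer(0), members = list()),
                conflicts = tibble()))
  }
  pool <- loci[order(-loci$depth, loci$consensus), ]
  cl <- cluster_by_mismatch(pool$consensus, pool$depth, max_mismatch)
  entries <- vector("list", max(cl))
  conflicts <- list()
  for (ci in unique(cl)) {
    m <- pool[cl == ci, c("accession", "locus_id", "consensus", "depth")]
    dup <- duplicated(m$accession)  # depth-sorted: first per accession wins
    if (any(dup)) {
      conflicts[[length(conflicts) + 1L]] <-
        mutate(m[dup, , drop = FALSE], catalog_id = sprintf("CAT%05d", ci))
      m <- m[!dup, , drop = FALSE]
    }
    entries[[ci]] <- tibble(
      catalog_id = sprintf("CAT%05d", ci),
      consensus = m$consensus[1],  # seed = deepest member
      n_members = nrow(m),
      members = list(m)
    )
  }
  list(catalog = bind_rows(entries), conflicts = bind_rows(conflicts))
}

#' Select single-bi-allelic-SNP catalog loci into a genotype matrix
#'
#' Applies the catalog filters: a locus is kept iff (a) it is genotyped in at
#' least `min_accessions` accessions, (b) exactly one variant site segregates
#' across members and within-member heterozygous calls, (c) exactly two
#' alleles are observed at that site, and (d) the site lies inside the 36-nt
#' variable region (tag positions 5-40). Member genotypes at the SNP come
#' from the member consensus (homozygous) or the member's heterozygous site
#' call; members whose site call at the SNP was discarded or underpowered are
#' treated as missing there. Monomorphic entries are tallied separately.
#'
#' @param matched Result of [match_loci_across_accessions()].
#' @param site_calls Tibble from [call_locus_genotypes()].
#' @param accessions Character vector of all accession names (defines matrix
#'   columns; defaults to those observed).
#' @param min_accessions Minimum non-missing accessions per kept locus.
#' @return A [rad_genotypes] object, with attributes `n_monomorphic` and
#'   `n_filtered` recording the side tallies.
#' @export
select_biallelic_snp_loci <- function(matched, site_calls,
                                      accessions = NULL,
                                      min_accessions = 14L) {
  catalog <- matched$catalog
  if (is.null(accessions)) {
    accessions <- sort(unique(unlist(lapply(catalog$members,
                                            function(m) m$accession))))
  }
  n_acc <- length(accessions)
  calls_key <- split(
    site_calls,
    paste(site_calls$accession, site_calls$locus_id, sep = "\r"))
  kept <- list()
  n_mono <- 0L
  n_filtered <- 0L
  for (i in seq_len(nrow(catalog))) {
    mem <- catalog$members[[i]]
    mem_calls <- lapply(seq_len(nrow(mem)), function(j) {
      calls_key[[paste(mem$accession[j], mem$locus_id[j], sep = "\r")]]
    })
    het_pos <- unlist(lapply(mem_calls, function(cc) {
      if (is.null(cc)) integer(0) else cc$pos[cc$status == "heterozygous"]
    }))
    cons_mat <- do.call(rbind, strsplit(mem$consensus, ""))
    cons_var <- which(apply(cons_mat, 2, function(col)
      length(unique(col)) > 1L)) - 1L
    var_pos <- sort(unique(c(cons_var, het_pos)))
    if (length(var_pos) == 0L) { n_mono <- n_mono + 1L; next }
    if (length(var_pos) != 1L ||
        !(var_pos %in% VARIABLE_REGION)) { n_filtered <- n_filtered + 1L; next }
    p <- var_pos
    # per-member genotype at the SNP position
    geno <- vector("list", nrow(mem))
    for (j in seq_len(nrow(mem))) {
      cc <- mem_calls[[j]]
      at_p <- if (is.null(cc)) NULL else cc[cc$pos == p, , drop = FALSE]
      if (is.null(at_p) || nrow(at_p) == 0L) {
        geno[[j]] <- rep(cons_mat[j, p + 1L], 2L)  # invariant within member
      } else if (at_p$status == "heterozygous") {
        geno[[j]] <- c(at_p$a1, at_p$a2)
      } else if (at_p$status == "homozygous") {
        geno[[j]] <- rep(at_p$a1, 2L)
      } else {
        geno[[j]] <- NULL  # ambiguous / insufficient: missing member
      }
    }
    present <- !vapply(geno, is.null, logical(1))
    if (sum(present) < min_accessions) { n_filtered <- n_filtered + 1L; next }
    alleles <- sort(unique(unlist(geno[present])))
    if (length(alleles) == 1L) { n_mono <- n_mono + 1L; next }
    if (length(alleles) != 2L) { n_filtered <- n_filtered + 1L; next }
    ref <- substr(catalog$consensus[i], p + 1L, p + 1L)
    if (!ref %in% alleles) { n_filtered <- n_filtered + 1L; next }
    alt <- setdiff(alleles, ref)
    dos <- rep(NA_real_, n_acc)
    ai <- match(mem$accession, accessions)
    for (j in which(present)) {
      dos[ai[j]] <- sum(geno[[j]] == alt) / 2
    }
    kept[[length(kept) + 1L]] <- list(
      locus = tibble(locus_id = catalog$catalog_id[i],
                     consensus = catalog$consensus[i],
                     snp_pos = p, a1 = ref, a2 = alt),
      dosage = dos)
  }
  loci <- if (length(kept)) {
    bind_rows(lapply(kept, `[[`, "locus"))
  } else {
    tibble(locus_id = character(0), consensus = character(0),
           snp_pos = integer(0), a1 = character(0), a2 = character(0))
  }
  dosage <- if (length(kept)) {
    do.call(rbind, lapply(kept, `[[`, "dosage"))
  } else {
    matrix(numeric(0), 0, n_acc)
  }
  dimnames(dosage) <- list(loci$locus_id, accessions)
  gm <- new_rad_genotypes(dosage, loci,
                          tibble(accession = accessions,
                                 group = NA_character_))
  attr(gm, "n_monomorphic") <- n_mono
  attr(gm, "n_filtered") <- n_filtered
  gm
}

# ---- genotype matrix container ------------------------------------------

new_rad_genotypes <- function(dosage, loci, accessions) {
  stopifnot(nrow(dosage) == nrow(loci),
            ncol(dosage) == nrow(accessions))
  structure(list(dosage = dosage, loci = loci, accessions = accessions),
            class = "rad_genotypes")
}

#' Build a genotype matrix from explicit calls
#'
#' Entry point for constructing a [rad_genotypes] object directly from
#' per-accession genotype strings, e.g. worked examples or external data.
#' Each locus must be bi-allelic across the supplied calls.
#'
#' @param calls Long tibble with columns `locus_id`, `accession`, `genotype`;
#'   genotypes are two-letter strings such as `"AA"`, `"AT"` or `"A/T"`, with
#'   `NA` for missing.
#' @param groups Optional tibble (`accession`, `group`) or named character
#'   vector of group labels.
#' @return A `rad_genotypes` object.
#' @export
rad_genotypes <- function(calls, groups = NULL) {
  calls <- as_tibble(calls)
  g <- gsub("/", "", calls$genotype)
  bad <- !is.na(g) & nchar(g) != 2L
  if (any(bad)) abort("genotypes must be two-letter strings like 'AA' or 'A/T'")
  accessions <- unique(calls$accession)
  locus_ids <- unique(calls$locus_id)
  loci <- vector("list", length(locus_ids))
  dosage <- matrix(NA_real_, length(locus_ids), length(accessions),
                   dimnames = list(locus_ids, accessions))
  for (k in seq_along(locus_ids)) {
    sel <- calls$locus_id == locus_ids[k] & !is.na(g)
    al <- c(substr(g[sel], 1, 1), substr(g[sel], 2, 2))
    tab <- sort(table(al), decreasing = TRUE)
    if (length(tab) > 2L) {
      abort(sprintf("locus %s has more than two alleles", locus_ids[k]))
    }
    a1 <- names(tab)[1]
    a2 <- if (length(tab) == 2L) names(tab)[2] else NA_character_
    loci[[k]] <- tibble(locus_id = locus_ids[k], consensus = NA_character_,
                        snp_pos = NA_integer_, a1 = a1, a2 = a2)
    idx <- match(calls$accession[sel], accessions)
    dosage[k, idx] <- (as.integer(substr(g[sel], 1, 1) != a1) +
                         as.integer(substr(g[sel], 2, 2) != a1)) / 2
  }
  gm <- new_rad_genotypes(dosage, bind_rows(loci),
                          tibble(accession = accessions,
                                 group = NA_character_))
  if (!is.null(groups)) gm <- set_groups(gm, groups)
  gm
}

#' Attach group labels to a genotype matrix
#'
#' @param gm A [rad_genotypes] object.
#' @param groups Tibble (`accession`, `group`) or named character vector.
#' @return The updated object.
#' @export
set_groups <- function(gm, groups) {
  if (is.character(groups) && !is.null(names(groups))) {
    groups <- tibble(accession = names(groups), group = unname(groups))
  }
  idx <- match(gm$accessions$accession, groups$accession)
  gm$accessions$group <- groups$group[idx]
  gm
}

#' @export
dim.rad_genotypes <- function(x) dim(x$dosage)

#' @export
print.rad_genotypes <- function(x, ...) {
  cat(sprintf("<rad_genotypes> %d loci x %d accessions (%.1f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' Tidy a genotype matrix into long form
#'
#' @param x A [rad_genotypes] object.
#' @param ... Unused.
#' @return Tibble with `locus_id`, `accession`, `group`, `dosage` (0 =
#'   homozygous reference allele, 0.5 = heterozygous, 1 = homozygous
#'   alternate) and `genotype` strings.
#' @export
tidy.rad_genotypes <- function(x, ...) {
  long <- as_tibble(as.data.frame.table(x$dosage, stringsAsFactors = FALSE))
  names(long) <- c("locus_id", "accession", "dosage")
  long <- long |>
    left_join(select(x$loci, "locus_id", "a1", "a2"), by = "locus_id") |>
    left_join(x$accessions, by = "accession")
  long$genotype <- dplyr::case_when(
    is.na(long$dosage) ~ NA_character_,
    long$dosage == 0 ~ paste0(long$a1, "/", long$a1),
    long$dosage == 1 ~ paste0(long$a2, "/", long$a2),
    .default = paste0(long$a1, "/", long$a2)
  )
  select(long, "locus_id", "accession", "group", "dosage", "genotype")
}

#' @export
glance.rad_genotypes <- function(x, ...) {
  tibble(n_loci = nrow(x$dosage), n_accessions = ncol(x$dosage),
         missing_fraction = mean(is.na(x$dosage)),
         het_fraction = mean(x$dosage == 0.5, na.rm = TRUE))
}

# ---- substitution typing and summaries ----------------------------------

#' Classify an allele pair as transition or transversion
#'
#' Purine/purine (`A/G`) and pyrimidine/pyrimidine (`C/T`) pairs are
#' transitions; the four purine/pyrimidine pairs are transversions.
#'
#' @param a1,a2 Character vectors of single bases; pairs must be distinct.
#' @return Character vector, `"transition"` or `"transversion"`.
#' @export
classify_substitution <- function(a1, a2) {
  if (any(a1 == a2, na.rm = TRUE)) {
    abort("allele pairs must contain two distinct bases")
  }
  pair <- paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
  ifelse(pair %in% c("C/T", "A/G"), "transition", "transversion")
}

#' Summarise a SNP catalog
#'
#' Counts loci per (unordered) allele pair, transitions and transversions,
#' the TI/TV ratio, and per-accession genotyping completeness and
#' heterozygous-call counts.
#'
#' @param gm A [rad_genotypes] object.
#' @return A list of class `rad_snp_summary` with elements `stats` (one-row
#'   tibble), `spectrum` (per allele pair) and `per_accession`. The TI/TV
#'   ratio is `NA` when no transversions are present.
#' @export
summarize_snps <- function(gm) {
  if (nrow(gm$loci) == 0) abort("genotype matrix is empty")
  type <- classify_substitution(gm$loci$a1, gm$loci$a2)
  ti <- sum(type == "transition")
  tv <- sum(type == "transversion")
  pair <- paste(pmin(gm$loci$a1, gm$loci$a2),
                pmax(gm$loci$a1, gm$loci$a2), sep = "/")
  spectrum <- tibble(pair = pair) |>
    count(.data$pair, name = "n") |>
    mutate(fraction = .data$n / sum(.data$n),
           type = classify_substitution(substr(.data$pair, 1, 1),
                                        substr(.data$pair, 3, 3))) |>
    arrange(dplyr::desc(.data$n))
  per_acc <- tibble(
    accession = colnames(gm$dosage),
    n_genotyped = unname(colSums(!is.na(gm$dosage))),
    n_het = unname(colSums(gm$dosage == 0.5, na.rm = TRUE))
  )
  stats <- tibble(
    n_loci = nrow(gm$loci),
    n_transitions = ti,
    n_transversions = tv,
    ti_tv = if (tv > 0) ti / tv else NA_real_,
    pct_transitions = 100 * ti / (ti + tv),
    rad_genome_mb = nrow(gm$loci) * TAG_LENGTH / 1e6
  )
  structure(list(stats = stats, spectrum = spectrum,
                 per_accession = per_acc),
            class = "rad_snp_summary")
}

#' @export
print.rad_snp_summary <- function(x, ...) {
  s <- x$stats
  cat(sprintf(
    "%d bi-allelic SNP loci: %d transitions, %d transversions (TI/TV %s)\n",
    s$n_loci, s$n_transitions, s$n_transversions,
    ifelse(is.na(s$ti_tv), "undefined", sprintf("%.2f", s$ti_tv))))
  print(x$spectrum)
  invisible(x)
}

#' @export
glance.rad_snp_summary <- function(x, ...) x$stats
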