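# Stack assembly, depth filtering, locus merging and depth-ratio genotyping.

#' Cluster identical tags into stacks
#'
#' Within each accession, identical 41-nt tags collapse into one stack whose
#' depth is the number of supporting reads. Stack depths always sum to the
#' input tag count.
#'
#' @param tags Tibble with `accession`, `sequence` (uniform 41 nt).
#' @return Tibble with `accession`, `sequence`, `depth`.
#' @export
build_stacks <- function(tags) {
  if (nrow(tags) == 0) {
    return(tibble(accession = character(0), sequence = character(0),
                  depth = integer(0)))
  }
  if (any(nchar(tags$sequence) != TAG_LENGTH)) {
    abort(sprintf("tags must be uniform %d nt", TAG_LENGTH))
  }
  tags |>
    count(.data$accession, .data$sequence, name = "depth") |>
    arrange(.data$accession, dplyr::desc(.data$depth), .data$sequence)
}

#' Filter stacks by depth
#'
#' Retains stacks with `min_depth <= depth <= max_depth`. Shallow stacks are
#' mostly sequencing-error singletons (`reason = "low"`); very deep stacks
#' come from repetitive genomic sequence (`reason = "repetitive"`).
#'
#' @param stacks Tibble from [build_stacks()].
#' @param min_depth Minimum retained depth (inclusive).
#' @param max_depth Maximum retained depth (inclusive).
#' @return List with `retained` and `discarded` (with a `reason` column).
#' @export
filter_stacks <- function(stacks, min_depth = 10L, max_depth = 300L) {
  low <- stacks$depth < min_depth
  high <- stacks$depth > max_depth
  discarded <- stacks[low | high, , drop = FALSE]
  discarded$reason <- ifelse(discarded$depth < min_depth, "low", "repetitive")
  list(retained = stacks[!low & !high, , drop = FALSE], discarded = discarded)
}

#' Merge stacks into RAD tag loci
#'
#' Within each accession, stacks are visited in decreasing depth order; each
#' stack joins the deepest existing locus whose seed (deepest) stack is within
#' `max_mismatch` of it, or founds a new locus (star linkage from the seed,
#' not transitive chaining). The locus consensus is the deepest base per
#' site; per-site depth tables accumulate over members, so site depths always
#' sum to the total member depth.
#'
#' Stacks below the depth floor cannot found a locus, but discarding their
#' reads outright would silently turn heterozygous sites into homozygous
#' calls whenever one haplotype's stack dips under the floor. Passing the
#' low-depth stacks as `secondary` re-attaches each one to the deepest
#' established locus whose seed lies within `max_mismatch` (mirroring the
#' secondary-read rescue of de novo RAD assemblers); unmatched secondary
#' stacks are dropped, and repetitive-depth stacks must not be supplied.
#' Secondary stacks shallower than `min_secondary_depth` are ignored: a
#' depth-1 or depth-2 stack is indistinguishable from one or two repeated
#' sequencing errors, and re-attaching such stacks lets coincident errors
#' masquerade as minor alleles at marginal-depth sites, whereas a genuine
#' minor haplotype that shallow is vanishingly rare above the site depth
#' threshold.
#'
#' @param stacks Retained stacks tibble (`accession`, `sequence`, `depth`).
#' @param max_mismatch Maximum mismatches between a member and the locus seed.
#' @param secondary Optional tibble of below-floor stacks to re-attach.
#' @param min_secondary_depth Minimum depth for a secondary stack to be
#'   eligible for rescue.
#' @return Tibble with one row per locus: `accession`, `locus_id`,
#'   `consensus`, `depth`, `n_stacks`, and a `members` list-column of
#'   per-member tibbles (`sequence`, `depth`).
#' @export
merge_stacks_to_loci <- function(stacks, max_mismatch = 1L,
                                 secondary = NULL,
                                 min_secondary_depth = 3L) {
  if (!is.null(secondary)) {
    secondary <- secondary[secondary$depth >= min_secondary_depth, ,
                           drop = FALSE]
  }
  if (nrow(stacks) == 0) {
    return(tibble(accession = character(0), locus_id = character(0),
                  consensus = character(0), depth = integer(0),
                  n_stacks = integer(0), members = list()))
  }
  sec_split <- if (!is.null(secondary) && nrow(secondary)) {
    split(secondary, secondary$accession)
  } else {
    list()
  }
  out <- lapply(split(stacks, stacks$accession), function(st) {
    st <- st[order(-st$depth, st$sequence), ]
    cl <- cluster_by_mismatch(st$sequence, st$depth, max_mismatch)
    sec <- sec_split[[st$accession[1]]]
    sec_cl <- integer(0)
    if (!is.null(sec) && nrow(sec)) {
      seed_rows <- which(!duplicated(cl))  # first (deepest) member per locus
      seed_seqs <- st$sequence[seed_rows]
      locus_depth <- tapply(st$depth, cl, sum)
      k <- max_mismatch + 1L
      idx <- new.env(parent = emptyenv())
      seed_pieces <- seq_pieces(seed_seqs, k)
      for (s in seq_along(seed_seqs)) {
        for (p in seq_len(k)) {
          key <- paste0(p, ":", seed_pieces[[p]][s])
          idx[[key]] <- c(idx[[key]], s)
        }
      }
      sec_pieces <- seq_pieces(sec$sequence, k)
      sec_cl <- vapply(seq_len(nrow(sec)), function(i) {
        cand <- unique(unlist(lapply(seq_len(k), function(p) {
          idx[[paste0(p, ":", sec_pieces[[p]][i])]]
        })))
        if (is.null(cand)) return(0L)
        ok <- cand[vapply(cand, function(s) {
          hamming(seed_seqs[s], sec$sequence[i]) <= max_mismatch
        }, logical(1))]
        if (!length(ok)) return(0L)
        cid <- cl[seed_rows[ok]]
        cid[which.max(locus_depth[as.character(cid)])]
      }, integer(1))
    }
    n_loci <- max(cl)
    all_seq <- c(st$sequence, if (length(sec_cl)) sec$sequence)
    all_dep <- c(st$depth, if (length(sec_cl)) sec$depth)
    all_cl <- c(cl, sec_cl)
    keep <- all_cl > 0L
    sp <- split(which(keep), factor(all_cl[keep], levels = seq_len(n_loci)))
    members <- lapply(sp, function(ix) {
      tibble(sequence = all_seq[ix], depth = all_dep[ix])
    })
    consensus <- vapply(sp, function(ix) {
      if (length(ix) == 1L) all_seq[ix]
      else consensus_from_depths(site_depth_table(all_seq[ix], all_dep[ix]))
    }, character(1))
    tibble(accession = st$accession[1],
           consensus = unname(consensus),
           depth = vapply(sp, function(ix) sum(all_dep[ix]), numeric(1),
                          USE.NAMES = FALSE),
           n_stacks = lengths(sp, use.names = FALSE),
           members = unname(members))
  })
  loci <- bind_rows(out)
  loci <- loci |>
    group_by(.data$accession) |>
    mutate(locus_id = sprintf("%s_%04d", .data$accession,
                              dplyr::row_number())) |>
    ungroup() |>
    select("accession", "locus_id", "consensus", "depth", "n_stacks",
           "members")
  loci
}

#' Depth-ratio genotype call for one site
#'
#' Implements the hard-threshold rule used throughout the pipeline. With A1
#' and A2 the most and second-most frequent alleles at a site and their
#' depths `depth_a1 >= depth_a2`:
#' * total depth below `min_total`: `insufficient_depth`;
#' * no second allele, or `depth_a2 / depth_a1 < hom_ratio`: `homozygous`;
#' * `depth_a2 / depth_a1 > het_ratio`: `heterozygous`;
#' * ratio inside the closed band `[hom_ratio, het_ratio]`:
#'   `discarded_ambiguous`.
#'
#' @param depth_a1,depth_a2 Non-negative depth vectors, `depth_a1 >= depth_a2`.
#' @param min_total Minimum total depth for a call.
#' @param hom_ratio,het_ratio Ratio thresholds (defaults 0.05 and 0.1).
#' @return Character vector of statuses.
#' @export
call_site_genotype <- function(depth_a1, depth_a2, min_total = 10L,
                               hom_ratio = 0.05, het_ratio = 0.1) {
  if (any(depth_a1 < 0 | depth_a2 < 0)) abort("depths must be non-negative")
  if (any(depth_a2 > depth_a1)) abort("depth_a1 must be >= depth_a2")
  total <- depth_a1 + depth_a2
  ratio <- ifelse(depth_a1 > 0, depth_a2 / depth_a1, 0)
  dplyr::case_when(
    total < min_total ~ "insufficient_depth",
    depth_a2 == 0 ~ "homozygous",
    ratio < hom_ratio ~ "homozygous",
    ratio > het_ratio ~ "heterozygous",
    .default = "discarded_ambiguous"
  )
}

#' Call per-site genotypes for merged loci
#'
#' For every site at which a locus's member stacks disagree, ranks the
#' observed bases by depth (ties broken alphabetically), applies
#' [call_site_genotype()] to the top two, and discards sites whose third
#' allele is too deep to be sequencing error
#' (`depth_a3 / depth_a1 > het_ratio`) as non-bi-allelic. Sites at which all
#' members agree are homozygous for the consensus base (their depth is the
#' locus depth, which already passed the stack depth filter).
#'
#' @param loci Tibble from [merge_stacks_to_loci()].
#' @inheritParams call_site_genotype
#' @return Tibble of variable-site calls: `accession`, `locus_id`, `pos`
#'   (0-based), `status`, `a1`, `a2`, `depth_a1`, `depth_a2`.
#' @export
call_locus_genotypes <- function(loci, min_total = 10L, hom_ratio = 0.05,
                                 het_ratio = 0.1) {
  empty <- tibble(accession = character(0), locus_id = character(0),
                  pos = integer(0), status = character(0),
                  a1 = character(0), a2 = character(0),
                  depth_a1 = numeric(0), depth_a2 = numeric(0))
  multi <- loci[loci$n_stacks > 1L, , drop = FALSE]
  if (nrow(multi) == 0) return(empty)
  acc_v <- loc_v <- status_v <- a1_v <- a2_v <- list()
  pos_v <- d1_v <- d2_v <- list()
  k <- 0L
  for (i in seq_len(nrow(multi))) {
    m <- multi$members[[i]]
    cons_raw <- charToRaw(multi$consensus[i])
    raws <- lapply(m$sequence, charToRaw)
    var_pos <- sort(unique(unlist(
      lapply(raws, function(r) which(r != cons_raw)))))
    if (!length(var_pos)) next
    np <- length(var_pos)
    pos0 <- a1s <- a2s <- statuses <- d1s <- d2s <- vector("list", np)
    for (q in seq_len(np)) {
      p <- var_pos[q]
      bases <- substring(m$sequence, p, p)
      d <- vapply(DNA_BASES, function(b) sum(m$depth[bases == b]),
                  numeric(1))
      ord <- order(-d)  # stable: ties resolve alphabetically
      d1 <- d[ord[1]]; d2 <- d[ord[2]]; d3 <- d[ord[3]]
      status <- call_site_genotype(d1, d2, min_total, hom_ratio, het_ratio)
      if (d1 > 0 && d3 / d1 > het_ratio) status <- "discarded_ambiguous"
      pos0[[q]] <- p - 1L
      statuses[[q]] <- status
      a1s[[q]] <- DNA_BASES[ord[1]]
      a2s[[q]] <- if (d2 > 0) DNA_BASES[ord[2]] else NA_character_
      d1s[[q]] <- unname(d1); d2s[[q]] <- unname(d2)
    }
    k <- k + 1L
    acc_v[[k]] <- rep(multi$accession[i], np)
    loc_v[[k]] <- rep(multi$locus_id[i], np)
    pos_v[[k]] <- unlist(pos0)
    status_v[[k]] <- unlist(statuses)
    a1_v[[k]] <- unlist(a1s)
    a2_v[[k]] <- unlist(a2s)
    d1_v[[k]] <- unlist(d1s)
    d2_v[[k]] <- unlist(d2s)
  }
  if (k == 0L) return(empty)
  tibble(accession = unlist(acc_v), locus_id = unlist(loc_v),
         pos = unlist(pos_v), status = unlist(status_v),
         a1 = unlist(a1_v), a2 = unlist(a2_v),
         depth_a1 = unlist(d1_v), depth_a2 = unlist(d2_v))
}
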