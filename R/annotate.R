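# Tag-to-transcript matching and synonymous / non-synonymous classification.

# All coordinates are 0-based, half-open. An alignment places the 36-nt
# variable region of a tag (tag positions 5-40) on a transcript, possibly
# reverse-complemented, with at most `max_mismatch` substitutions and no
# gaps; partial overlaps hanging off a transcript end are allowed down to
# `min_coverage` of the region.

# scan one region (plus strand already materialised) against one transcript;
# returns tibble of candidate placements
scan_region <- function(region, tx, max_mismatch, min_overlap, min_identity) {
  rl <- nchar(region)
  tl <- nchar(tx)
  if (tl < min_overlap) {
    return(NULL)
  }
  rows <- list()
  # offset = transcript position of region position 0 (may be negative or
  # run past the end for hanging alignments)
  for (off in seq(min_overlap - rl, tl - min_overlap)) {
    r_from <- max(0L, -off)
    r_to <- min(rl, tl - off)  # region positions [r_from, r_to)
    ov <- r_to - r_from
    a <- substr(region, r_from + 1L, r_to)
    b <- substr(tx, off + r_from + 1L, off + r_to)
    mm <- hamming(a, b)
    if (mm <= max_mismatch && (ov - mm) / ov > min_identity) {
      rows[[length(rows) + 1L]] <- tibble(
        tx_start = off + r_from, r_from = r_from, r_to = r_to,
        mismatches = mm, overlap = ov)
    }
  }
  if (length(rows)) bind_rows(rows) else NULL
}

#' Map SNP-bearing tags onto a transcript set
#'
#' Deterministic ungapped scan of the 36-nt variable region of each tag
#' against both strands of every transcript. An alignment is reported when it
#' has at most `max_mismatch` substitutions, covers at least `min_coverage`
#' of the region and exceeds `min_identity` identity. Among candidates the
#' single best alignment is kept (fewest mismatches, then longest overlap,
#' then transcript id and leftmost position); runners-up are returned as
#' secondary hits.
#'
#' @param tags Tibble with `locus_id` and `consensus` (41-nt tag) columns, as
#'   in a [rad_genotypes] `$loci` table.
#' @param transcripts Tibble with `transcript_id`, `sequence`, or a path to a
#'   FASTA file.
#' @param max_mismatch Maximum substitutions in the alignment.
#' @param min_coverage Minimum aligned fraction of the variable region.
#' @param min_identity Minimum (strict) identity over the aligned part.
#' @return List with `alignments` (tibble `locus_id`, `transcript_id`,
#'   `strand`, `tx_start`, `region_from`, `region_to`, `mismatches`,
#'   `overlap`; unmapped tags absent) and `secondary` (tied or inferior
#'   candidate placements for mapped tags).
#' @export
map_tag_to_transcripts <- function(tags, transcripts, max_mismatch = 1L,
                                   min_coverage = 0.8, min_identity = 0.9) {
  if (is.character(transcripts) && length(transcripts) == 1) {
    x <- Biostrings::readDNAStringSet(transcripts)
    transcripts <- tibble(transcript_id = names(x), sequence = as.character(x))
  }
  if (nrow(transcripts) == 0) abort("transcript set is empty")
  transcripts <- arrange(transcripts, .data$transcript_id)
  region_len <- TAG_LENGTH - 5L
  min_overlap <- as.integer(ceiling(min_coverage * region_len))
  best_rows <- list()
  sec_rows <- list()
  for (t in seq_len(nrow(tags))) {
    region <- substr(tags$consensus[t], 6L, TAG_LENGTH)
    cands <- list()
    for (strand in c("+", "-")) {
      qry <- if (strand == "+") region else revcomp(region)
      # seed prefilter: any reported alignment covers >= 2 complete 9-mer
      # blocks of the query, and <= 1 mismatch leaves >= 1 block exact, so
      # candidate transcripts must contain one of the four blocks verbatim
      if (max_mismatch <= 1L && min_overlap >= 29L) {
        blocks <- unique(substring(qry, c(1, 10, 19, 28), c(9, 18, 27, 36)))
        hit_tx <- rep(FALSE, nrow(transcripts))
        for (bl in blocks) {
          hit_tx <- hit_tx | stringr::str_detect(transcripts$sequence,
                                                 stringr::fixed(bl))
        }
      } else {
        hit_tx <- rep(TRUE, nrow(transcripts))
      }
      for (x in which(hit_tx)) {
        hits <- scan_region(qry, transcripts$sequence[x], max_mismatch,
                            min_overlap, min_identity)
        if (!is.null(hits)) {
          hits$transcript_id <- transcripts$transcript_id[x]
          hits$strand <- strand
          cands[[length(cands) + 1L]] <- hits
        }
      }
    }
    if (!length(cands)) next
    cands <- bind_rows(cands)
    # on the minus strand the scan coordinates index the reverse-complemented
    # region; convert to original region coordinates
    flip <- cands$strand == "-"
    rf <- cands$r_from; rt <- cands$r_to
    cands$region_from <- ifelse(flip, region_len - rt, rf)
    cands$region_to <- ifelse(flip, region_len - rf, rt)
    ord <- order(cands$mismatches, -cands$overlap, cands$transcript_id,
                 cands$tx_start)
    cands <- cands[ord, ]
    best <- cands[1, ]
    best_rows[[length(best_rows) + 1L]] <- tibble(
      locus_id = tags$locus_id[t],
      transcript_id = best$transcript_id, strand = best$strand,
      tx_start = best$tx_start,
      region_from = best$region_from, region_to = best$region_to,
      mismatches = best$mismatches, overlap = best$overlap)
    if (nrow(cands) > 1) {
      extra <- cands[-1, ]
      extra$locus_id <- tags$locus_id[t]
      sec_rows[[length(sec_rows) + 1L]] <-
        select(extra, "locus_id", "transcript_id", "strand", "tx_start",
               "region_from", "region_to", "mismatches", "overlap")
    }
  }
  list(alignments = bind_rows(best_rows), secondary = bind_rows(sec_rows))
}

#' Classify SNP coding effects
#'
#' Maps each aligned SNP into transcript coordinates, locates its codon from
#' the CDS interval and frame, substitutes the two alleles, and translates
#' with the standard genetic code. SNPs outside every CDS (or whose codon is
#' truncated) are `non_coding`; unaligned loci are `unmapped`. Alleles are
#' complemented for minus-strand alignments, so classification is
#' strand-consistent.
#'
#' @param alignments Tibble from [map_tag_to_transcripts()] (`$alignments`).
#' @param loci Tibble with `locus_id`, `snp_pos` (0-based tag position) and
#'   alleles `a1`, `a2`, as in a [rad_genotypes] `$loci` table.
#' @param cds Tibble with `transcript_id`, `cds_start`, `cds_end` (0-based,
#'   half-open), `frame`. A CDS whose in-frame length is not a multiple of 3
#'   is an error naming the transcript.
#' @param transcripts Tibble with `transcript_id`, `sequence`.
#' @return Tibble with `locus_id`, `effect` (`synonymous`, `non_synonymous`,
#'   `non_coding`, `unmapped`), `transcript_id`, `codon_ref`, `codon_alt`,
#'   `aa_ref`, `aa_alt`.
#' @export
classify_coding_effect <- function(alignments, loci, cds, transcripts) {
  tx_of <- setNames(transcripts$sequence, transcripts$transcript_id)
  if (nrow(cds)) {
    bad <- (cds$cds_end - cds$cds_start - cds$frame) %% 3L != 0L
    if (any(bad)) {
      abort(sprintf("CDS of transcript %s is not a codon multiple",
                    paste(cds$transcript_id[bad], collapse = ", ")))
    }
  }
  out <- vector("list", nrow(loci))
  for (i in seq_len(nrow(loci))) {
    li <- loci[i, ]
    al <- alignments[alignments$locus_id == li$locus_id, , drop = FALSE]
    blank <- tibble(locus_id = li$locus_id, effect = "unmapped",
                    transcript_id = NA_character_,
                    codon_ref = NA_character_, codon_alt = NA_character_,
                    aa_ref = NA_character_, aa_alt = NA_character_)
    if (nrow(al) == 0) { out[[i]] <- blank; next }
    al <- al[1, ]
    region_pos <- li$snp_pos - 5L  # SNP position within the variable region
    if (is.na(region_pos) || region_pos < al$region_from ||
        region_pos >= al$region_to) {
      out[[i]] <- mutate(blank, effect = "non_coding",
                         transcript_id = al$transcript_id)
      next
    }
    if (al$strand == "+") {
      tx_pos <- al$tx_start + (region_pos - al$region_from)
      a1 <- li$a1; a2 <- li$a2
    } else {
      tx_pos <- al$tx_start + (al$region_to - 1L - region_pos)
      a1 <- complement_base(li$a1); a2 <- complement_base(li$a2)
    }
    cd <- cds[cds$transcript_id == al$transcript_id, , drop = FALSE]
    eff <- mutate(blank, effect = "non_coding",
                  transcript_id = al$transcript_id)
    for (r in seq_len(nrow(cd))) {
      start <- cd$cds_start[r] + cd$frame[r]
      end <- cd$cds_end[r]
      if (tx_pos < start || tx_pos >= end) next
      codon_start <- start + 3L * ((tx_pos - start) %/% 3L)
      if (codon_start + 3L > end) next  # truncated codon
      tx <- tx_of[[al$transcript_id]]
      codon <- substr(tx, codon_start + 1L, codon_start + 3L)
      p <- tx_pos - codon_start
      codon_ref <- codon; substr(codon_ref, p + 1L, p + 1L) <- a1
      codon_alt <- codon; substr(codon_alt, p + 1L, p + 1L) <- a2
      aa_ref <- unname(Biostrings::GENETIC_CODE[codon_ref])
      aa_alt <- unname(Biostrings::GENETIC_CODE[codon_alt])
      eff <- tibble(
        locus_id = li$locus_id,
        effect = if (aa_ref == aa_alt) "synonymous" else "non_synonymous",
        transcript_id = al$transcript_id,
        codon_ref = codon_ref, codon_alt = codon_alt,
        aa_ref = aa_ref, aa_alt = aa_alt)
      break
    }
    out[[i]] <- eff
  }
  bind_rows(out)
}

#' Summarise coding-effect calls
#'
#' @param effects Tibble from [classify_coding_effect()].
#' @return One-row tibble with counts per effect class and the dN/dS ratio
#'   (non-synonymous / synonymous counts; `NA` when no synonymous calls).
#' @export
dn_ds_summary <- function(effects) {
  if (nrow(effects) == 0) abort("no effect calls")
  n_syn <- sum(effects$effect == "synonymous")
  n_non <- sum(effects$effect == "non_synonymous")
  tibble(
    n_coding = n_syn + n_non,
    n_synonymous = n_syn,
    n_non_synonymous = n_non,
    dn_ds = if (n_syn > 0) n_non / n_syn else NA_real_,
    n_non_coding = sum(effects$effect == "non_coding"),
    n_unmapped = sum(effects$effect == "unmapped")
  )
}
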