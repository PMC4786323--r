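# Read preprocessing: quality filter, barcode demultiplexing, tag trimming.

#' Read a FASTQ file into a tibble
#'
#' @param path Path to an (uncompressed or gzipped) FASTQ file, Phred+33.
#' @return Tibble with columns `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  tibble(
    read_id = names(x),
    sequence = unname(as.character(x)),
    quality = unname(as.character(S4Vectors::mcols(x)$qualities))
  )
}

#' Write reads to a FASTQ file
#'
#' @param reads Tibble with `read_id`, `sequence`, `quality`.
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}

#' Read / write a barcode table
#'
#' Two-column tab-separated table: accession, barcode.
#' @param path File path.
#' @return Tibble with columns `accession`, `barcode`.
#' @export
read_barcodes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("accession", "barcode"),
                          colClasses = "character")
  as_tibble(df)
}

#' @rdname read_barcodes
#' @param barcodes Tibble with `accession`, `barcode`.
#' @export
write_barcodes <- function(barcodes, path) {
  write.table(barcodes[, c("accession", "barcode")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

phred_counts_le <- function(quality, q = 5L) {
  # count bases with Phred score <= q in Phred+33 strings
  hi <- intToUtf8(33L + q)
  stringr::str_count(quality, sprintf("[\\x21-%s]",
                                      gsub("([\\\\\\]])", "\\\\\\1", hi)))
}

#' Quality-filter raw reads
#'
#' Drops reads in which more than `max_low_fraction` of bases have a Phred
#' quality at or below `low_q` (strictly greater than the threshold fraction),
#' and reads containing any adapter from `adapters` as an exact substring.
#'
#' @param reads Tibble with `read_id`, `sequence`, `quality`.
#' @param low_q Phred score at or below which a base counts as low quality.
#' @param max_low_fraction Maximum tolerated fraction of low-quality bases.
#' @param adapters Character vector of adapter sequences to screen out.
#' @return List with `kept` (reads tibble) and `discards`
#'   (`read_id`, `reason` in `low_quality` / `adapter`).
#' @export
quality_filter <- function(reads, low_q = 5L, max_low_fraction = 0.5,
                           adapters = character(0)) {
  n_low <- phred_counts_le(reads$quality, low_q)
  len <- nchar(reads$sequence)
  drop_q <- n_low / len > max_low_fraction
  drop_a <- rep(FALSE, nrow(reads))
  for (ad in adapters) {
    drop_a <- drop_a | stringr::str_detect(reads$sequence,
                                           stringr::fixed(ad))
  }
  reason <- rep(NA_character_, nrow(reads))
  reason[drop_a] <- "adapter"
  reason[drop_q] <- "low_quality"
  list(
    kept = reads[is.na(reason), , drop = FALSE],
    discards = tibble(read_id = reads$read_id[!is.na(reason)],
                      reason = reason[!is.na(reason)])
  )
}

#' Demultiplex reads by inline barcode and restriction-site check
#'
#' A read is assigned to an accession iff its prefix exactly matches that
#' accession's barcode and the five bases immediately following are the EcoRI
#' remnant `AATTC`. Variable-length barcodes are resolved longest-match-first.
#' Unassigned reads are logged with a reason: `no_barcode` (no exact prefix
#' match) or `no_site` (barcode matched, remnant absent). Assignment is a
#' partition: every input read lands in exactly one bin or in the discard log.
#'
#' @param reads Tibble with `read_id`, `sequence`, `quality`.
#' @param barcodes Tibble with `accession`, `barcode`; duplicate barcodes are
#'   an error.
#' @return List with `assigned` (tibble `read_id`, `accession`, `sequence`,
#'   `quality`; barcode stripped) and `discards` (`read_id`, `reason`).
#' @export
demultiplex <- function(reads, barcodes) {
  if (nrow(barcodes) == 0) abort("barcode table is empty")
  if (anyDuplicated(barcodes$barcode)) {
    abort("duplicate barcode in barcode table")
  }
  lens <- sort(unique(nchar(barcodes$barcode)), decreasing = TRUE)
  n <- nrow(reads)
  accession <- rep(NA_character_, n)
  bc_len <- rep(NA_integer_, n)
  matched_prefix <- rep(FALSE, n)
  for (L in lens) {
    bcs <- barcodes[nchar(barcodes$barcode) == L, ]
    idx <- match(substr(reads$sequence, 1, L), bcs$barcode)
    hit <- !is.na(idx)
    matched_prefix <- matched_prefix | hit
    site_ok <- substr(reads$sequence, L + 1L, L + 5L) == ECORI_REMNANT
    take <- is.na(accession) & hit & site_ok
    accession[take] <- bcs$accession[idx[take]]
    bc_len[take] <- L
  }
  ok <- !is.na(accession)
  assigned <- tibble(
    read_id = reads$read_id[ok],
    accession = accession[ok],
    sequence = substr(reads$sequence[ok], bc_len[ok] + 1L, 1e9L),
    quality = substr(reads$quality[ok], bc_len[ok] + 1L, 1e9L)
  )
  reason <- c("no_barcode", "no_site")[matched_prefix[!ok] + 1L]
  list(assigned = assigned,
       discards = tibble(read_id = reads$read_id[!ok], reason = reason))
}

#' Trim assigned reads to uniform 41-nt RAD tags
#'
#' Keeps the first 41 nt after the barcode (5-nt EcoRI remnant + 36-nt
#' variable region); shorter reads are discarded with reason `too_short`.
#'
#' @param assigned Tibble from [demultiplex()] (`$assigned`).
#' @return List with `tags` (tibble `read_id`, `accession`, `sequence` of
#'   41 nt) and `discards`.
#' @export
trim_tag <- function(assigned) {
  long_enough <- nchar(assigned$sequence) >= TAG_LENGTH
  tags <- tibble(
    read_id = assigned$read_id[long_enough],
    accession = assigned$accession[long_enough],
    sequence = substr(assigned$sequence[long_enough], 1L, TAG_LENGTH)
  )
  list(tags = tags,
       discards = tibble(read_id = assigned$read_id[!long_enough],
                         reason = rep("too_short", sum(!long_enough))))
}

#' Preprocess raw reads end to end
#'
#' Chains [quality_filter()], [demultiplex()] and [trim_tag()], returning the
#' uniform tags and a combined discard log. The assigned-plus-discarded
#' counts always partition the input.
#'
#' @inheritParams quality_filter
#' @inheritParams demultiplex
#' @return List with `tags` and `discards` (`read_id`, `reason` in
#'   `low_quality`, `adapter`, `no_barcode`, `no_site`, `too_short`).
#' @export
preprocess_reads <- function(reads, barcodes, low_q = 5L,
                             max_low_fraction = 0.5,
                             adapters = character(0)) {
  qf <- quality_filter(reads, low_q, max_low_fraction, adapters)
  dm <- demultiplex(qf$kept, barcodes)
  tr <- trim_tag(dm$assigned)
  list(tags = tr$tags,
       discards = bind_rows(qf$discards, dm$discards, tr$discards))
}
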