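# Internal helpers shared across the pipeline.

# Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

#' Round halves away from zero
#'
#' Commercial rounding to `digits` decimals, with ties going away from zero
#' rather than to the nearest even digit as in [round()]. Used when quoting
#' statistics at a fixed printed precision (e.g. 3.5/28 = 0.125 -> 0.13).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

random_dna <- function(n, length) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, length, replace = TRUE), collapse = "")
  }, character(1))
}

complement_base <- function(x) {
  unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[x])
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Split a sequence into `k` contiguous pieces. Any pair of sequences within
# k - 1 mismatches must agree exactly on at least one piece, which makes the
# pieces usable as hash keys for near-duplicate candidate lookup.
seq_pieces <- function(x, k) {
  len <- nchar(x[1])
  bounds <- floor(seq(0, len, length.out = k + 1))
  lapply(seq_len(k), function(i) {
    substr(x, bounds[i] + 1L, bounds[i + 1L])
  })
}

# Greedy near-duplicate clustering shared by stack merging and catalog
# matching: sequences are visited in the given order (callers pass depth-sorted
# input); each sequence joins the deepest already-seen seed within
# `max_mismatch`, or founds a new seed. Returns the seed index for each input.
cluster_by_mismatch <- function(seqs, depths, max_mismatch = 1L) {
  n <- length(seqs)
  if (n == 0) return(integer(0))
  k <- max_mismatch + 1L
  pieces <- seq_pieces(seqs, k)
  buckets <- new.env(parent = emptyenv(), size = n)
  seed_of <- integer(n)
  seed_depth <- numeric(n)
  n_seeds <- 0L
  seed_idx <- integer(n)
  for (i in seq_len(n)) {
    cand <- integer(0)
    keys <- character(k)
    for (p in seq_len(k)) {
      keys[p] <- paste0(p, ":", pieces[[p]][i])
      hit <- buckets[[keys[p]]]
      if (!is.null(hit)) cand <- c(cand, hit)
    }
    cand <- unique(cand)
    best <- 0L
    if (length(cand)) {
      ok <- cand[vapply(cand, function(s) {
        hamming(seqs[seed_idx[s]], seqs[i]) <= max_mismatch
      }, logical(1))]
      if (length(ok)) best <- ok[which.max(seed_depth[ok])]
    }
    if (best > 0L) {
      seed_of[i] <- best
    } else {
      n_seeds <- n_seeds + 1L
      seed_of[i] <- n_seeds
      seed_idx[n_seeds] <- i
      seed_depth[n_seeds] <- depths[i]
      for (p in seq_len(k)) {
        buckets[[keys[p]]] <- c(buckets[[keys[p]]], n_seeds)
      }
    }
  }
  seed_of
}

# Per-site base-depth table (4 x tag length) for a set of member sequences.
site_depth_table <- function(seqs, depths) {
  len <- nchar(seqs[1])
  tab <- matrix(0, nrow = 4, ncol = len, dimnames = list(DNA_BASES, NULL))
  for (i in seq_along(seqs)) {
    b <- strsplit(seqs[i], "")[[1]]
    idx <- match(b, DNA_BASES)
    keep <- !is.na(idx)
    tab[cbind(idx[keep], which(keep))] <-
      tab[cbind(idx[keep], which(keep))] + depths[i]
  }
  tab
}

consensus_from_depths <- function(tab) {
  paste(DNA_BASES[apply(tab, 2, which.max)], collapse = "")
}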