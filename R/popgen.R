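# Population-genetic summaries on the genotype matrix: p-distances,
# neighbor-joining with bootstrap, PCA, heterozygosity, within-group
# diversity and the loss-of-diversity selection scan.

#' Pairwise genotype p-distance matrix
#'
#' For accessions i and j, the distance is the mean over loci genotyped in
#' both of a per-locus genotype distance d: 0 for identical genotypes
#' (including het vs het), 0.5 for homozygote vs heterozygote, 1 for opposite
#' homozygotes. With genotypes coded as alternate-allele dosages g in
#' {0, 0.5, 1}, d = |g_i - g_j|. `scale = "per_nt"` divides by 41 x shared
#' loci (nucleotide scaling) instead of the shared locus count; the two
#' differ by a constant factor, so tree topology is unaffected.
#'
#' @param gm A [rad_genotypes] object with at least two accessions.
#' @param scale `"per_snp"` (default, distances in \[0, 1\]) or `"per_nt"`.
#' @return A `rad_dist` object: list with `d` (symmetric matrix), `n_loci`
#'   (pairwise shared-locus counts) and `scale`.
#' @export
pairwise_distance_matrix <- function(gm, scale = c("per_snp", "per_nt")) {
  scale <- match.arg(scale)
  G <- gm$dosage
  n <- ncol(G)
  if (n < 2) abort("need at least two accessions")
  d <- matrix(0, n, n, dimnames = list(colnames(G), colnames(G)))
  L <- matrix(0L, n, n, dimnames = dimnames(d))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- !is.na(G[, i]) & !is.na(G[, j])
      lij <- sum(shared)
      if (lij == 0) {
        abort(sprintf("no shared genotyped loci for pair %s / %s",
                      colnames(G)[i], colnames(G)[j]))
      }
      denom <- if (scale == "per_snp") lij else TAG_LENGTH * lij
      d[i, j] <- d[j, i] <- sum(abs(G[shared, i] - G[shared, j])) / denom
      L[i, j] <- L[j, i] <- lij
    }
  }
  structure(list(d = d, n_loci = L, scale = scale), class = "rad_dist")
}

#' @export
as.matrix.rad_dist <- function(x, ...) x$d

#' @export
as.dist.rad_dist <- function(m, ...) stats::as.dist(m$d)

#' @export
print.rad_dist <- function(x, ...) {
  cat(sprintf("<rad_dist> %d accessions, %s scaling\n", ncol(x$d), x$scale))
  print(round(x$d, 4))
  invisible(x)
}

#' Tidy a distance matrix into pair rows
#'
#' @param x A `rad_dist` object.
#' @param ... Unused.
#' @return Tibble with `accession_1`, `accession_2`, `distance`, `n_loci`
#'   (one row per unordered pair).
#' @export
tidy.rad_dist <- function(x, ...) {
  n <- ncol(x$d)
  idx <- which(upper.tri(x$d), arr.ind = TRUE)
  tibble(accession_1 = colnames(x$d)[idx[, 1]],
         accession_2 = colnames(x$d)[idx[, 2]],
         distance = x$d[idx],
         n_loci = x$n_loci[idx])
}

#' Neighbor-joining tree
#'
#' Classical neighbor joining (Q-criterion agglomeration with the standard
#' distance update). On an additive distance matrix the true tree and its
#' branch lengths are recovered exactly. Negative branch length estimates are
#' clamped to zero with the deficit transferred to the sibling branch, so
#' path lengths through each join are preserved.
#'
#' @param d A `rad_dist`, `dist` or symmetric matrix with row/col names; at
#'   least three taxa.
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(d) {
  D <- if (inherits(d, "rad_dist")) d$d else as.matrix(d)
  n <- nrow(D)
  if (n < 3) abort("neighbor joining needs at least three taxa")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  nodes <- labels  # newick fragment per active node
  fmt <- function(x) sprintf("%.15g", x)
  while (length(nodes) > 3) {
    m <- length(nodes)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    k <- which.min(Q)  # first minimum in column-major order: deterministic
    i <- (k - 1) %% m + 1
    j <- (k - 1) %/% m + 1
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    vi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    new_node <- sprintf("(%s:%s,%s:%s)", nodes[i], fmt(vi), nodes[j], fmt(vj))
    dn <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dn[keep]),
                c(dn[keep], 0))
    nodes <- c(nodes[keep], new_node)
    D <- D2
  }
  va <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  vb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  vc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  va <- max(va, 0); vb <- max(vb, 0); vc <- max(vc, 0)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 nodes[1], fmt(va), nodes[2], fmt(vb), nodes[3], fmt(vc))
  ape::read.tree(text = nwk)
}

# canonical bipartition keys of a tree's internal edges; the side not
# containing the reference first label is listed, so keys are rooting-free
tree_splits <- function(phy, ref_labels) {
  pp <- ape::prop.part(phy)
  keys <- vapply(pp, function(part) {
    tips <- phy$tip.label[part]
    if (ref_labels[1] %in% tips) tips <- setdiff(ref_labels, tips)
    paste(sort(tips), collapse = "|")
  }, character(1))
  keys
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples catalog loci with replacement `n_reps` times, rebuilds the
#' distance matrix and NJ tree per replicate, and reports for each internal
#' edge of the reference tree the percentage of replicates containing the
#' same bipartition. Replicates in which some accession pair shares no
#' genotyped locus are redrawn (and counted).
#'
#' @param gm A [rad_genotypes] object.
#' @param n_reps Number of bootstrap replicates.
#' @param seed Optional integer seed.
#' @param scale Distance scaling, see [pairwise_distance_matrix()].
#' @return A list of class `rad_boot`: `tree` (reference `phylo` with
#'   bootstrap percentages as internal node labels), `supports` (tibble
#'   `clade`, `n_tips`, `support`), `n_reps`, `n_redrawn`.
#' @export
bootstrap_support <- function(gm, n_reps = 1000L, seed = NULL,
                              scale = "per_snp") {
  if (nrow(gm$loci) == 0) abort("genotype matrix is empty")
  if (!is.null(seed)) set.seed(seed)
  ref <- neighbor_joining(pairwise_distance_matrix(gm, scale))
  labels <- gm$accessions$accession
  n_loci <- nrow(gm$dosage)
  rep_keys <- vector("list", n_reps)
  n_redrawn <- 0L
  for (b in seq_len(n_reps)) {
    repeat {
      idx <- sample.int(n_loci, n_loci, replace = TRUE)
      sub <- gm
      sub$dosage <- gm$dosage[idx, , drop = FALSE]
      sub$loci <- gm$loci[idx, ]
      tr <- tryCatch(
        neighbor_joining(pairwise_distance_matrix(sub, scale)),
        error = function(e) NULL)
      if (!is.null(tr)) break
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > 100L * n_reps) {
        abort("too many degenerate bootstrap replicates")
      }
    }
    rep_keys[[b]] <- tree_splits(tr, labels)
  }
  ref_keys <- tree_splits(ref, labels)
  support <- vapply(ref_keys, function(k) {
    100 * mean(vapply(rep_keys, function(s) k %in% s, logical(1)))
  }, numeric(1))
  # node labels follow prop.part's internal-node order; the root partition is
  # the trivial all-tips split
  ref$node.label <- format(round(support, 1), trim = TRUE)
  ref$node.label[1] <- ""
  pp <- ape::prop.part(ref)
  supports <- tibble(
    clade = vapply(pp, function(p)
      paste(sort(ref$tip.label[p]), collapse = "|"), character(1)),
    n_tips = lengths(pp),
    support = support
  )[-1, ]
  structure(list(tree = ref, supports = supports, n_reps = n_reps,
                 n_redrawn = n_redrawn),
            class = "rad_boot")
}

#' @export
print.rad_boot <- function(x, ...) {
  cat(sprintf("<rad_boot> NJ tree, %d tips, %d bootstrap replicates\n",
              length(x$tree$tip.label), x$n_reps))
  print(x$supports)
  invisible(x)
}

#' Bootstrap support for a named set of accessions
#'
#' Convenience lookup: returns the support of the bipartition separating
#' `accessions` from everything else, or `NA` if that clade is not in the
#' reference tree (trivial one-tip groups return 100).
#'
#' @param boot A `rad_boot` object.
#' @param accessions Character vector of tip labels.
#' @return Support percentage, or `NA`.
#' @export
clade_support <- function(boot, accessions) {
  tips <- boot$tree$tip.label
  if (length(accessions) <= 1L || length(accessions) >= length(tips) - 1L) {
    return(100)
  }
  key <- paste(sort(accessions), collapse = "|")
  alt <- paste(sort(setdiff(tips, accessions)), collapse = "|")
  hit <- boot$supports$clade %in% c(key, alt)
  if (!any(hit)) return(NA_real_)
  max(boot$supports$support[hit])
}

#' Principal components of the genotype matrix
#'
#' Genotypes are coded as alternate-allele dosages in {0, 0.5, 1}, each locus
#' is centred on its mean over genotyped accessions, missing entries are
#' filled with the locus mean (zero after centring), and the
#' accession-by-accession covariance matrix is eigendecomposed.
#'
#' @param gm A [rad_genotypes] object (>= 2 accessions, >= 1 locus).
#' @param k Number of components to retain (default all).
#' @return A `rad_pca` object: `values` (eigenvalues, descending), `coords`
#'   (accessions x components, scaled by sqrt eigenvalue), `var_fraction`,
#'   `accessions`, `n_loci`.
#' @export
pca_coordinates <- function(gm, k = NULL) {
  G <- gm$dosage
  if (ncol(G) < 2 || nrow(G) < 1) abort("need >= 2 accessions and >= 1 locus")
  all_missing <- rowSums(!is.na(G)) == 0
  if (any(all_missing)) {
    warn(sprintf("dropping %d loci with no genotypes", sum(all_missing)))
    G <- G[!all_missing, , drop = FALSE]
  }
  mu <- rowMeans(G, na.rm = TRUE)
  X <- G - mu
  X[is.na(X)] <- 0
  C <- crossprod(X) / max(nrow(X) - 1, 1)
  eig <- eigen(C, symmetric = TRUE)
  k <- k %||% ncol(C)
  vals <- eig$values
  pos <- pmax(vals, 0)
  coords <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pos[seq_len(k)]), k)
  dimnames(coords) <- list(colnames(G), paste0("PC", seq_len(k)))
  structure(list(values = vals,
                 coords = coords,
                 var_fraction = pos / sum(pos),
                 accessions = gm$accessions,
                 n_loci = nrow(X)),
            class = "rad_pca")
}

#' @export
print.rad_pca <- function(x, ...) {
  cat(sprintf("<rad_pca> %d accessions, %d loci; PC1 %.1f%%, PC2 %.1f%%\n",
              nrow(x$coords), x$n_loci,
              100 * x$var_fraction[1], 100 * x$var_fraction[2]))
  invisible(x)
}

#' @export
tidy.rad_pca <- function(x, ...) {
  out <- as_tibble(x$coords, rownames = "accession")
  left_join(out, x$accessions, by = "accession") |>
    select("accession", "group", dplyr::everything())
}

#' @export
glance.rad_pca <- function(x, ...) {
  tibble(n_accessions = nrow(x$coords), n_loci = x$n_loci,
         total_variance = sum(pmax(x$values, 0)),
         var_pc1 = x$var_fraction[1], var_pc2 = x$var_fraction[2])
}

#' @export
autoplot.rad_pca <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2,
                                   colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_fraction[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_fraction[2]),
      colour = "group") +
    ggplot2::theme_minimal()
}

#' Per-accession heterozygosity rate
#'
#' Heterozygous SNP calls per kilobase of SNP-bearing RAD tag sequence:
#' H = N_het / (41 x loci genotyped in the accession) x 1000. The upper
#' bound is 1000/41 = 24.39 per Kb (every genotyped locus heterozygous).
#'
#' @param gm A [rad_genotypes] object.
#' @param accessions Accessions to report (default all).
#' @return Tibble of class `rad_het` with `accession`, `group`, `n_het`,
#'   `n_genotyped`, `l_rad_genome` (nt) and `het_per_kb`.
#' @export
heterozygosity_rate <- function(gm, accessions = NULL) {
  accessions <- accessions %||% colnames(gm$dosage)
  missing_acc <- setdiff(accessions, colnames(gm$dosage))
  if (length(missing_acc)) {
    abort(sprintf("unknown accession(s): %s",
                  paste(missing_acc, collapse = ", ")))
  }
  G <- gm$dosage[, accessions, drop = FALSE]
  n_geno <- colSums(!is.na(G))
  if (any(n_geno == 0)) {
    abort(sprintf("no genotyped loci for accession(s): %s",
                  paste(accessions[n_geno == 0], collapse = ", ")))
  }
  n_het <- colSums(G == 0.5, na.rm = TRUE)
  out <- tibble(
    accession = accessions,
    n_het = unname(n_het),
    n_genotyped = unname(n_geno),
    l_rad_genome = unname(TAG_LENGTH * n_geno),
    het_per_kb = unname(n_het / (TAG_LENGTH * n_geno) * 1000)
  ) |>
    left_join(gm$accessions, by = "accession") |>
    select("accession", "group", dplyr::everything())
  class(out) <- c("rad_het", class(out))
  out
}

#' @export
autoplot.rad_het <- function(object, ...) {
  df <- dplyr::arrange(object, .data$group, .data$het_per_kb)
  df$accession <- factor(df$accession, levels = df$accession)
  ggplot2::ggplot(df, ggplot2::aes(.data$accession, .data$het_per_kb,
                                   fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "heterozygous SNPs per Kb", fill = "group") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

resolve_group <- function(gm, group) {
  if (length(group) == 1 && group %in% gm$accessions$group) {
    gm$accessions$accession[!is.na(gm$accessions$group) &
                              gm$accessions$group == group]
  } else {
    unknown <- setdiff(group, gm$accessions$accession)
    if (length(unknown)) {
      abort(sprintf("unknown group or accession(s): %s",
                    paste(unknown, collapse = ", ")))
    }
    group
  }
}

#' Within-group nucleotide diversity at each SNP locus
#'
#' The per-locus diversity of a group is the mean over all unordered pairs of
#' genotyped group members of the 0 / 0.5 / 1 genotype distance also used in
#' the p-distance (identical genotypes 0, homozygote vs heterozygote 0.5,
#' opposite homozygotes 1). Pairs involving a missing genotype are excluded;
#' loci with fewer than `min_members` genotyped members are flagged
#' undefined (`NA`).
#'
#' @param gm A [rad_genotypes] object.
#' @param group A group label (after [set_groups()]) or a character vector of
#'   accession names.
#' @param min_members Minimum genotyped members for a defined value.
#' @return Tibble with `locus_id`, `n_members`, `pi`.
#' @export
group_pi <- function(gm, group, min_members = 3L) {
  members <- resolve_group(gm, group)
  if (length(members) < 2) abort("group must contain at least two accessions")
  G <- gm$dosage[, members, drop = FALSE]
  n0 <- rowSums(G == 0, na.rm = TRUE)
  nh <- rowSums(G == 0.5, na.rm = TRUE)
  n1 <- rowSums(G == 1, na.rm = TRUE)
  m <- n0 + nh + n1
  num <- n0 * n1 + 0.5 * nh * (n0 + n1)
  den <- m * (m - 1) / 2
  pi <- ifelse(m >= pmax(min_members, 2), num / den, NA_real_)
  tibble(locus_id = gm$loci$locus_id, n_members = unname(as.integer(m)),
         pi = unname(pi))
}

#' Loss-of-diversity selection scan
#'
#' For each locus computes the within-group diversities of the cultivated and
#' wild groups and the loss of diversity LOD = 1 - pi_cultivated / pi_wild
#' (undefined when pi_wild = 0 or either diversity is undefined). A locus is
#' flagged selected iff the cultivated group is completely fixed
#' (pi_cultivated exactly 0, an integer-ratio quantity, so no tolerance is
#' needed) while the wild group is polymorphic - i.e. LOD is exactly 1.
#'
#' @param gm A [rad_genotypes] object.
#' @param cultivated,wild Group labels or accession vectors; must be disjoint
#'   and contain at least three members each.
#' @param min_members Passed to [group_pi()].
#' @return Tibble of class `rad_lod_scan` with `locus_id`, `a1`, `a2`,
#'   `substitution`, `n_cultivated`, `n_wild`, `pi_cultivated`, `pi_wild`,
#'   `lod`, `selected`.
#' @export
lod_selection_scan <- function(gm, cultivated = "cultivated", wild = "wild",
                               min_members = 3L) {
  cult <- resolve_group(gm, cultivated)
  wld <- resolve_group(gm, wild)
  if (length(intersect(cult, wld))) {
    abort("cultivated and wild groups must be disjoint")
  }
  if (length(cult) < 3 || length(wld) < 3) {
    abort("each group needs at least three members")
  }
  pc <- group_pi(gm, cult, min_members)
  pw <- group_pi(gm, wld, min_members)
  lod <- ifelse(!is.na(pc$pi) & !is.na(pw$pi) & pw$pi > 0,
                1 - pc$pi / pw$pi, NA_real_)
  has_alleles <- !is.na(gm$loci$a2)
  substitution <- rep(NA_character_, nrow(gm$loci))
  substitution[has_alleles] <- classify_substitution(
    gm$loci$a1[has_alleles], gm$loci$a2[has_alleles])
  out <- tibble(
    locus_id = gm$loci$locus_id,
    a1 = gm$loci$a1, a2 = gm$loci$a2,
    substitution = substitution,
    n_cultivated = pc$n_members, n_wild = pw$n_members,
    pi_cultivated = pc$pi, pi_wild = pw$pi,
    lod = lod,
    selected = !is.na(lod) & pc$pi == 0
  )
  class(out) <- c("rad_lod_scan", class(out))
  out
}

#' @export
autoplot.rad_lod_scan <- function(object, ...) {
  df <- dplyr::filter(object, !is.na(.data$pi_wild), !is.na(.data$pi_cultivated))
  ggplot2::ggplot(df, ggplot2::aes(.data$pi_wild, .data$pi_cultivated,
                                   colour = .data$selected)) +
    ggplot2::geom_jitter(width = 0.005, height = 0.005, alpha = 0.5) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = expression(pi[wild]), y = expression(pi[cultivated]),
                  colour = "LOD = 1") +
    ggplot2::theme_minimal()
}
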