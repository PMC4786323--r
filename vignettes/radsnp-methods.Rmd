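---
title: "Methods: de novo RAD-seq genotyping and diversity scans in radsnp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: de novo RAD-seq genotyping and diversity scans in radsnp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`radsnp` is a reference-free RAD-seq analysis pipeline for small diploid
panels, together with a simulator that generates the whole experiment with
recorded ground truth. This vignette explains the models and rules each
stage implements, the choices made where the method description left room,
and what the validation suite does and does not establish.

## The analysis model

### Read structure and preprocessing

A read is `barcode + AATTC + insert`, sequenced single-end at 50 bp. The
EcoRI remnant `AATTC` is part of every genuine RAD read, so demultiplexing
requires an **exact** barcode prefix match *and* the remnant immediately
after it; everything else is logged (`no_barcode` / `no_site`). Barcode
matching is exact rather than error-correcting: with all barcode pairs at
Hamming distance ≥ 2, a single sequencing error is detectable but not
reliably attributable, and a wrong assignment is worse than a lost read.
Variable-length barcodes are resolved longest-match-first; since assignment
also requires the remnant, collisions between a long barcode and a short
barcode followed by remnant bases resolve correctly.

The quality filter drops a read when *strictly more than* 50% of its bases
have Phred ≤ 5 — so a 50-bp read with exactly 25 low-quality bases is kept.
Adapter screening is exact-substring against a configurable list (no
algorithm for approximate adapter matching is implied by the method, so none
is invented). Assigned reads are trimmed to 41 nt: a 5-nt remnant plus a
36-nt variable region; SNPs are only ever accepted inside the variable
region (tag positions 5–40, 0-based).

### Stacks, loci, and the rescue of minor stacks

Within an accession, identical tags collapse into *stacks*. Stacks below
10× cannot seed a locus (they are dominated by error reads); stacks above
300× are flagged repetitive and removed, because a tag whose depth is many
times the library mean is almost surely a multi-copy genomic sequence whose
"SNPs" would be paralogous sequence variants. Retained stacks merge into RAD
tag loci by *star linkage*: stacks are visited in decreasing depth order and
each joins the deepest existing locus whose **seed** stack is within one
mismatch, or founds a new locus. Star linkage rather than transitive
single-linkage keeps chains `A–B–C` (with `A~C` at distance 2) from
collapsing; the suite contains the explicit chain case and a brute-force
connected-components oracle quantifying the difference.

One consequence of a hard 10× stack floor matters enormously for
genotyping: a heterozygote's two haplotypes split the locus depth
binomially, so at a 40× locus each haplotype averages only ~20 reads, and
the minor haplotype dips under 10× for a few percent of heterozygous sites.
Simply deleting those stacks silently converts heterozygotes into
homozygotes. The merge step therefore *rescues* sub-threshold stacks: they
may re-attach to an established locus within one mismatch of its seed (never
found one), restoring the minor allele's depth at the site. Rescue has its
own floor (`min_secondary_depth = 3`): a depth-1 or depth-2 stack is
indistinguishable from one or two coincident sequencing errors, and
re-attaching such stacks lets error doubletons masquerade as minor alleles
at marginal-depth sites, while genuine haplotype stacks that shallow
essentially never occur above the site-depth minimum.

### The depth-ratio genotyper

At each site where a locus's members disagree, alleles are ranked by depth
(ties broken alphabetically, which never affects the call because tied
depths imply a heterozygote). With `A1`, `A2` the two deepest alleles:

| condition | call |
|---|---|
| `depth_A1 + depth_A2 < 10` | insufficient depth |
| `A2` absent or `Depth_A2 / Depth_A1 < 0.05` | homozygous `A1` |
| `Depth_A2 / Depth_A1 > 0.1` | heterozygous `A1/A2` |
| ratio in `[0.05, 0.1]` | discarded (ambiguous) |

The boundary ratios 0.05 and 0.1 fall in the discarded band (closed
interval), which makes the three strict conditions a clean partition. A
third allele deeper than `0.1 × depth_A1` marks the site non-bi-allelic and
it is discarded; a shallower third allele is treated as sequencing error and
ignored. The 10× minimum is applied to the site's top-two depth total (the
per-site reading of the minimum; the per-stack floor already guarantees 10×
at invariant sites). The test suite checks the implementation against an
independent brute-force restatement of this table for every depth pair with
total ≤ 100.

### Catalog construction

Locus consensus sequences are compared across accessions with at most one
mismatch against a catalog seed (the deepest contributing locus). Each
accession contributes at most one locus per entry — the deepest — and
runners-up are logged as paralog conflicts rather than silently dropped. A
catalog locus enters the genotype matrix iff

* it is genotyped in ≥ 14 of the 18 accessions,
* exactly one site segregates across members (including within-member
  heterozygous calls),
* exactly two alleles occur at that site, and
* the site lies in the 36-nt variable region.

Monomorphic entries are tallied separately: they are real RAD loci but not
SNPs. The completeness and single-SNP filters commute, which the suite
asserts directly. Genotypes are stored as alternate-allele dosages
`0 / 0.5 / 1` with `NA` for missing; the reference allele is the catalog
seed's base at the SNP.

### Distances, trees, PCA

The genotype p-distance between accessions *i* and *j* averages, over loci
genotyped in both, a per-locus distance *d* that is 0 for identical
genotypes (heterozygote vs heterozygote included), 0.5 for homozygote vs
heterozygote, and 1 for opposite homozygotes — equivalently
`d = |g_i − g_j|` on dosages. The normalising constant is the shared-locus
count by default, giving distances in `[0, 1]`; a nucleotide scaling
(41 × shared loci) is available and changes nothing topological, since NJ is
invariant to a constant factor. The "length of regions" in the distance
definition is thus read as the number of co-genotyped SNP loci, the only
reading that makes the per-locus values 0/0.5/1 average correctly.

`neighbor_joining()` is the classical Q-criterion agglomeration with the
standard distance update, written in-package so its numerical behaviour is
pinned: ties in Q break deterministically (first minimum in column-major
order), and negative branch-length estimates are clamped to zero with the
deficit moved to the sibling branch, preserving path lengths through the
join. On additive matrices NJ is exact; the suite verifies recovery of
topology and branch lengths to 1e-9 on hundreds of random 8–12-leaf trees
and cross-checks topology against `ape::nj`. Bootstrap support resamples
catalog loci with replacement, rebuilds distance + NJ per replicate, and
reports for each internal edge of the reference tree the percentage of
replicates containing the same bipartition (computed on canonicalised
splits, so rooting is irrelevant). Replicates in which some accession pair
shares no genotyped locus are redrawn and counted.

PCA codes genotypes as dosages, centres each locus on its mean across
genotyped accessions, fills missing entries with that mean (zero after
centring), and eigendecomposes the accession-by-accession covariance
matrix. Only the plain covariance decomposition is performed — significance
testing of components is out of scope. The eigenvalue sum equals the total
centred variance (asserted as the trace identity), and cluster separation is
tested sign-invariantly, never on raw coordinate values.

### Heterozygosity, π, and the LOD scan

Per-accession heterozygosity is heterozygous calls per kilobase of
SNP-bearing tag sequence: `H = N_het / (41 · L_genotyped) × 1000`, bounded
above by 1000/41 ≈ 24.4/Kb. Within-group diversity at a locus is the mean
pairwise genotype distance (`0/0.5/1` as above) over all genotyped group
members — e.g. four-vs-four opposite homozygotes give 16/28 ≈ 0.57, seven
homozygotes plus one heterozygote give 3.5/28 ≈ 0.13. π is undefined below
three genotyped members (a guard against two-member "groups" where a single
pair decides the value).

The loss of diversity is `LOD = 1 − π_cultivated / π_wild`, undefined when
`π_wild = 0`. A locus is *selected* iff `LOD = 1` exactly, i.e.
`π_cultivated = 0` with a polymorphic wild group. Because π is a ratio of
small integers, the equality needs no floating-point tolerance. The
cultivated group comprises the nine cultivated accessions, the wild group
the eight wild accessions; the admixed landrace belongs to neither, exactly
as an intermediate hybrid should be excluded from a domestication contrast.

### Transcript matching and coding effects

The mapper is a deterministic ungapped scan of the tag's 36-nt variable
region against both strands of every transcript, honouring ≥ 80% coverage
(partial overlaps may hang off transcript ends), > 90% identity and at most
one mismatch; no E-value is computed, because alignment statistics against a
toy transcript set would be theatre. The single best alignment is kept
(fewest mismatches, longest overlap, then transcript id and position);
runners-up are returned for inspection. A mapped SNP inside a CDS is
classified by locating its codon from the CDS interval and frame (0-based,
half-open coordinates; an interval that is not a codon multiple is an error
naming the transcript), substituting both alleles — complemented on
minus-strand alignments — and translating with the standard genetic code.
The suite checks strand-consistency and agreement with a brute-force
translate-and-compare oracle over random codons, and `dn_ds_summary()`
reports the non-synonymous / synonymous count ratio.

## The simulator: what it emulates, and what it does not

The generator reproduces the statistical structure the analysis assumes: 18
diploid accessions in six clades — two cultivated (6 + 3), three wild
(4 + 3 + 1) and one admixed landrace — typed at up to a few thousand EcoRI
tag loci.

* **Allele frequencies** follow a hierarchical Balding–Nichols model: an
  ancestral frequency per locus (uniform on 0.1–0.9), drifted once at the
  cultivated/wild split and once per clade, with `F = 0.2` at each level.
  The wild clades stand for distinct *Camellia* species, so strong
  differentiation is the realistic regime; it is also what makes six clades
  recoverable from ~2,000 SNPs.
* **Genotypes** are Hardy–Weinberg draws within clades, thinned by a
  per-status heterozygote retention factor (1 − F_IS: cultivated 0.9, wild
  0.5, admixed 1.0), reproducing the empirical ordering in which cultivated
  accessions are more heterozygous than wild ones and the admixed landrace
  is the most heterozygous. The admixed accession draws one haplotype from
  a cultivated-like and one from a wild-like frequency.
* **Selected loci**: 5% of clean tags are forced to a single homozygous
  genotype across all cultivated accessions while the wild clades segregate
  (redrawn until realized polymorphism). The truth flag is computed from
  the *realized* genotypes, so loci that fix in the cultivated group by
  drift alone are flagged too — the scan is scored against what is actually
  true in the sample, not against intentions.
* **Depth** is negative binomial with mean 40 and size 20 per accession-tag
  (Poisson when the dispersion is infinite), split binomially between the
  two haplotypes. Repetitive tags (2% of families) carry 8–12 genomic
  copies, multiplying their depth past the 300× filter.
* **Errors and artefacts**: substitution errors at 0.002/base uniformly
  within the read; 2% of reads carry a heavy Q ≤ 5 tail to exercise the
  quality filter; 3% of tags carry a second variant to exercise the
  single-SNP filter; accessions go missing at a locus with probability
  0.005; barcodes are drawn with pairwise Hamming distance ≥ 2.

Deliberately absent: indels, paired ends, PCR duplicates, chimeras, quality
miscalibration, base-context error biases, and linkage between loci (every
locus is drawn independently). Passing the suite therefore shows the
pipeline implements its rules correctly and recovers structure under
realistic depth and error regimes — it does not certify performance on real
libraries, where error is context-dependent and repeats are subtler.

## Validation design and problem sizes

Three kinds of evidence, all generated at test time:

* **Oracle agreement** — the genotyper against an exhaustive rule-table
  enumeration (all depth pairs, total ≤ 100); π against a brute-force pair
  loop over every genotype configuration of up to six members; coding
  effects against direct codon translation; NJ against path-length metrics
  of 200 random additive trees (exact to 1e-9) and against `ape::nj`.
* **Printed worked examples** — the summary statistics the method reports
  (TI/TV 1.48 and a 59.7% transition share on a 15,444-locus spectrum with
  4,695 C/T; dN/dS 1.1 from 238/215; π extremes 0.57/0.13; LOD 1 at a fixed
  locus; a 60.1% transition share among 644 selected loci; 0.63 MB of tag
  sequence; run-level bookkeeping ratios) recomputed through the package's
  own functions from the corresponding published table counts.
* **End-to-end recovery** — the full scenario (2,000 fragments, seed 1,
  defaults above): ≥ 95% of clean segregating planted loci recovered in the
  catalog with every non-missing genotype correct; ≥ 99% precision and
  recall of the LOD-selected set; all six clades monophyletic at ≥ 95%
  support over 200 bootstrap replicates. A perfect-data variant (600
  fragments, zero error, zero missingness, Poisson depth so no stochastic
  coverage dropout) must be recovered *exactly* and byte-identically across
  reruns.

The 2,000-fragment scale keeps the full scenario at a few minutes on one
CPU while leaving every per-locus probability estimate (recovery, precision,
recall) with a denominator in the hundreds; the smaller simulations used by
unit tests (150–600 fragments) resolve the deep cultivated/wild split but
not every shallow clade, which is why only the end-to-end scenario asserts
six-clade monophyly.

## Numerical and degenerate-input policy

* Coordinates are 0-based half-open internally; VCF export converts to
  1-based positions.
* Consensus ties (equal depth) resolve to the alphabetically first base;
  A1/A2 ties likewise, which never changes a call (tied depths are
  heterozygous regardless of labelling).
* `π_cultivated = 0` is tested exactly; no tolerances are applied to
  integer-ratio statistics. Printed-precision comparisons round halves away
  from zero (`round_half_up()`), matching how 0.125 prints as 0.13.
* Degenerate inputs fail loudly with the offending object named: accession
  pairs sharing no loci, unknown groups or accessions, overlapping group
  definitions, duplicate barcodes, infeasible barcode requests, CDS
  intervals that are not codon multiples.
* The simulator, pipeline and bootstrap are deterministic given a seed; the
  only RNG consumers are the generator and locus resampling.

## Known limitations

* The genotyper is a hard threshold rule, not a likelihood model; near the
  ratio boundaries its calls discard information that a probabilistic
  caller would use. This is faithful to the method being implemented, not a
  recommendation.
* Star-linkage merging and deepest-seed cataloguing are greedy; rare
  configurations of equal-depth stacks could cluster differently under a
  different visiting order, though ordering is fully deterministic here.
* The transcript matcher is ungapped by design and will miss hits spanning
  indels; with at most one mismatch allowed this is the intended behaviour.
* Six-clade phylogenetic recovery depends on the planted differentiation
  level; at much lower F or far fewer loci, shallow clades are genuinely
  unresolvable and the tree tests say nothing about such regimes.
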