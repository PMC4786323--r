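# radsnp

De novo RAD-seq SNP discovery and domestication diversity scans for small
diploid panels, with a ground-truthed read simulator for end-to-end
validation.

## The problem

Restriction site-associated DNA (RAD) sequencing reads short tags next to
restriction cut sites (here EcoRI, remnant `AATTC`), reducing a genome to a
reproducible subset that can be sequenced deeply across many individuals.
For non-model species without a reference genome — the motivating case is a
panel of cultivated tea accessions and their wild *Camellia* relatives — SNPs
must be discovered *de novo* by clustering the reads themselves. `radsnp`
implements that whole analysis as composable R functions:

1. **Preprocess** — demultiplex inline 4–8 nt barcodes (exact match plus the
   `AATTC` remnant check), drop reads with >50% of bases at Phred ≤ 5, trim
   to uniform 41-nt tags (5-nt remnant + 36-nt variable region).
2. **Stack assembly** — cluster identical tags into stacks per accession;
   discard stacks below 10× (error products) and above 300× (repeats); merge
   stacks within one mismatch of a seed into RAD tag loci, re-attaching
   sub-threshold minor-allele stacks to established loci.
3. **Genotyping** — at each variable site, order alleles by depth and call
   with the hard ratio rule: homozygous if `Depth_A2 / Depth_A1 < 0.05`,
   heterozygous if `> 0.1`, discarded in between, with a 10× minimum site
   depth.
4. **Catalog** — match locus consensus sequences across accessions (≤1
   mismatch), keep loci genotyped in ≥14 of 18 accessions that carry exactly
   one bi-allelic SNP in the 36-nt variable region.
5. **Population genetics** — genotype p-distances
   (`d = 0, 0.5, 1` for identical / hom-vs-het / opposite-hom pairs),
   neighbor-joining trees with bootstrap support, covariance-matrix PCA,
   per-accession heterozygosity `H = N_het / (41 · L) × 1000` per Kb,
   per-locus within-group diversity π (mean pairwise genotype distance), and
   the loss-of-diversity scan `LOD = 1 − π_cultivated / π_wild`, flagging
   loci fixed by domestication (`LOD = 1`).
6. **Annotation** — ungapped ≤1-mismatch matching of SNP tags onto a
   transcript set (≥80% coverage, >90% identity) and codon-level
   synonymous / non-synonymous classification with a dN/dS summary.

A first-class simulator (`simulate_rad_experiment()`) generates barcoded
FASTQ-style reads for 18 accessions in six clades with a recorded truth
table — planted SNPs, genotypes, repeats, multi-SNP tags, and loci fixed in
the cultivated group — so every stage is testable without any external data.

## Worked example

```r
library(radsnp)

sim <- simulate_rad_experiment(sim_config(n_fragments = 500, seed = 21))
grp <- setNames(sim$config$accessions$status, sim$config$accessions$accession)
res <- rad_pipeline(sim$reads, sim$barcodes, groups = grp)

res$genotypes
#> <rad_genotypes> 441 loci x 18 accessions (0.8% missing)

glance(summarize_snps(res$genotypes))[, 1:5]
#> # A tibble: 1 × 5
#>   n_loci n_transitions n_transversions ti_tv pct_transitions
#>    <int>         <int>           <int> <dbl>           <dbl>
#> 1    441           264             177  1.49            59.9

scan <- lod_selection_scan(res$genotypes)
sum(scan$selected)        # loci with LOD = 1: fixed in cultivated, wild-poly
#> [1] 96

boot <- bootstrap_support(res$genotypes, n_reps = 200, seed = 1)
ape::write.tree(boot$tree)  # Newick with bootstrap % as node labels
```

The genotype matrix is a light S3 object with `tidy()` / `glance()` methods
and dosage coding 0 / 0.5 / 1; `pca_coordinates()`, `heterozygosity_rate()`
and the scan all return tibbles (with `autoplot()` methods), so results
chain straight into dplyr/ggplot2. `write_genotype_vcf()`,
`write_genotype_tsv()`, `write_distance_matrix()` and `ape::write.tree()`
cover the standard interchange formats.

On the default validation scenario (2,000 fragments, mean tag depth 40×,
0.2% base error), the pipeline recovers ~99% of planted segregating SNP loci
with fully correct genotypes, the LOD scan attains ≥99% precision and recall
against the planted fixed loci, and all six planted clades are monophyletic
with ≥95% bootstrap support.

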