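# haplotrio

Phasing quality control for trios of hybrid diploid genome assemblies that
pairwise share a parental species.

## The problem

Interspecific hybrids — grape rootstocks are the motivating case — carry one
haplotype from each of two parental species. Three such hybrids whose
pedigrees form a *triangle* (every pair of genomes shares exactly one
parental species) provide each other with an internal phasing reference: a
haplotype derived from species *S* should match the *S*-haplotype of the
genome sharing *S* far more closely than any haplotype of the third genome.
A *haplotype switch* — an assembly error in which a pseudomolecule
alternates between segments of the two haplotypes — appears as a
change-point in this per-gene-locus similarity signal.

haplotrio implements the full analysis:

* **Parental assignment.** For each chromosome, gene-locus best hits are
  summarized into a similarity matrix over the six (genome, haplotype)
  units; the labeling maximizing the three shared-species entries over the
  2³ haplotype orientations assigns each haplotype to a parental species.
* **Switch detection and correction.** Each locus votes between the two
  pedigree species of its genome (margin = identity difference between the
  competing foreign genomes); majority smoothing plus two pedigree
  complementarity constraints call switch events, which are corrected by
  exchanging the complementary segments between haplotypes, snapping cuts
  to assembly (AGP) component junctions.
* **Divergence statistics.** Whole-sequence alignment of every ordered
  haplotype pair (30 directional comparisons for a trio) yields SNP/indel/
  SV calls and the *unaffected-length similarity*: the percentage of the
  haploid sequence set not covered by any variant,
  `100 * (1 - affected / haploid_length)`. Shared- vs non-shared-species
  groups (6 vs 24) are compared with an unpaired two-sample rank-sum test:
  `W` is the Mann-Whitney pair count (ties half), with an exact permutation
  p-value for small samples and a tie- and continuity-corrected normal
  approximation otherwise.
* **Colinearity.** Filtered locus anchors (identity and coverage > 80%)
  are chained by dynamic programming (rank gaps ≤ 5, ≥ 10 anchors per
  block, both orientations) into colinear blocks; coverage is reported at
  the locus level and as the fraction of sequence length under blocks.
* **Synthetic trios with truth.** A generator simulates three parental
  species at controlled divergence (SNPs, short indels, SVs > 50 bp),
  composes hybrids under a triangle pedigree, and injects haplotype
  switches with machine-readable truth, so every stage is testable at desk
  scale without downloads.

## Worked example

```r
library(haplotrio)

cfg <- run_config(seed = 1L, permissive = TRUE)   # 3 genomes x 2 x 500 kbp,
report <- run_full(cfg)                           # 5 switches per genome

report$evaluation$precision
#> [1] 1
report$evaluation$recall
#> [1] 1
nrow(report$residual_events)                      # switches left after correction
#> [1] 0
report$divergence
#> Haplotype-pair similarity: shared 99.34% (n=6) vs non-shared 96.97% (n=24)
#> Rank-sum test (normal_approx): W = 144, n = 6 vs 24, two-sided p = 0.0002096
report$summary$colinear_locus_pct_shared
#> [1] 100
```

All 15 injected switches are recovered with breakpoints localized to one
intergenic interval, correction leaves no residual events, haplotype pairs
sharing a parental species are distinctly more similar than pairs that do
not (99.34% vs 96.97% of sequence length unaffected by variants; the
rank-sum statistic W = 144 of a maximum 144 at p ≈ 2 × 10⁻⁴ says the two
groups separate completely), and essentially all loci fall in colinear
blocks in this repeat-free simulation.

`tidy()`, `glance()` and `autoplot()` methods summarize and plot the
rank-sum and group-comparison objects; `plot_profile()` draws the per-locus
assignment tracks with detected breakpoints.

For real assemblies, `read_fasta()`, `read_gff3()`, `read_paf()` and
`read_mummer_tables()` ingest the standard formats;
`best_hits_from_paf()` substitutes externally computed alignments for the
internal scorer at chromosome scale.

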