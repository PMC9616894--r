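---
title: "Shared-parentage haplotyping of hybrid assembly trios: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shared-parentage haplotyping of hybrid assembly trios: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplotrio)
```

## The problem

Commercial grape rootstocks are interspecific hybrids: each genome carries
one haplotype from each of two parental *Vitis* species. When three such
hybrids form a *triangle pedigree* — every pair of genomes shares exactly one
parental species — the shared species provides an internal reference for
haplotype phasing quality control. A haplotype of genome 1 derived from
species *S* should resemble the *S*-derived haplotype of the genome that
shares *S* far more closely than any haplotype of the third genome. A
*haplotype switch* — an assembly error where a pseudomolecule alternates
between segments of the two haplotypes — shows up as a change-point in this
similarity signal along the chromosome.

haplotrio implements this analysis end to end: per-locus similarity scoring,
pedigree-constrained parental assignment, switch detection and correction,
inter-haplotype divergence statistics with a rank-sum comparison of shared-
versus non-shared-species haplotype pairs, and colinear-block coverage. A
synthetic trio generator with machine-readable truth makes every stage
testable at desk scale.

## The synthetic trio generator

`simulate_ancestors()` draws a uniform random ancestor (species A) with
non-overlapping gene loci, then derives species B and C by independent
mutation passes: per-base substitutions, short indels (length uniform on
1..`indel_max`), and structural variants (> 50 bp; deletions and tandem
duplications). Gene loci are lifted through every edit so orthologs
correspond across species by (chromosome, rank). SVs are placed in
intergenic space only, keeping ortholog counts equal — a prerequisite for
the rank-based anchoring used downstream.

`compose_hybrids()` builds each hybrid's two haplotypes as mutated copies of
its two pedigree species at `noise_factor` (default 0.2) times the
between-species rates. The species-to-haplotype-slot assignment is
randomized per chromosome, as it would be after automated scaffolding.
Pseudomolecules are cut into 2–6 AGP components at random positions.

`inject_switches()` exchanges alternating segments between the two
haplotypes of a chromosome at sampled breakpoints, preferring AGP component
junctions with probability 0.8 (the typical origin of real switches), and
records the truth.

Default parameters and why:

| parameter | default | rationale |
|---|---|---|
| `chrom_length` | 500 kbp | desk-scale stand-in for a ~25 Mbp pseudomolecule |
| `n_genes_per_chrom` | 200 | keeps locus density (1 gene / 2.5 kbp) near a gene-rich genome |
| `gene_length` | 2,000 bp | typical genomic span of a plant gene locus |
| `snp_rate` | 0.01 /bp | between-species divergence of closely related congeners |
| `indel_rate`, `indel_max` | 0.002 /bp, 10 bp | short indels dominated by few-bp events |
| `sv_count_per_chrom`, `sv_length_range` | 2, 100–1,000 bp | exercises the > 50 bp variant class |
| `noise_factor` | 0.2 | within-species (haplotype) noise well below between-species divergence, so shared-species similarity exceeds cross-species similarity by construction |

The locus geometry matters quantitatively. A vote compares identities whose
difference (the species signal) is roughly the between- minus within-species
divergence (~2–3% here), while the per-locus noise is dominated by the
variance of indel lengths in individual gene copies. With 2 kb loci and
indels ≤ 10 bp the noise standard deviation is ~0.7%, putting a single
locus's vote about four standard deviations from the wrong side; with 1 kb
loci and 20 bp indels the two are of the same magnitude and single-locus
votes become unreliable, which contradicts the cleanly segregating per-locus
similarity tracks this method presumes. The defaults are calibrated to the
former regime.

Injected switch boundaries keep ≥ 10 gene intervals between them and ≥ 10
loci from chromosome ends, so each exchanged segment is resolvable at the
detector's smoothing scale.

### What the generator does not emulate

Repeat landscapes, segmental duplications and gene-family expansions (the
main source of paralog noise in real data), read-level artifacts, assembly
gaps, and inversions or translocations between haplotypes. Passing tests
therefore demonstrate correctness of the algorithms under the stated model,
not performance on repeat-rich real assemblies, where the identity floors
and the k-mer prefilter would have to carry more weight.

## Locus similarity

Loci are scored on their genomic spans (introns included). The scorer is a
deterministic two-stage pipeline: a minimizer prefilter (k = 15, window 10,
candidates need ≥ 10 shared minimizers) proposes locus pairs, then a banded
pairwise alignment (match +2, mismatch −2, linear gap −3) computes identity
as matches over alignment columns, excluding columns that touch an N.
`score_pair()` uses a band of 0.2 × the longer length; `best_hits()`
narrows it to 0.05 because prefilter-proposed pairs have bounded indel
drift. The `"glocal"` mode aligns the shorter sequence end-to-end with free
end gaps on the longer, so a query embedded in a longer target scores
coverage 1.0 / 0.5 rather than being punished with end gaps. Best hits are
ranked by identity × query coverage, ties broken by identity, then target
id — a total order where "highest coverage and identity" alone is not.

## Parental assignment and switch detection

`build_similarity_matrix()` averages best-hit identities between the six
(genome, haplotype) units of a chromosome, pooling both directions.
`assign_parent_labels()` searches the 2³ per-genome haplotype orientations
exhaustively and keeps the one maximizing the sum of the three
shared-species entries; a winning margin below 0.005 flags the chromosome
ambiguous. Labeling is per chromosome, so a whole-arm switch remains
representable.

`build_profile()` gives each locus a vote between the genome's two pedigree
species. The evidence for species *S* is the best-hit identity against the
genome sharing *S*, taking the better of that genome's two haplotypes. This
max-over-haplotypes rule is what makes voting robust: if the foreign genome
itself carries a haplotype switch, the shared-species ortholog is still
present — merely on its other haplotype — so the vote is unchanged. Votes
with an identity margin below 0.002, or loci with no hit, are ambiguous.

Two pedigree constraints are exploited before events are called:

* *Locus complementarity.* The two haplotypes of a chromosome carry
  different species, so at any rank their votes must differ. Equal
  confident votes on both haplotypes mark a degraded locus (typically a
  long indel in the shared foreign copy) and are demoted to ambiguous.
* *Event complementarity.* A genuine switch exchanges material between the
  haplotypes, flipping both profiles at the same boundary with swapped
  species. `detect_all_switches()` therefore keeps only mirrored event
  pairs; single-haplotype flips are reported separately as artifacts.

`detect_switches()` smooths votes with a centered 5-locus majority window
and calls a state change after ≥ 3 consecutive smoothed votes of the new
state. The breakpoint interval runs from the last locus *supporting* the
old state to the first locus supporting the new one, so ambiguous
boundary-adjacent loci widen the interval instead of displacing it.
Chromosomes with > 50% ambiguous votes are flagged uncallable. The window
and run length are the smallest values that suppress single-locus noise in
synthetic calibration; they bound detectable segments to ≥ 3 loci.

## Correction

`plan_correction()` converts paired events into segment-exchange plans. The
cut snaps to the nearest AGP component junction within 50 kbp of the
breakpoint interval (a junction inside the interval has distance zero),
else falls back to the interval midpoint; a cut may split a component.
Plans are anchored as (boundary gene rank, offset past that gene's end) on
each haplotype. This anchoring makes the exchange self-locating: because
the anchor gene and the sequence up to the cut move rigidly with their
segment, `apply_correction()` can return an `plans_undo` table — the same
boundaries re-anchored on the corrected state — whose application restores
the input byte-identically even when the exchanged segments differ in
length (for a single boundary per chromosome the verbatim plan is its own
undo). Loci crossing a cut cannot be split and are dropped from the
corrected catalog with a logged count. Base content per chromosome pair is
conserved by construction.

## Divergence statistics

`align_haplotypes()` is a desk-scale whole-sequence comparator: unique
shared 21-mers anchor the alignment, anchors are chained by longest
increasing subsequence on both coordinates, inter-anchor gaps ≤ 20 kbp per
side are closed by banded global alignment, and larger gaps become SV
spans. Variants are classified SNP / INDEL (≤ 50 bp) / SV (> 50 bp, the
larger of the two sides). Unaligned reference spans count as SV-affected —
a sequence that cannot be aligned cannot be called unaffected. Inputs are
capped at 10 Mbp; beyond that the MUMmer `show-snps`/`show-diff` import
path (`read_mummer_tables()`) provides the same variant sets at real scale.

`unaffected_fraction()` computes the similarity statistic: 100 × (1 −
affected / haploid length), where affected is the coordinate union of SNP
positions, indel spans and SV spans (overlaps counted once; a zero-length
insertion point counts 1 bp, otherwise insertions would be invisible).

`grouped_similarity()` builds the six species-coherent haploid units (per
genome, the per-chromosome haplotypes labeled with one parental species)
and compares every ordered pair: 30 directional comparisons — 6 between
units of the same species and 24 between units of different species
(including the sibling pair within each genome). Both directions are
reported, never averaged. `rank_sum_test()` compares the two groups: W is
the Mann-Whitney count of group-1-over-group-2 pairs with half ties; the
two-sided p-value comes from exhaustive permutation enumeration when
n₁ + n₂ ≤ 20 (extremeness as distance of W from its null mean — this
definition also gives p = 1 for identical groups), else from a normal
approximation with tie and continuity corrections. At group sizes 6 and 24,
W = 142 gives p ≈ 3 × 10⁻⁴ under that approximation.

## Colinearity

Anchors derive from best hits passing the retention floors (identity and
query coverage > 0.8) and a dual-fraction overlap rule (aligned span covers
≥ 50% of the query locus; the target locus covers ≥ 75% of the aligned
span — trivially satisfied for locus-to-locus alignments, retained for PAF
imports where spans need not sit inside loci). `chain_blocks()` runs a
dynamic program over anchors sorted by query rank with chain score = anchor
count, rank gaps ≤ 5 on both sides, both orientations searched; blocks need
≥ 10 anchors and are extracted best-first with anchors marked used, which
keeps reported blocks disjoint. `coverage_stats()` reports the fraction of
loci in ≥ 1 block and the fraction of sequence length covered by the union
of block extents, summarized for shared- versus different-species unit
pairs.

## Numerical and degenerate-input choices

* All internal coordinates are 0-based half-open; GFF3/AGP convert at the
  file boundary, PAF/BED pass through natively.
* Alignment identity denominators exclude columns touching N; sequences
  over 50% N are excluded from voting entirely.
* Ties in locus ranking break by start then lexicographic gene id; ties in
  best-hit ranking by identity then target id; orientation ties in
  labeling leave the chromosome flagged rather than silently choosing.
* Empty inputs (no anchors, empty variant sets, empty event lists) return
  typed empty tibbles, and a whole-sequence SV span is emitted with a
  warning when two sequences share no alignment anchor.
* A single integer seed drives the full simulation chain through R's RNG;
  rerunning any pipeline configuration is byte-deterministic.

## Problem sizes used by the test-suite

Unit tests run on one-chromosome trios of 80–120 kbp with 25–40 loci; the
acceptance checks run the full study conditions (2 × 500 kbp, 200 loci per
chromosome, 5 switches per genome) across 10 seeds for detection and single
seeds for the correction, divergence and colinearity stages, with
brute-force oracles (per-base marking, exhaustive permutation enumeration,
exhaustive chain search, [Biostrings::pairwiseAlignment()]) at small n.

## Known limitations

* Paralogy is modeled only implicitly (all loci are single-copy); real
  gene families would add best-hit ambiguity the prefilter must absorb.
* Inversions between haplotypes are not simulated, so antiparallel blocks
  are exercised only by constructed cases.
* The switch detector needs ≥ 3 informative loci per segment; switches in
  gene deserts are out of reach by design.
* The internal aligner targets desk-scale inputs; chromosome-scale real
  assemblies should enter through the PAF / MUMmer import paths.
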