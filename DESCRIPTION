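Package: haplotrio
Title: Shared-Parentage Haplotyping of Hybrid Diploid Assembly Trios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quality control of haplotype phasing in trios of
    hybrid diploid genome assemblies that pairwise share a parental
    species (a triangle pedigree). The package assigns each haplotype of
    each pseudomolecule to its parental species from gene-locus sequence
    similarity, detects and corrects haplotype switches as change-points
    in the per-locus assignment signal, computes inter-haplotype
    SNP/indel/structural-variant divergence and the unaffected-length
    similarity statistic with a rank-sum comparison of shared- versus
    non-shared-species haplotype pairs, and measures colinear-block
    coverage between haplotypes. A synthetic trio generator with
    machine-readable truth makes the full pipeline testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    Biostrings,
    IRanges,
    rtracklayer,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
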