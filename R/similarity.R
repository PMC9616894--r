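# Gene-locus similarity scoring: the evidence layer for parental assignment.
#
# The scorer is deliberately self-contained and deterministic: a minimizer
# prefilter proposes candidate locus pairs, then a banded pairwise alignment
# (implemented in C++) yields identity and coverage. Columns containing N are
# excluded from the identity denominator.

revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", vapply(s, function(x)
    paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""), "",
    USE.NAMES = FALSE))
}

#' Extract gene-locus sequences from an assembly
#'
#' Takes the genomic locus span (introns included, not spliced mRNA);
#' minus-strand loci are reverse-complemented.
#'
#' @param assembly A [diploid_assembly()].
#' @param catalog Locus catalog restricted to (or filtered for) this genome.
#' @return Named character vector, one sequence per `gene_id`.
#' @export
extract_locus_sequences <- function(assembly, catalog) {
  catalog <- dplyr::filter(catalog, .data$genome == assembly$genome)
  out <- character(nrow(catalog))
  for (key in unique(paste(catalog$chrom, catalog$haplotype))) {
    sel <- paste(catalog$chrom, catalog$haplotype) == key
    ch <- catalog$chrom[sel][1]; h <- catalog$haplotype[sel][1]
    s <- assembly_seq(assembly, ch, h)
    if (any(catalog$end[sel] > nchar(s)) || any(catalog$start[sel] < 0)) {
      bad <- catalog$gene_id[sel][catalog$end[sel] > nchar(s) | catalog$start[sel] < 0][1]
      abort(sprintf("locus %s out of bounds on %s", bad, seq_name(ch, h)))
    }
    out[sel] <- substring(s, catalog$start[sel] + 1L, catalog$end[sel])
  }
  neg <- catalog$strand == "-"
  if (any(neg)) out[neg] <- revcomp(out[neg])
  setNames(out, catalog$gene_id)
}

#' Score a pair of locus sequences
#'
#' Two sequences are aligned with a banded pairwise alignment (band
#' `band_frac` of the longer length). `"glocal"` aligns the shorter
#' sequence end-to-end with free end gaps on the longer one; `"global"`
#' aligns both end-to-end. Identity is matches over alignment columns,
#' excluding columns that touch an N; it is symmetric in the two inputs.
#' Sequences with more than 50% N are flagged low-confidence.
#'
#' @param seq_a,seq_b Nucleotide strings.
#' @param mode `"glocal"` (default) or `"global"`.
#' @param band_frac Band width as a fraction of the longer sequence.
#' @return One-row tibble: `identity`, `coverage_a`, `coverage_b`,
#'   `low_confidence`.
#' @export
score_pair <- function(seq_a, seq_b, mode = c("glocal", "global"),
                       band_frac = 0.2) {
  mode <- match.arg(mode)
  if (nchar(seq_a) == 0 || nchar(seq_b) == 0) abort("empty sequence")
  lowconf <- function(s) {
    mean(strsplit(s, "", fixed = TRUE)[[1]] == "N") > 0.5
  }
  low <- lowconf(seq_a) || lowconf(seq_b)
  # canonical orientation makes identity symmetric: shorter (ties:
  # lexicographically smaller) sequence is the pattern
  flip <- (nchar(seq_a) > nchar(seq_b)) ||
    (nchar(seq_a) == nchar(seq_b) && seq_a > seq_b)
  p <- if (flip) seq_b else seq_a
  s <- if (flip) seq_a else seq_b
  al <- .cpp_band_align(p, s, band_frac = band_frac,
                        mode = if (mode == "global") 0L else 1L)
  denom <- al$block_len - al$n_excluded
  identity <- if (denom > 0) al$matches / denom else 0
  cov_p <- 1.0
  cov_s <- (al$t_end - al$t_start) / nchar(s)
  if (mode == "global") cov_s <- 1.0
  tibble(identity = identity,
         coverage_a = if (flip) cov_s else cov_p,
         coverage_b = if (flip) cov_p else cov_s,
         low_confidence = low)
}

# Vectorized scorer over paired sequence vectors; same alignment and
# canonical orientation as score_pair(), without per-row tibble overhead.
score_pairs_fast <- function(qs, ts, band_frac) {
  n <- length(qs)
  id <- covq <- covt <- numeric(n)
  n_frac <- function(s) {
    (nchar(s) - nchar(gsub("N", "", s, fixed = TRUE))) / pmax(nchar(s), 1L)
  }
  low <- n_frac(qs) > 0.5 | n_frac(ts) > 0.5
  for (i in seq_len(n)) {
    a <- qs[[i]]; b <- ts[[i]]
    flip <- (nchar(a) > nchar(b)) || (nchar(a) == nchar(b) && a > b)
    p <- if (flip) b else a
    s <- if (flip) a else b
    al <- .cpp_band_align(p, s, band_frac = band_frac, mode = 1L)
    denom <- al$block_len - al$n_excluded
    id[i] <- if (denom > 0) al$matches / denom else 0
    cs <- (al$t_end - al$t_start) / nchar(s)
    covq[i] <- if (flip) cs else 1
    covt[i] <- if (flip) 1 else cs
  }
  tibble(identity = id, coverage_query = covq, coverage_target = covt,
         low = low)
}

# Minimizer sketches for a set of locus sequences -> long tibble (gene_id,
# hash). Used by the candidate prefilter.
locus_sketches <- function(seqs, k = 15L, w = 10L) {
  hl <- lapply(seqs, .cpp_minimizers, k = k, w = w)
  tibble(gene_id = rep(names(hl), lengths(hl)),
         hash = as.double(unlist(hl, use.names = FALSE)))
}

#' Best foreign hits per locus
#'
#' For every query locus and every foreign (genome, haplotype) unit, finds
#' the target locus maximizing `identity * coverage_query` (ties broken by
#' identity, then target `gene_id`). Candidates are proposed by a shared
#' minimizer prefilter (`k = 15`, at least `min_shared` shared minimizers),
#' then scored by banded alignment; entries below the identity/coverage
#' floors are dropped, as are low-confidence (>50% N) sequences.
#'
#' @param query_seqs Named sequences of the query loci
#'   (see [extract_locus_sequences()]).
#' @param query_catalog Catalog rows describing the query loci.
#' @param foreign_seqs,foreign_catalog Same for the loci of all foreign
#'   genomes to search (may span several genomes; haplotype units are
#'   distinguished automatically).
#' @param min_identity,min_coverage Retention floors on identity and query
#'   coverage.
#' @param min_shared Minimum shared minimizers for a candidate pair.
#' @param max_candidates Candidates scored per query and foreign unit.
#' @param same_chrom_only Restrict candidates to the query's chromosome
#'   index (orthologous pseudomolecules), the pipeline default.
#' @param band_frac Alignment band fraction; the default is narrower than
#'   [score_pair()]'s because locus pairs proposed by the prefilter have
#'   bounded indel drift.
#' @return Best-hit tibble, one row per (query locus, foreign unit).
#' @export
best_hits <- function(query_seqs, query_catalog, foreign_seqs, foreign_catalog,
                      min_identity = 0, min_coverage = 0, min_shared = 10L,
                      max_candidates = 5L, same_chrom_only = TRUE,
                      band_frac = 0.05) {
  empty <- tibble(query_gene_id = character(), query_genome = character(),
                  query_chrom = integer(), query_haplotype = integer(),
                  query_rank = integer(), target_genome = character(),
                  target_haplotype = integer(), target_gene_id = character(),
                  target_chrom = integer(), target_rank = integer(),
                  identity = double(), coverage_query = double(),
                  coverage_target = double(), score = double())
  if (nrow(foreign_catalog) == 0 || nrow(query_catalog) == 0) return(empty)

  qs <- locus_sketches(query_seqs[query_catalog$gene_id])
  fs <- locus_sketches(foreign_seqs[foreign_catalog$gene_id])
  qmeta <- query_catalog %>%
    select(query_gene_id = "gene_id", query_genome = "genome",
           query_chrom = "chrom", query_haplotype = "haplotype",
           query_rank = "rank")
  fmeta <- foreign_catalog %>%
    select(target_gene_id = "gene_id", target_genome = "genome",
           target_chrom = "chrom", target_haplotype = "haplotype",
           target_rank = "rank")

  cand <- inner_join(rename(qs, query_gene_id = "gene_id"),
                     rename(fs, target_gene_id = "gene_id"),
                     by = "hash", relationship = "many-to-many") %>%
    count(.data$query_gene_id, .data$target_gene_id, name = "shared") %>%
    filter(.data$shared >= min_shared) %>%
    left_join(qmeta, by = "query_gene_id") %>%
    left_join(fmeta, by = "target_gene_id")
  if (same_chrom_only) {
    cand <- filter(cand, .data$target_chrom == .data$query_chrom)
  }
  if (nrow(cand) == 0) return(empty)
  cand <- cand %>%
    group_by(.data$query_gene_id, .data$target_genome, .data$target_haplotype) %>%
    filter(.data$shared >= 0.5 * max(.data$shared)) %>%
    slice_max(.data$shared, n = max_candidates, with_ties = FALSE) %>%
    ungroup()
  if (nrow(cand) == 0) return(empty)

  scores <- score_pairs_fast(query_seqs[cand$query_gene_id],
                             foreign_seqs[cand$target_gene_id], band_frac)
  scores$query_gene_id <- cand$query_gene_id
  scores$target_gene_id <- cand$target_gene_id

  cand %>%
    left_join(scores, by = c("query_gene_id", "target_gene_id")) %>%
    filter(!.data$low, .data$identity >= min_identity,
           .data$coverage_query >= min_coverage) %>%
    mutate(score = .data$identity * .data$coverage_query) %>%
    group_by(.data$query_gene_id, .data$target_genome, .data$target_haplotype) %>%
    arrange(dplyr::desc(.data$score), dplyr::desc(.data$identity),
            .data$target_gene_id, .by_group = TRUE) %>%
    dplyr::slice(1L) %>%
    ungroup() %>%
    select(all_of(names(empty))) %>%
    arrange(.data$query_genome, .data$query_chrom, .data$query_haplotype,
            .data$query_rank, .data$target_genome, .data$target_haplotype)
}

#' Import externally produced PAF alignments as best hits
#'
#' Drop-in replacement for the internal scorer at real scale: PAF records
#' whose query/target ids are locus ids are filtered and reduced to the
#' best hit per (query locus, foreign genome, haplotype) under the same
#' ranking key as [best_hits()].
#'
#' @param paf Tibble from [read_paf()], query/target ids being `gene_id`s.
#' @param query_catalog,foreign_catalog Catalogs giving locus metadata.
#' @inheritParams best_hits
#' @return Best-hit tibble in the [best_hits()] layout.
#' @export
best_hits_from_paf <- function(paf, query_catalog, foreign_catalog,
                               min_identity = 0, min_coverage = 0) {
  qmeta <- query_catalog %>%
    select(query_gene_id = "gene_id", query_genome = "genome",
           query_chrom = "chrom", query_haplotype = "haplotype",
           query_rank = "rank")
  fmeta <- foreign_catalog %>%
    select(target_gene_id = "gene_id", target_genome = "genome",
           target_chrom = "chrom", target_haplotype = "haplotype",
           target_rank = "rank")
  paf %>%
    mutate(coverage_target = (.data$target_end - .data$target_start) /
             pmax(.data$target_len, 1L)) %>%
    select(query_gene_id = "query_id", target_gene_id = "target_id",
           "identity", coverage_query = "coverage_query", "coverage_target") %>%
    inner_join(qmeta, by = "query_gene_id") %>%
    inner_join(fmeta, by = "target_gene_id") %>%
    filter(.data$identity >= min_identity, .data$coverage_query >= min_coverage) %>%
    mutate(score = .data$identity * .data$coverage_query) %>%
    group_by(.data$query_gene_id, .data$target_genome, .data$target_haplotype) %>%
    arrange(dplyr::desc(.data$score), dplyr::desc(.data$identity),
            .data$target_gene_id, .by_group = TRUE) %>%
    dplyr::slice(1L) %>%
    ungroup() %>%
    select("query_gene_id", "query_genome", "query_chrom", "query_haplotype",
           "query_rank", "target_genome", "target_haplotype", "target_gene_id",
           "target_chrom", "target_rank", "identity", "coverage_query",
           "coverage_target", "score")
}
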