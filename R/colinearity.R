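# Colinear gene blocks between haplotypes from filtered locus anchors, and
# locus-/length-level colinearity coverage.

#' Build colinearity anchors from best hits
#'
#' A hit becomes an anchor when it passes the retention floors
#' (identity and query coverage > `min_identity` / `min_coverage`) and the
#' dual-fraction overlap rule: the aligned span must cover at least
#' `f_query` of the query locus, and the target locus must cover at least
#' `f_span` of the aligned span. One anchor per locus pair.
#'
#' @param hits Best-hit tibble restricted to one (unit a, unit b) pair
#'   (either or both directions; duplicates are collapsed).
#' @param catalog Locus catalog providing positions for block spans.
#' @param min_identity,min_coverage Retention floors (exclusive).
#' @param f_query Minimum fraction of the query locus covered by the
#'   aligned span.
#' @param f_span Minimum fraction of the aligned span covered by the
#'   target locus.
#' @return Anchor tibble: `gene_a`, `gene_b`, `rank_a`, `rank_b`,
#'   `a_start`, `a_end`, `b_start`, `b_end`, `identity`, `coverage`.
#' @export
build_anchors <- function(hits, catalog, min_identity = 0.8,
                          min_coverage = 0.8, f_query = 0.5, f_span = 0.75) {
  if (nrow(hits) == 0) {
    return(tibble(gene_a = character(), gene_b = character(),
                  rank_a = integer(), rank_b = integer(),
                  a_start = integer(), a_end = integer(),
                  b_start = integer(), b_end = integer(),
                  identity = double(), coverage = double()))
  }
  # the aligned span sits inside both loci (locus-to-locus alignment), so
  # the span fraction covered by the target locus is 1; the query-side
  # fraction is the query coverage
  f2 <- 1.0
  h <- hits %>%
    filter(.data$identity > min_identity, .data$coverage_query > min_coverage,
           .data$coverage_query >= f_query, f2 >= f_span)
  pos <- catalog %>% select("gene_id", "start", "end")
  h %>%
    left_join(rename(pos, a_start = "start", a_end = "end"),
              by = c(query_gene_id = "gene_id")) %>%
    left_join(rename(pos, b_start = "start", b_end = "end"),
              by = c(target_gene_id = "gene_id")) %>%
    mutate(pair = paste(pmin(.data$query_gene_id, .data$target_gene_id),
                        pmax(.data$query_gene_id, .data$target_gene_id))) %>%
    distinct(.data$pair, .keep_all = TRUE) %>%
    select(gene_a = "query_gene_id", gene_b = "target_gene_id",
           rank_a = "query_rank", rank_b = "target_rank",
           "a_start", "a_end", "b_start", "b_end",
           "identity", coverage = "coverage_query") %>%
    arrange(.data$rank_a, .data$rank_b)
}

# one round of chain DP over the remaining anchors; returns indices of the
# best chain for one orientation
chain_round <- function(rank_a, rank_b, max_gap, antiparallel = FALSE) {
  n <- length(rank_a)
  if (n == 0) return(integer(0))
  ord <- order(rank_a, if (antiparallel) -rank_b else rank_b)
  ra <- rank_a[ord]; rb <- rank_b[ord]
  dp <- rep(1L, n); par <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      ok_a <- ra[j] < ra[i] && ra[i] - ra[j] <= max_gap + 1L
      ok_b <- if (antiparallel) {
        rb[j] > rb[i] && rb[j] - rb[i] <= max_gap + 1L
      } else {
        rb[j] < rb[i] && rb[i] - rb[j] <= max_gap + 1L
      }
      if (ok_a && ok_b && dp[j] + 1L > dp[i]) {
        dp[i] <- dp[j] + 1L; par[i] <- j
      }
    }
  }
  best <- which.max(dp)
  chain <- integer(0)
  cur <- best
  while (cur != 0L) { chain <- c(cur, chain); cur <- par[cur] }
  ord[chain]
}

#' Chain anchors into colinear blocks
#'
#' Dynamic programming over anchors sorted by query rank; the chain score is
#' the anchor count, extension requires rank gaps of at most `max_gap` on
#' both sides, and both orientations (parallel and antiparallel) are
#' searched. Blocks are extracted best-first with anchors marked used (so
#' reported blocks have disjoint anchor sets, subsuming the
#' `overlap_window` merge-or-best-kept rule); chains shorter than
#' `match_size` are discarded.
#'
#' @param anchors Anchor tibble from [build_anchors()].
#' @param match_size Minimum anchors per block.
#' @param max_gap Maximum rank gap (in loci) on either side.
#' @param overlap_window Retained for interface compatibility; block
#'   extraction keeps anchor sets disjoint.
#' @return Block tibble: `orientation`, `n_anchors`, `a_start`, `a_end`,
#'   `b_start`, `b_end`, `anchors` (list column of the block's anchors).
#' @export
chain_blocks <- function(anchors, match_size = 10L, max_gap = 5L,
                         overlap_window = 5L) {
  empty <- tibble(orientation = character(), n_anchors = integer(),
                  a_start = integer(), a_end = integer(),
                  b_start = integer(), b_end = integer(),
                  anchors = list())
  if (nrow(anchors) == 0) return(empty)
  remaining <- anchors
  blocks <- list()
  repeat {
    if (nrow(remaining) == 0) break
    ch_par <- chain_round(remaining$rank_a, remaining$rank_b, max_gap, FALSE)
    ch_anti <- chain_round(remaining$rank_a, remaining$rank_b, max_gap, TRUE)
    use_par <- length(ch_par) >= length(ch_anti)
    ch <- if (use_par) ch_par else ch_anti
    if (length(ch) < match_size) break
    blk <- remaining[ch, , drop = FALSE]
    blocks[[length(blocks) + 1L]] <- tibble(
      orientation = if (use_par) "parallel" else "antiparallel",
      n_anchors = nrow(blk),
      a_start = min(blk$a_start), a_end = max(blk$a_end),
      b_start = min(blk$b_start), b_end = max(blk$b_end),
      anchors = list(blk))
    remaining <- remaining[-ch, , drop = FALSE]
  }
  if (length(blocks) == 0) return(empty)
  bind_rows(blocks) %>% arrange(dplyr::desc(.data$n_anchors), .data$a_start)
}

#' Locus- and length-level colinearity coverage for one unit pair
#'
#' @param blocks Block tibble from [chain_blocks()].
#' @param n_loci_a,n_loci_b Total locus counts of the two units.
#' @param len_a,len_b Sequence lengths of the two units.
#' @return One-row tibble: `loci_in_blocks`, `total_loci`, `locus_pct`,
#'   `covered_bp`, `total_bp`, `length_pct`.
#' @export
coverage_stats <- function(blocks, n_loci_a, n_loci_b, len_a, len_b) {
  if (nrow(blocks) == 0) {
    return(tibble(loci_in_blocks = 0L, total_loci = n_loci_a + n_loci_b,
                  locus_pct = 0, covered_bp = 0, total_bp = len_a + len_b,
                  length_pct = 0))
  }
  all_anchors <- bind_rows(blocks$anchors)
  n_in <- dplyr::n_distinct(all_anchors$gene_a) + dplyr::n_distinct(all_anchors$gene_b)
  union_bp <- function(starts, ends, cap) {
    ir <- IRanges::IRanges(start = pmax(starts, 0L) + 1L, end = pmin(ends, cap))
    sum(IRanges::width(IRanges::reduce(ir)))
  }
  cov <- union_bp(blocks$a_start, blocks$a_end, len_a) +
    union_bp(blocks$b_start, blocks$b_end, len_b)
  tibble(loci_in_blocks = n_in, total_loci = n_loci_a + n_loci_b,
         locus_pct = 100 * n_in / (n_loci_a + n_loci_b),
         covered_bp = cov, total_bp = len_a + len_b,
         length_pct = 100 * cov / (len_a + len_b))
}

#' Colinearity analysis across a labeled trio
#'
#' For every cross-genome pair of species-coherent haploid units and every
#' chromosome: anchors are built from the best hits between the two units,
#' chained into blocks, and coverage is aggregated per unit pair, then
#' summarized by group (shared vs different parental species).
#'
#' @param hits Best-hit tibble across the trio.
#' @param catalog Locus catalog.
#' @param assemblies Named list of [diploid_assembly()] objects.
#' @param labeling Per-chromosome labeling from [label_chromosomes()].
#' @param ... Passed to [build_anchors()] and [chain_blocks()]
#'   (`min_identity`, `min_coverage`, `match_size`, `max_gap`).
#' @param match_size,max_gap Chaining parameters.
#' @param min_identity,min_coverage Anchor retention floors.
#' @return List: `pair_stats` (per unit pair), `summary` (group means),
#'   `blocks` (all blocks with pair annotations).
#' @export
colinearity_analysis <- function(hits, catalog, assemblies, labeling,
                                 min_identity = 0.8, min_coverage = 0.8,
                                 match_size = 10L, max_gap = 5L) {
  units <- labeling %>% distinct(.data$genome, .data$species) %>%
    arrange(.data$genome, .data$species)
  chroms <- sort(unique(labeling$chrom))
  hap_of <- function(g, sp, ch) {
    labeling$haplotype[labeling$genome == g & labeling$species == sp &
                         labeling$chrom == ch]
  }
  pair_rows <- list(); block_rows <- list()
  for (i in seq_len(nrow(units) - 1L)) {
    for (j in seq((i + 1L), nrow(units))) {
      ga <- units$genome[i]; sa <- units$species[i]
      gb <- units$genome[j]; sb <- units$species[j]
      per_chrom <- purrr::map_dfr(chroms, function(ch) {
        ha <- hap_of(ga, sa, ch); hb <- hap_of(gb, sb, ch)
        h_ab <- hits %>% filter(.data$query_genome == ga,
                                .data$query_chrom == ch,
                                .data$query_haplotype == ha,
                                .data$target_genome == gb,
                                .data$target_haplotype == hb,
                                .data$target_chrom == ch)
        anc <- build_anchors(h_ab, catalog, min_identity, min_coverage)
        blk <- chain_blocks(anc, match_size = match_size, max_gap = max_gap)
        n_a <- sum(catalog$genome == ga & catalog$chrom == ch &
                     catalog$haplotype == ha)
        n_b <- sum(catalog$genome == gb & catalog$chrom == ch &
                     catalog$haplotype == hb)
        cs <- coverage_stats(blk, n_a, n_b,
                             nchar(assembly_seq(assemblies[[ga]], ch, ha)),
                             nchar(assembly_seq(assemblies[[gb]], ch, hb)))
        if (nrow(blk) > 0) {
          block_rows[[length(block_rows) + 1L]] <<- mutate(
            select(blk, -"anchors"),
            ref_genome = ga, ref_species = sa, other_genome = gb,
            other_species = sb, chrom = ch)
        }
        cs
      })
      pair_rows[[length(pair_rows) + 1L]] <- tibble(
        ref_genome = ga, ref_species = sa,
        other_genome = gb, other_species = sb,
        shared = sa == sb,
        loci_in_blocks = sum(per_chrom$loci_in_blocks),
        total_loci = sum(per_chrom$total_loci),
        locus_pct = 100 * sum(per_chrom$loci_in_blocks) / sum(per_chrom$total_loci),
        covered_bp = sum(per_chrom$covered_bp),
        total_bp = sum(per_chrom$total_bp),
        length_pct = 100 * sum(per_chrom$covered_bp) / sum(per_chrom$total_bp))
    }
  }
  pair_stats <- bind_rows(pair_rows)
  summary <- tibble(
    locus_pct_shared = mean(pair_stats$locus_pct[pair_stats$shared]),
    locus_pct_nonshared = mean(pair_stats$locus_pct[!pair_stats$shared]),
    length_pct_overall = mean(pair_stats$length_pct))
  list(pair_stats = pair_stats, summary = summary,
       blocks = if (length(block_rows) > 0) bind_rows(block_rows) else tibble())
}
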