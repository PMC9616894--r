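# Anchor filtering, block chaining and colinearity coverage.

mk_anchor_hits <- function(n, chrom = 1L, identity = 0.95, coverage = 0.95,
                           rank_b = seq_len(n)) {
  tibble::tibble(
    query_gene_id = sprintf("qa%03d", seq_len(n)),
    query_genome = "ga", query_chrom = chrom, query_haplotype = 1L,
    query_rank = seq_len(n),
    target_genome = "gb", target_haplotype = 1L,
    target_gene_id = sprintf("tb%03d", rank_b),
    target_chrom = chrom, target_rank = rank_b,
    identity = identity, coverage_query = coverage, coverage_target = coverage,
    score = identity * coverage)
}

mk_cat <- function(hits) {
  tibble::tibble(
    gene_id = c(hits$query_gene_id, hits$target_gene_id),
    start = c(hits$query_rank, hits$target_rank) * 1000L,
    end = c(hits$query_rank, hits$target_rank) * 1000L + 500L)
}

test_that("anchor filters enforce coverage fractions and retention floors", {
  hits <- mk_anchor_hits(3)
  hits$coverage_query <- c(0.9, 0.4, 0.85)
  cat_tbl <- mk_cat(hits)
  anc <- build_anchors(hits, cat_tbl)
  # 90% query coverage passes; 40% fails the 50% rule (and the 80% floor)
  expect_identical(anc$gene_a, c("qa001", "qa003"))
  hits$coverage_query <- 0.95
  hits$identity <- c(0.95, 0.75, 0.95)
  anc2 <- build_anchors(hits, cat_tbl)
  expect_identical(nrow(anc2), 2L)   # 0.75 identity dropped by the 0.8 floor

  # monotonicity: raising min_identity never increases the anchor count
  set.seed(9)
  hits3 <- mk_anchor_hits(40, identity = runif(40, 0.7, 1))
  cat3 <- mk_cat(hits3)
  counts <- vapply(c(0.7, 0.8, 0.9, 0.95),
                   function(t) nrow(build_anchors(hits3, cat3, min_identity = t)), 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("perfectly colinear anchors chain into one block per orientation", {
  hits <- mk_anchor_hits(12)
  anc <- build_anchors(hits, mk_cat(hits))
  blk <- chain_blocks(anc, match_size = 10L)
  expect_identical(nrow(blk), 1L)
  expect_identical(blk$orientation, "parallel")
  expect_identical(blk$n_anchors, 12L)

  # strictly decreasing target ranks -> one antiparallel block
  hits_inv <- mk_anchor_hits(12, rank_b = 12:1)
  blk_inv <- chain_blocks(build_anchors(hits_inv, mk_cat(hits_inv)),
                          match_size = 10L)
  expect_identical(nrow(blk_inv), 1L)
  expect_identical(blk_inv$orientation, "antiparallel")
})

test_that("a rank gap beyond max_gap splits chains; short segments are discarded", {
  # 20 colinear anchors with a rank gap of 7 after the 12th
  hits <- mk_anchor_hits(20)
  hits$query_rank[13:20] <- hits$query_rank[13:20] + 7L
  hits$target_rank[13:20] <- hits$target_rank[13:20] + 7L
  anc <- build_anchors(hits, mk_cat(hits))
  blk <- chain_blocks(anc, match_size = 10L, max_gap = 5L)
  expect_identical(nrow(blk), 1L)        # only the 12-anchor segment survives
  expect_identical(blk$n_anchors, 12L)
  blk2 <- chain_blocks(anc, match_size = 5L, max_gap = 5L)
  expect_identical(sort(blk2$n_anchors), c(8L, 12L))
})

test_that("chaining matches the exhaustive oracle on random small instances", {
  set.seed(123)
  for (i in 1:30) {
    n <- sample(4:12, 1)
    anc <- tibble::tibble(
      gene_a = sprintf("a%d", seq_len(n)), gene_b = sprintf("b%d", seq_len(n)),
      rank_a = sample(1:20, n), rank_b = sample(1:20, n),
      a_start = 0L, a_end = 1L, b_start = 0L, b_end = 1L,
      identity = 0.95, coverage = 0.95)
    got <- chain_blocks(anc, match_size = 1L, max_gap = 4L)
    expect_identical(max(got$n_anchors),
                     oracle_best_chain(anc$rank_a, anc$rank_b, 4L))
  }
})

test_that("coverage statistics count loci and union block extents", {
  expect_equal(coverage_stats(chain_blocks(tibble::tibble()[0, ]), 50L, 50L,
                              1000L, 1000L)$locus_pct, 0)
  # 80 of 100 loci in blocks
  hits <- mk_anchor_hits(40)
  anc <- build_anchors(hits, mk_cat(hits))
  blk <- chain_blocks(anc, match_size = 10L)
  cs <- coverage_stats(blk, 50L, 50L, 60000L, 60000L)
  expect_equal(cs$locus_pct, 100 * 80 / 100)
  # two overlapping blocks covering [0,100) and [50,200) of a 1000-bp unit
  blocks <- tibble::tibble(
    orientation = "parallel", n_anchors = c(10L, 10L),
    a_start = c(0L, 50L), a_end = c(100L, 200L),
    b_start = c(0L, 0L), b_end = c(1L, 1L),
    anchors = list(tibble::tibble(gene_a = "x", gene_b = "y"),
                   tibble::tibble(gene_a = "x", gene_b = "y")))
  cs2 <- coverage_stats(blocks, 1L, 1L, 1000L, 0L)
  expect_equal(cs2$covered_bp, 200)       # union of [0,100) and [50,200)
  expect_equal(100 * cs2$covered_bp / 1000, 20.0)
})

test_that("noise-free trios are fully colinear with parallel blocks", {
  trio <- tiny_noise0_trio()
  hits <- trio_best_hits(trio$assemblies, trio$catalog, include_sibling = TRUE)
  lab <- label_chromosomes(hits, trio$design, 1L)
  col <- colinearity_analysis(hits, trio$catalog, trio$assemblies, lab)
  expect_equal(col$summary$locus_pct_shared, 100)
  expect_equal(col$summary$locus_pct_nonshared, 100)
  expect_true(all(col$blocks$orientation == "parallel"))
  expect_identical(nrow(col$pair_stats), 15L)
  expect_identical(sum(col$pair_stats$shared), 3L)
})
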