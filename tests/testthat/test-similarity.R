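# Locus extraction and the two-stage similarity scorer.

test_that("locus sequences extract by genomic span with strand handling", {
  seqs <- setNames(c("AAAACGTAAAGG", "AAAACGTAAAGG"),
                   c(seq_name(1, 1), seq_name(1, 2)))
  asm <- diploid_assembly("g", seqs)
  cat_tbl <- tibble::tibble(
    gene_id = c("p", "m"), genome = "g", chrom = 1L, haplotype = c(1L, 2L),
    start = c(3L, 3L), end = c(7L, 7L), strand = c("+", "-"), rank = 1L)
  out <- extract_locus_sequences(asm, cat_tbl)
  expect_identical(out[["p"]], "ACGT")
  expect_identical(out[["m"]], "ACGT")  # reverse complement of ACGT
  cat_tbl$strand <- c("+", "+")
  cat_tbl$end[1] <- 99L
  expect_error(extract_locus_sequences(asm, cat_tbl), "out of bounds.*p")
})

test_that("all loci of a synthetic catalog extract with length end - start", {
  trio <- tiny_noise0_trio()
  for (g in names(trio$assemblies)) {
    cc <- dplyr::filter(trio$catalog, genome == g)
    out <- extract_locus_sequences(trio$assemblies[[g]], cc)
    expect_identical(unname(nchar(out[cc$gene_id])), cc$end - cc$start)
  }
})

test_that("score_pair matches direct expectations and the alignment oracle", {
  set.seed(21)
  a <- random_seq(300)
  sp <- score_pair(a, a)
  expect_equal(sp$identity, 1.0)
  expect_equal(sp$coverage_a, 1.0)
  expect_equal(sp$coverage_b, 1.0)

  # 5 substitutions in 100 bp -> identity 0.95 (any optimal alignment)
  b <- random_seq(100)
  b2 <- b
  for (p in c(10, 30, 50, 70, 90)) {
    old <- substr(b2, p, p)
    substr(b2, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  expect_equal(score_pair(b, b2, mode = "global")$identity, 0.95)
  expect_equal(oracle_global_identity(b, b2), 0.95)

  # query equal to a substring of a double-length target
  long <- random_seq(200)
  q <- substring(long, 51, 150)
  sp <- score_pair(q, long)
  expect_equal(sp$identity, 1.0)
  expect_equal(sp$coverage_a, 1.0)
  expect_equal(sp$coverage_b, 0.5)
})

test_that("identity is symmetric and N-dense sequences are flagged", {
  set.seed(8)
  for (i in 1:10) {
    a <- random_seq(150 + i)
    b <- random_seq(150)
    expect_identical(score_pair(a, b)$identity, score_pair(b, a)$identity)
  }
  n_heavy <- paste(c(rep("N", 80), strsplit(random_seq(20), "")[[1]]), collapse = "")
  expect_true(score_pair(n_heavy, random_seq(100))$low_confidence)
  expect_error(score_pair("", "ACGT"), "empty")
})

test_that("best_hits picks the true ortholog over a paralog and honors floors", {
  set.seed(31)
  tmpl <- random_seq(600)
  mutate_n <- function(s, k) {
    for (p in sample(nchar(s), k)) {
      old <- substr(s, p, p)
      substr(s, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
    }
    s
  }
  q_seqs <- c(q1 = tmpl)
  f_seqs <- c(ortho = mutate_n(tmpl, 12),   # ~0.98 identity
              para = mutate_n(tmpl, 90))    # ~0.85 identity
  q_cat <- tibble::tibble(gene_id = "q1", genome = "gq", chrom = 1L,
                          haplotype = 1L, start = 0L, end = 600L,
                          strand = "+", rank = 1L)
  f_cat <- tibble::tibble(gene_id = c("ortho", "para"), genome = "gf",
                          chrom = 1L, haplotype = 1L,
                          start = c(0L, 700L), end = c(600L, 1300L),
                          strand = "+", rank = 1:2)
  bh <- best_hits(q_seqs, q_cat, f_seqs, f_cat, min_shared = 3L)
  expect_identical(bh$target_gene_id, "ortho")
  expect_gt(bh$identity, 0.95)
  # floors drop sub-threshold matches
  bh2 <- best_hits(q_seqs, q_cat, f_seqs["para"], f_cat[2, ],
                   min_identity = 0.9, min_shared = 3L)
  expect_identical(nrow(bh2), 0L)
  # empty foreign catalog
  expect_identical(nrow(best_hits(q_seqs, q_cat, character(), f_cat[0, ])), 0L)
})

test_that("best_hits equals brute-force all-pairs scoring on small catalogs", {
  trio <- tiny_noise0_trio()
  g <- "hybAB"; og <- c("hybBC", "hybAC")
  q_cat <- dplyr::filter(trio$catalog, genome == g, rank <= 15)
  f_cat <- dplyr::filter(trio$catalog, genome %in% og, rank <= 15)
  q_seqs <- extract_locus_sequences(trio$assemblies[[g]], q_cat)
  f_seqs <- c(extract_locus_sequences(trio$assemblies[[og[1]]], f_cat),
              extract_locus_sequences(trio$assemblies[[og[2]]], f_cat))
  bh <- best_hits(q_seqs, q_cat, f_seqs, f_cat)
  # brute force: score every pair, rank by (identity * coverage, identity, id)
  brute <- purrr::map_dfr(q_cat$gene_id, function(q) {
    purrr::map_dfr(f_cat$gene_id, function(t) {
      sc <- score_pair(q_seqs[[q]], f_seqs[[t]], band_frac = 0.05)
      tibble::tibble(query_gene_id = q, target_gene_id = t,
                     target_genome = f_cat$genome[f_cat$gene_id == t],
                     target_haplotype = f_cat$haplotype[f_cat$gene_id == t],
                     identity = sc$identity, coverage_query = sc$coverage_a)
    })
  }) %>%
    dplyr::mutate(score = identity * coverage_query) %>%
    dplyr::group_by(query_gene_id, target_genome, target_haplotype) %>%
    dplyr::arrange(dplyr::desc(score), dplyr::desc(identity), target_gene_id,
                   .by_group = TRUE) %>%
    dplyr::slice(1L) %>%
    dplyr::ungroup()
  joined <- dplyr::inner_join(
    bh, brute,
    by = c("query_gene_id", "target_genome", "target_haplotype"),
    suffix = c("", ".brute"))
  expect_identical(nrow(joined), nrow(bh))
  expect_identical(joined$target_gene_id, joined$target_gene_id.brute)
  expect_equal(joined$identity, joined$identity.brute)
  # noise-0 trio: every shared-species best hit has identity 1.0
  lab <- trio$truth_labels
  shared <- dplyr::inner_join(
    bh,
    dplyr::inner_join(
      dplyr::select(dplyr::filter(trio$catalog, genome == g), gene_id, haplotype),
      dplyr::select(dplyr::filter(lab, genome == g), haplotype, species),
      by = "haplotype"),
    by = c(query_gene_id = "gene_id", query_haplotype = "haplotype")) %>%
    dplyr::inner_join(dplyr::select(dplyr::filter(lab, genome != g),
                                    genome, haplotype, species),
                      by = c(target_genome = "genome",
                             target_haplotype = "haplotype",
                             species = "species"))
  expect_gt(nrow(shared), 0)
  expect_true(all(shared$identity == 1.0))
})
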