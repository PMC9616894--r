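# Desk-scale haplotype alignment, the unaffected-length statistic, and the
# rank-sum test.

test_that("identical sequences yield an empty variant set", {
  set.seed(5)
  s <- random_seq(20000)
  expect_identical(nrow(align_haplotypes(s, s)), 0L)
})

test_that("planted SNPs, a short indel and an SV are recovered and classified", {
  set.seed(6)
  ref <- random_seq(10000)
  oth <- ref
  # 20 substitutions, well separated
  snp_pos <- seq(200, 5900, by = 300)
  for (p in snp_pos) {
    old <- substr(oth, p, p)
    substr(oth, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  # one 10-bp deletion at 7000 and one 100-bp deletion at 8500 (apply
  # right-to-left so positions stay valid)
  oth <- paste0(substr(oth, 1, 8500), substr(oth, 8601, 10000))
  oth <- paste0(substr(oth, 1, 7000), substr(oth, 7011, nchar(oth)))
  v <- align_haplotypes(ref, oth)
  expect_identical(sum(v$kind == "SNP"), 20L)
  expect_identical(sum(v$kind == "INDEL"), 1L)
  expect_identical(sum(v$kind == "SV"), 1L)
  ind <- v[v$kind == "INDEL", ]
  expect_identical(ind$ref_end - ind$ref_start, 10L)
  sv <- v[v$kind == "SV", ]
  expect_identical(sv$ref_end - sv$ref_start, 100L)
  # the resulting similarity: 20 + 10 + 100 = 130 affected bp of 10 kbp
  uf <- unaffected_fraction(dplyr::mutate(v, ref_name = "c"), c(c = 10000L))
  expect_equal(uf$similarity_pct, 98.7)
})

test_that("recovered SNP counts track planted counts within 10%", {
  for (sd in 1:5) {
    m <- ancestor_model(n_chromosomes = 1L, chrom_length = 60000L,
                        n_genes_per_chrom = 10L, snp_rate = 0.01,
                        indel_rate = 0, sv_count_per_chrom = 0L, seed = sd)
    anc <- simulate_ancestors(m)
    planted <- sum(anc$edits$species == "spB" & anc$edits$kind == "SNP")
    v <- align_haplotypes(anc$species$spA[["1"]], anc$species$spB[["1"]])
    got <- sum(v$kind == "SNP")
    expect_lt(abs(got - planted) / planted, 0.10)
  }
})

test_that("applying the variant set as edits reconstructs the other sequence", {
  for (sd in 1:3) {
    set.seed(sd)
    ref <- random_seq(50000)
    ed <- haplotrio:::gen_edits(ref, 0.005, 0.001, 10L, 0L, c(100L, 200L))
    oth <- haplotrio:::apply_edits(ref, ed)
    v <- align_haplotypes(ref, oth)
    # rebuild `oth` from `ref` using the variants' coordinates on both sides
    v <- dplyr::arrange(v, ref_start)
    pieces <- character(0)
    prev <- 0L
    for (i in seq_len(nrow(v))) {
      pieces <- c(pieces, substring(ref, prev + 1L, v$ref_start[i]),
                  substring(oth, v$other_start[i] + 1L, v$other_end[i]))
      prev <- v$ref_end[i]
    }
    pieces <- c(pieces, substring(ref, prev + 1L, nchar(ref)))
    expect_identical(paste(pieces, collapse = ""), oth)
  }
})

test_that("unaffected_fraction unions overlapping spans and checks bounds", {
  v <- tibble::tibble(
    kind = c("INDEL", "INDEL", "SNP", "SNP", "SNP"),
    ref_name = "c",
    ref_start = c(10L, 15L, 100L, 200L, 300L),
    ref_end = c(20L, 25L, 101L, 201L, 301L))
  uf <- unaffected_fraction(v, c(c = 10000L))
  expect_equal(uf$affected_bp, 18)   # union(10..20, 15..25) = 15, + 3 SNPs
  expect_equal(uf$similarity_pct, 99.82)
  expect_equal(unaffected_fraction(v[0, ], c(c = 500L))$similarity_pct, 100.0)
  bad <- dplyr::mutate(v, ref_start = ref_start + 9990L, ref_end = ref_end + 9990L)
  expect_error(unaffected_fraction(bad, c(c = 10000L)), "bounds")
})

test_that("unaffected_fraction equals the per-base oracle on random inputs", {
  set.seed(77)
  for (i in 1:20) {
    len <- sample(1000:100000, 1)
    nv <- sample(0:60, 1)
    v <- tibble::tibble(
      kind = sample(c("SNP", "INDEL", "SV"), nv, replace = TRUE),
      ref_name = "c",
      ref_start = sort(sample(0:(len - 200L), nv)))
    v$ref_end <- pmin(len, v$ref_start +
                        ifelse(v$kind == "SNP", 1L,
                               ifelse(v$kind == "INDEL", sample(0:50, nv, TRUE),
                                      sample(51:150, nv, TRUE))))
    got <- unaffected_fraction(v, c(c = len))$similarity_pct
    expect_equal(got, oracle_unaffected_pct(v, c(c = len)))
  }
})

test_that("rank-sum examples match exhaustive enumeration", {
  rs <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_identical(rs$W, 0)
  expect_equal(rs$p_value, 0.1)
  expect_identical(rs$method, "exact")
  orc <- oracle_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_identical(orc$W, 0)
  expect_equal(orc$p, 0.1)

  same <- rank_sum_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$p_value, 1.0)
  expect_identical(same$method, "exact")

  expect_error(rank_sum_test(numeric(0), 1), "non-empty")
  # broom-style accessors
  expect_identical(names(glance(rs)),
                   c("statistic", "p.value", "method", "n1", "n2"))
  expect_identical(nrow(tidy(rs)), 2L)
})

test_that("the normal approximation reproduces the printed headline test", {
  # group sizes 6 vs 24, W = 142, continuity-corrected normal approximation
  p <- haplotrio:::rank_sum_normal_p(142, 6, 24)
  expect_equal(signif(p, 1), 3e-04)
  # and the statistic definition agrees with stats::wilcox.test's W
  set.seed(12)
  g1 <- rnorm(10); g2 <- rnorm(15)
  expect_equal(rank_sum_test(g1, g2)$W,
               unname(stats::wilcox.test(g1, g2)$statistic))
})

test_that("grouped similarity compares 6 shared vs 24 non-shared directional pairs", {
  trio <- tiny_noise0_trio()
  hits <- trio_best_hits(trio$assemblies, trio$catalog)
  lab <- label_chromosomes(hits, trio$design, 1L)
  div <- grouped_similarity(trio$assemblies, lab)
  expect_identical(length(div$shared_group), 6L)
  expect_identical(length(div$nonshared_group), 24L)
  expect_identical(nrow(div$pair_table), 30L)
  # zero within-species noise: shared pairs are perfectly similar
  expect_true(all(div$shared_group == 100.0))
  expect_true(all(div$nonshared_group < 100.0))
  g <- glance(div)
  expect_identical(g$n_shared, 6L)
  expect_s3_class(autoplot(div), "ggplot")
})
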