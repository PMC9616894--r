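# Synthetic trio generator: divergence realization, hybrid composition,
# switch injection and its invariants.

test_that("zero divergence yields three identical ancestors", {
  m <- ancestor_model(n_chromosomes = 1L, chrom_length = 20000L,
                      n_genes_per_chrom = 5L, snp_rate = 0,
                      indel_rate = 0, sv_count_per_chrom = 0L, seed = 3L)
  anc <- simulate_ancestors(m)
  expect_identical(anc$species$spB, anc$species$spA)
  expect_identical(anc$species$spC, anc$species$spA)
})

test_that("realized SNP counts stay within 4 sigma of the binomial law", {
  m <- ancestor_model(n_chromosomes = 1L, chrom_length = 1000000L,
                      n_genes_per_chrom = 50L, snp_rate = 0.005,
                      indel_rate = 0, sv_count_per_chrom = 0L, seed = 11L)
  anc <- simulate_ancestors(m)
  for (sp in c("spB", "spC")) {
    n <- sum(anc$edits$species == sp & anc$edits$kind == "SNP")
    expect_gte(n, 4717)
    expect_lte(n, 5283)
  }
})

test_that("the generator is deterministic for a fixed seed", {
  m <- ancestor_model(n_chromosomes = 1L, chrom_length = 30000L,
                      n_genes_per_chrom = 8L, seed = 9L)
  t1 <- suppressMessages(simulate_trio(m, k_switches = 1L, min_sep = 3L,
                                       edge_margin = 3L))
  t2 <- suppressMessages(simulate_trio(m, k_switches = 1L, min_sep = 3L,
                                       edge_margin = 3L))
  for (g in names(t1$assemblies)) {
    expect_identical(t1$assemblies[[g]]$seqs, t2$assemblies[[g]]$seqs)
  }
  expect_identical(as.data.frame(t1$truth_switches),
                   as.data.frame(t2$truth_switches))
  # byte-identical FASTA output
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fasta(t1$assemblies$hybAB$seqs, f1)
  write_fasta(t2$assemblies$hybAB$seqs, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("the triangle design places each species in exactly two genomes", {
  trio <- tiny_noise0_trio()
  lab <- trio$truth_labels
  per_species <- table(unique(lab[, c("genome", "species")])$species)
  expect_true(all(per_species == 2))
  # zero within-species noise: shared haplotypes are identical across genomes
  for (sp in names(per_species)) {
    u <- lab[lab$species == sp & lab$chrom == 1, ]
    s1 <- assembly_seq(trio$assemblies[[u$genome[1]]], 1, u$haplotype[1])
    s2 <- assembly_seq(trio$assemblies[[u$genome[2]]], 1, u$haplotype[2])
    expect_identical(s1, s2)
  }
})

test_that("non-triangle pedigrees are refused", {
  expect_error(hybrid_design(list(a = c("x", "y"), b = c("x", "y"),
                                  c = c("x", "y"))), "triangle")
  expect_error(hybrid_design(list(a = c("x", "y"), b = c("y", "z"))),
               "three genomes")
})

test_that("AGP components re-concatenate to each pseudomolecule", {
  trio <- tiny_trio()
  for (g in names(trio$assemblies)) {
    asm <- trio$assemblies[[g]]
    for (nm in names(asm$seqs)) {
      a <- dplyr::arrange(dplyr::filter(asm$agp, object_id == nm), start)
      expect_identical(a$start[1], 0L)
      expect_identical(a$end[nrow(a)], nchar(asm$seqs[[nm]]))
      expect_true(all(a$start[-1] == a$end[-nrow(a)]))
    }
  }
})

test_that("k = 0 leaves the assembly unchanged with empty truth", {
  m <- tiny_model(seed = 5L)
  anc <- simulate_ancestors(m)
  trio <- compose_hybrids(anc)
  pre_seqs <- purrr::map(trio$assemblies, "seqs")
  out <- inject_switches(trio, 0L)
  expect_identical(purrr::map(out$assemblies, "seqs"), pre_seqs)
  expect_identical(nrow(out$truth_switches), 0L)
})

test_that("a single switch exchanges the suffixes at the recorded cuts", {
  trio <- cached_trio("k1", suppressMessages(
    simulate_trio(tiny_model(seed = 13L), k_switches = 1L)))
  tr <- trio$truth_switches
  expect_identical(nrow(tr), 3L)  # one per genome
  for (i in seq_len(nrow(tr))) {
    g <- tr$genome[i]; ch <- tr$chrom[i]
    post1 <- assembly_seq(trio$assemblies[[g]], ch, 1)
    post2 <- assembly_seq(trio$assemblies[[g]], ch, 2)
    pre1 <- assembly_seq(trio$pre$assemblies[[g]], ch, 1)
    pre2 <- assembly_seq(trio$pre$assemblies[[g]], ch, 2)
    c1 <- tr$cut_hap1[i]; c2 <- tr$cut_hap2[i]
    expect_identical(substring(post1, c1 + 1), substring(pre2, c2 + 1))
    expect_identical(substring(post2, c2 + 1), substring(pre1, c1 + 1))
    expect_identical(substring(post1, 1, c1), substring(pre1, 1, c1))
  }
})

test_that("injection is an involution and conserves per-chromosome base content", {
  trio <- cached_trio("k3", suppressMessages(
    simulate_trio(tiny_model(seed = 17L), k_switches = 3L, min_sep = 8L,
                  edge_margin = 5L)))
  # base multiset over hap1+hap2 invariant under injection
  for (g in names(trio$assemblies)) {
    expect_identical(
      haplotrio:::chrom_base_multiset(trio$assemblies[[g]], 1L),
      haplotrio:::chrom_base_multiset(trio$pre$assemblies[[g]], 1L))
  }
  # exchanging at the truth boundaries undoes the injection; exchanging the
  # undo plan restores the injected state byte-identically
  corr <- suppressMessages(apply_correction(trio$assemblies, trio$catalog,
                                            plans_from_truth(trio$truth_switches)))
  for (g in names(trio$assemblies)) {
    expect_identical(corr$assemblies[[g]]$seqs, trio$pre$assemblies[[g]]$seqs)
  }
  back <- suppressMessages(apply_correction(corr$assemblies, corr$catalog,
                                            corr$plans_undo))
  for (g in names(trio$assemblies)) {
    expect_identical(back$assemblies[[g]]$seqs, trio$assemblies[[g]]$seqs)
  }
})

test_that("orthologous gene counts are equal across species and hybrids", {
  trio <- tiny_trio()
  anc <- trio$ancestors
  counts <- dplyr::count(anc$catalogs, genome)
  expect_true(all(counts$n == counts$n[1]))
  hyb <- dplyr::count(trio$catalog, genome, haplotype)
  expect_true(all(hyb$n == hyb$n[1]))
})
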