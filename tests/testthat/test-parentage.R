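# Parent labeling and switch detection.

mk_hit <- function(qg, qh, tg, th, id, chrom = 1L, qid = "q", tid = "t",
                   qrank = 1L, trank = 1L) {
  tibble::tibble(query_gene_id = qid, query_genome = qg, query_chrom = chrom,
                 query_haplotype = qh, query_rank = qrank,
                 target_genome = tg, target_haplotype = th,
                 target_gene_id = tid, target_chrom = chrom,
                 target_rank = trank, identity = id,
                 coverage_query = 1, coverage_target = 1, score = id)
}

test_that("similarity-matrix entries pool both directions of best hits", {
  hits <- dplyr::bind_rows(
    mk_hit("a", 1L, "b", 1L, 0.9, qid = "q1"),
    mk_hit("a", 1L, "b", 1L, 0.8, qid = "q2"),
    mk_hit("b", 1L, "a", 1L, 0.7, qid = "q3"))
  mat <- build_similarity_matrix(hits, 1L)
  expect_identical(nrow(mat), 1L)
  expect_equal(mat$similarity, (0.9 + 0.8 + 0.7) / 3)
  expect_identical(mat$support, 3L)
  expect_true(mat$low_support)          # support < 10 is flagged
  expect_identical(nrow(build_similarity_matrix(hits[0, ], 1L)), 0L)
})

# matrix with designed shared-species entries high and all others low
design_matrix <- function(design, labels, hi = 0.85, lo = 0.74) {
  units <- expand.grid(genome = design$genomes, hap = 1:2,
                       stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(nrow(units) - 1)) for (j in seq((i + 1), nrow(units))) {
    u <- units[i, ]; v <- units[j, ]
    if (u$genome == v$genome) next
    sp_u <- labels$species[labels$genome == u$genome & labels$haplotype == u$hap]
    sp_v <- labels$species[labels$genome == v$genome & labels$haplotype == v$hap]
    key_first <- paste(u$genome, u$hap) < paste(v$genome, v$hap)
    rows[[length(rows) + 1]] <- tibble::tibble(
      genome_a = if (key_first) u$genome else v$genome,
      hap_a = if (key_first) u$hap else v$hap,
      genome_b = if (key_first) v$genome else u$genome,
      hap_b = if (key_first) v$hap else u$hap,
      similarity = if (sp_u == sp_v) hi else lo,
      support = 20L, low_support = FALSE)
  }
  dplyr::bind_rows(rows)
}

test_that("labeling recovers a designed orientation and is equivariant", {
  design <- hybrid_design()
  labels <- tibble::tibble(
    genome = rep(c("hybAB", "hybBC", "hybAC"), each = 2),
    haplotype = rep(1:2, 3),
    species = c("spA", "spB", "spB", "spC", "spC", "spA"))
  mat <- design_matrix(design, labels)
  got <- assign_parent_labels(mat, design)
  joined <- dplyr::inner_join(got, labels, by = c("genome", "haplotype"),
                              suffix = c("", ".truth"))
  expect_identical(joined$species, joined$species.truth)
  expect_false(any(got$flagged))
  expect_gt(got$margin[1], 0.05)

  # enumeration oracle: no other orientation scores as high
  best_total <- sum(rep(0.85, 3))
  scores <- vapply(0:7, function(k) {
    orient <- as.list(setNames(1L + c(k %% 2, (k %/% 2) %% 2, (k %/% 4) %% 2),
                               sort(design$genomes)))
    haplotrio:::orientation_score(mat, design, orient)$total
  }, 1)
  expect_equal(max(scores), best_total)
  expect_identical(sum(scores == max(scores)), 1L)

  # swapping one genome's haplotype rows swaps its labels only
  swap <- mat
  for (col in c("hap_a", "hap_b")) {
    sel <- (if (col == "hap_a") swap$genome_a else swap$genome_b) == "hybAB"
    swap[[col]][sel] <- 3L - swap[[col]][sel]
  }
  got2 <- assign_parent_labels(swap, design)
  for (g in design$genomes) {
    s1 <- got$species[got$genome == g][order(got$haplotype[got$genome == g])]
    s2 <- got2$species[got2$genome == g][order(got2$haplotype[got2$genome == g])]
    if (g == "hybAB") expect_identical(s2, rev(s1)) else expect_identical(s2, s1)
  }

  # a flat matrix is ambiguous
  flat <- dplyr::mutate(mat, similarity = 0.8)
  expect_true(all(assign_parent_labels(flat, design)$flagged))
})

test_that("noise-free unswitched profiles vote the labeled species everywhere", {
  trio <- tiny_noise0_trio()
  hits <- trio_best_hits(trio$assemblies, trio$catalog)
  lab <- label_chromosomes(hits, trio$design, 1L)
  joined <- dplyr::inner_join(lab, trio$truth_labels,
                              by = c("genome", "chrom", "haplotype"),
                              suffix = c("", ".truth"))
  expect_identical(joined$species, joined$species.truth)
  for (g in trio$design$genomes) {
    p <- build_profile(hits, lab, trio$design, g, 1L, 1L, trio$catalog)
    truth_sp <- trio$truth_labels$species[
      trio$truth_labels$genome == g & trio$truth_labels$haplotype == 1L]
    expect_true(all(p$vote == truth_sp))
    expect_identical(nrow(detect_switches(p)), 0L)  # uniform -> no events
  }
})

test_that("a wrong-species best hit votes with its identity margin", {
  design <- hybrid_design()
  lab <- tibble::tibble(
    genome = rep(c("hybBC", "hybAC"), each = 2), chrom = 1L,
    haplotype = rep(1:2, 2), species = c("spB", "spC", "spA", "spC"),
    margin = 1, flagged = FALSE)
  cat_tbl <- tibble::tibble(gene_id = "L1", genome = "hybAB", chrom = 1L,
                            haplotype = 1L, start = 0L, end = 100L,
                            strand = "+", rank = 1L)
  hits <- dplyr::bind_rows(
    mk_hit("hybAB", 1L, "hybAC", 1L, 0.80, qid = "L1"),  # spA evidence
    mk_hit("hybAB", 1L, "hybBC", 1L, 0.95, qid = "L1"))  # spB evidence
  p <- build_profile(hits, lab, design, "hybAB", 1L, 1L, cat_tbl)
  expect_identical(p$vote, "spB")
  expect_equal(p$margin, 0.15)
})

test_that("detection calls the constructed 60/40 change point exactly", {
  n <- 100L
  votes <- c(rep("spR", 60), rep("spB", 40))
  prof <- tibble::tibble(
    genome = "g", chrom = 1L, haplotype = 1L, rank = seq_len(n),
    gene_id = sprintf("g%03d", seq_len(n)),
    start = seq_len(n) * 1000L, end = seq_len(n) * 1000L + 500L,
    vote = votes, margin = 0.02)
  ev <- detect_switches(prof, window = 5L, min_run = 3L)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$upstream_rank, 60L)
  expect_identical(ev$bp_start, prof$end[60])
  expect_identical(ev$bp_end, prof$start[61])
  expect_identical(ev$upstream_species, "spR")
  expect_identical(ev$downstream_species, "spB")
  # brute-force change point maximizing flank purity agrees
  expect_identical(oracle_change_point(votes, "spR", "spB"), 60L)

  # terminal-segment pattern: one event near the boundary
  votes2 <- c(rep("light_green", 80), rep("red", 20))
  prof2 <- dplyr::mutate(prof, vote = votes2)
  ev2 <- detect_switches(prof2)
  expect_identical(nrow(ev2), 1L)
  expect_identical(ev2$upstream_rank, 80L)

  # mostly ambiguous chromosome is uncallable
  prof3 <- dplyr::mutate(prof, vote = ifelse(rank %% 3 == 0, vote, "ambiguous"))
  expect_warning(ev3 <- detect_switches(prof3), "uncallable")
  expect_identical(nrow(ev3), 0L)
})

test_that("switched synthetic chromosomes flip votes at the truth boundary", {
  trio <- tiny_trio()
  hits <- tiny_hits()
  lab <- label_chromosomes(hits, trio$design, 1L)
  det <- detect_all_switches(hits, lab, trio$design, trio$catalog)
  tr <- trio$truth_switches
  for (i in seq_len(nrow(tr))) {
    e <- det$events[det$events$genome == tr$genome[i] &
                      det$events$chrom == tr$chrom[i] &
                      det$events$haplotype == 1L, ]
    d <- abs(e$upstream_rank - tr$rank[i])
    expect_lte(min(d), 1L)
  }
  # complementarity: mirrored events on the sibling haplotype
  for (i in seq_len(nrow(det$events))) {
    e <- det$events[i, ]
    sib <- det$events[det$events$genome == e$genome &
                        det$events$chrom == e$chrom &
                        det$events$haplotype == 3L - e$haplotype, ]
    expect_true(any(abs(sib$upstream_rank - e$upstream_rank) <= 1L &
                      sib$upstream_species == e$downstream_species &
                      sib$downstream_species == e$upstream_species))
  }
})
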