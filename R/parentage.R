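# Parental-species assignment of haplotypes under a triangle pedigree, and
# haplotype-switch detection as change-points of the per-locus assignment
# signal.

#' Haplotype similarity matrix for one chromosome
#'
#' Mean best-hit identity between the six (genome, haplotype) units of one
#' chromosome index. The entry for units u, v pools best hits from u's loci
#' to v with the reverse direction (one mean over all hits, both ways).
#' Entries supported by fewer than `min_support` loci are flagged.
#'
#' @param hits Best-hit tibble (see [best_hits()]) covering the genome pairs.
#' @param chromosome Chromosome index.
#' @param min_support Minimum locus count per entry.
#' @return Tibble with `genome_a`, `hap_a`, `genome_b`, `hap_b`,
#'   `similarity`, `support`, `low_support` (one row per unordered unit
#'   pair, `a` < `b` lexicographically).
#' @export
build_similarity_matrix <- function(hits, chromosome, min_support = 10L) {
  h <- hits %>%
    filter(.data$query_chrom == chromosome, .data$target_chrom == chromosome) %>%
    mutate(
      a_first = paste(.data$query_genome, .data$query_haplotype) <
        paste(.data$target_genome, .data$target_haplotype),
      genome_a = if_else(.data$a_first, .data$query_genome, .data$target_genome),
      hap_a = if_else(.data$a_first, .data$query_haplotype, .data$target_haplotype),
      genome_b = if_else(.data$a_first, .data$target_genome, .data$query_genome),
      hap_b = if_else(.data$a_first, .data$target_haplotype, .data$query_haplotype)
    ) %>%
    group_by(.data$genome_a, .data$hap_a, .data$genome_b, .data$hap_b) %>%
    summarise(similarity = mean(.data$identity), support = n(), .groups = "drop")
  mutate(h, low_support = .data$support < min_support)
}

# total shared-species score of one orientation assignment.
# orient: named integer vector, genome -> 1 or 2, meaning "haplotype carrying
# the FIRST pedigree species of that genome".
orientation_score <- function(mat, design, orient) {
  pairs <- combn(design$genomes, 2, simplify = FALSE)
  total <- 0
  n_found <- 0L
  for (p in pairs) {
    sp <- shared_species(design, p[1], p[2])
    hap_of <- function(g) {
      first_sp <- design$pedigree[[g]][1]
      if (sp == first_sp) orient[[g]] else 3L - orient[[g]]
    }
    h1 <- hap_of(p[1]); h2 <- hap_of(p[2])
    key <- if (paste(p[1], h1) < paste(p[2], h2)) {
      c(p[1], h1, p[2], h2)
    } else c(p[2], h2, p[1], h1)
    row <- mat[mat$genome_a == key[1] & mat$hap_a == as.integer(key[2]) &
                 mat$genome_b == key[3] & mat$hap_b == as.integer(key[4]), ]
    if (nrow(row) == 1) {
      total <- total + row$similarity
      n_found <- n_found + 1L
    }
  }
  list(total = total, n_found = n_found)
}

#' Assign parental species to haplotypes of one chromosome
#'
#' Exhaustive search over the 8 per-genome haplotype orientations; the
#' labeling maximizing the sum of the three shared-species similarity
#' entries wins. Within each genome the two haplotypes always receive the
#' genome's two pedigree species. A margin below `ambiguous_margin` between
#' best and second-best total flags the chromosome ambiguous.
#'
#' @param mat Output of [build_similarity_matrix()] for one chromosome.
#' @param design A [hybrid_design()].
#' @param ambiguous_margin Minimum best-vs-second-best total-score margin.
#' @return Tibble `genome`, `haplotype`, `species`, `margin`, `flagged`
#'   (ambiguous or supported by low-support entries).
#' @export
assign_parent_labels <- function(mat, design, ambiguous_margin = 0.005) {
  genomes <- sort(design$genomes)
  grid <- expand.grid(rep(list(1:2), 3))
  names(grid) <- genomes
  totals <- apply(grid, 1, function(row) {
    orientation_score(mat, design, as.list(setNames(as.integer(row), genomes)))$total
  })
  best <- which.max(totals)
  margin <- if (length(totals) > 1) {
    totals[best] - max(totals[-best])
  } else Inf
  orient <- as.list(setNames(as.integer(grid[best, ]), genomes))
  flagged <- margin < ambiguous_margin || any(mat$low_support)
  purrr::map_dfr(design$genomes, function(g) {
    first_sp <- design$pedigree[[g]][1]
    other_sp <- design$pedigree[[g]][2]
    h_first <- orient[[g]]
    tibble(genome = g, haplotype = c(h_first, 3L - h_first),
           species = c(first_sp, other_sp),
           margin = margin, flagged = flagged)
  }) %>% arrange(.data$genome, .data$haplotype)
}

#' Per-chromosome parent labeling across a trio
#'
#' Runs [build_similarity_matrix()] + [assign_parent_labels()] for every
#' chromosome index.
#'
#' @inheritParams build_similarity_matrix
#' @inheritParams assign_parent_labels
#' @param chromosomes Chromosome indices to label.
#' @return Labeling tibble with a `chrom` column.
#' @export
label_chromosomes <- function(hits, design, chromosomes,
                              min_support = 10L, ambiguous_margin = 0.005) {
  purrr::map_dfr(chromosomes, function(ch) {
    mat <- build_similarity_matrix(hits, ch, min_support = min_support)
    mutate(assign_parent_labels(mat, design, ambiguous_margin), chrom = ch)
  })
}

#' Per-locus parental assignment profile
#'
#' Each locus of the given (genome, chromosome, haplotype) votes for one of
#' the genome's two pedigree species: the evidence for species `s` is the
#' best-hit identity against the foreign genome sharing `s`, taking the
#' better of that genome's two haplotypes. (The shared-species ortholog is
#' always carried by one of them, so the vote is unaffected by haplotype
#' switches in the foreign genome itself; under clean phasing the best hit
#' sits on the haplotype labeled `s`.) The margin is the identity
#' difference between the two competing species; votes with margin below
#' `ambiguous_margin`, or loci with no hit in either foreign genome, are
#' "ambiguous".
#'
#' @param hits Best-hit tibble.
#' @param labeling Labeling tibble from [label_chromosomes()] (retained for
#'   reporting; voting itself is pedigree-driven).
#' @param design A [hybrid_design()].
#' @param genome,chromosome,haplotype Unit to profile.
#' @param catalog Locus catalog (for locus order and positions).
#' @param ambiguous_margin Identity-margin floor for a confident vote.
#' @return Ordered profile tibble: `rank`, `gene_id`, `start`, `end`,
#'   `vote`, `margin`.
#' @export
build_profile <- function(hits, labeling, design, genome, chromosome,
                          haplotype, catalog, ambiguous_margin = 0.002) {
  species_pair <- design$pedigree[[genome]]
  # for each pedigree species: the foreign genome sharing it
  unit_for <- purrr::map(species_pair, function(sp) {
    og <- setdiff(names(design$pedigree)[vapply(design$pedigree,
                                                function(x) sp %in% x, TRUE)],
                  genome)
    list(genome = og)
  })
  loci <- catalog %>%
    filter(.data$genome == !!genome, .data$chrom == chromosome,
           .data$haplotype == !!haplotype) %>%
    arrange(.data$rank)
  ids <- purrr::map(unit_for, function(u) {
    hits %>%
      filter(.data$query_gene_id %in% loci$gene_id,
             .data$target_genome == u$genome,
             .data$target_chrom == chromosome) %>%
      group_by(.data$query_gene_id) %>%
      summarise(identity = max(.data$identity), .groups = "drop")
  })
  prof <- loci %>%
    select("gene_id", "rank", "start", "end") %>%
    left_join(rename(ids[[1]], id1 = "identity"), by = c(gene_id = "query_gene_id")) %>%
    left_join(rename(ids[[2]], id2 = "identity"), by = c(gene_id = "query_gene_id"))
  prof %>%
    mutate(
      margin = dplyr::case_when(
        is.na(.data$id1) & is.na(.data$id2) ~ NA_real_,
        is.na(.data$id1) ~ .data$id2,
        is.na(.data$id2) ~ .data$id1,
        TRUE ~ abs(.data$id1 - .data$id2)),
      vote = dplyr::case_when(
        is.na(.data$id1) & is.na(.data$id2) ~ "ambiguous",
        .data$margin < ambiguous_margin ~ "ambiguous",
        dplyr::coalesce(.data$id1, -1) >= dplyr::coalesce(.data$id2, -1) ~ species_pair[1],
        TRUE ~ species_pair[2]),
      genome = !!genome, chrom = chromosome, haplotype = !!haplotype
    ) %>%
    select("genome", "chrom", "haplotype", "rank", "gene_id", "start", "end",
           "vote", "margin")
}

#' Detect haplotype switches in an assignment profile
#'
#' Two-state majority smoothing over sliding windows of `window` loci
#' (centered); a state change is called when at least `min_run` consecutive
#' smoothed votes support the new state. The breakpoint interval runs from
#' the end of the last old-state locus to the start of the first new-state
#' locus. Chromosomes with more than `max_ambiguous_frac` ambiguous votes
#' are flagged uncallable (attribute `uncallable`), returning no events.
#'
#' @param profile Tibble from [build_profile()].
#' @param window Smoothing window in loci (odd).
#' @param min_run Minimum consecutive smoothed votes to accept a new state,
#'   and minimum support on each flank of an event.
#' @param max_ambiguous_frac Ambiguous-vote fraction above which the
#'   chromosome is uncallable.
#' @return Tibble of switch events: `genome`, `chrom`, `haplotype`,
#'   `upstream_rank`, `bp_start`, `bp_end`, `upstream_species`,
#'   `downstream_species`, `support_up`, `support_down`.
#' @export
detect_switches <- function(profile, window = 5L, min_run = 3L,
                            max_ambiguous_frac = 0.5) {
  empty <- tibble(genome = character(), chrom = integer(),
                  haplotype = integer(), upstream_rank = integer(),
                  bp_start = integer(), bp_end = integer(),
                  upstream_species = character(),
                  downstream_species = character(),
                  support_up = integer(), support_down = integer())
  profile <- arrange(profile, .data$rank)
  n <- nrow(profile)
  if (n == 0) return(empty)
  votes <- profile$vote
  amb_frac <- mean(votes == "ambiguous")
  if (amb_frac > max_ambiguous_frac) {
    warn(sprintf("%s chr%d hap%d: %.0f%% ambiguous votes; uncallable",
                 profile$genome[1], profile$chrom[1], profile$haplotype[1],
                 100 * amb_frac))
    attr(empty, "uncallable") <- TRUE
    return(empty)
  }
  states <- setdiff(unique(votes), "ambiguous")
  if (length(states) < 2) return(empty)

  half <- window %/% 2L
  smoothed <- character(n)
  for (i in seq_len(n)) {
    win <- votes[max(1L, i - half):min(n, i + half)]
    tab <- table(win[win != "ambiguous"])
    if (length(tab) == 0) { smoothed[i] <- NA_character_; next }
    top <- names(tab)[tab == max(tab)]
    smoothed[i] <- if (length(top) == 1) top else NA_character_
  }
  # carry previous state through ties/all-ambiguous windows
  for (i in seq_len(n)) {
    if (is.na(smoothed[i]) && i > 1) smoothed[i] <- smoothed[i - 1L]
  }
  for (i in rev(seq_len(n))) {
    if (is.na(smoothed[i]) && i < n) smoothed[i] <- smoothed[i + 1L]
  }
  if (anyNA(smoothed)) return(empty)

  r <- rle(smoothed)
  keep <- r$lengths >= min_run
  if (sum(keep) < 2) return(empty)
  # run boundaries (locus indices)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  kept <- which(keep)
  events <- list()
  for (j in seq_len(length(kept) - 1L)) {
    a <- kept[j]; b <- kept[j + 1L]
    if (r$values[a] == r$values[b]) next
    # breakpoint endpoints: last locus whose raw vote supports the upstream
    # state and first locus supporting the downstream state (ambiguous loci
    # support neither)
    up_idx <- max(which(votes[seq_len(starts[b] - 1L)] == r$values[a]))
    down_cand <- which(votes == r$values[b])
    down_idx <- min(down_cand[down_cand > ends[a]])
    events[[length(events) + 1L]] <- tibble(
      genome = profile$genome[1], chrom = profile$chrom[1],
      haplotype = profile$haplotype[1],
      upstream_rank = profile$rank[up_idx],
      bp_start = profile$end[up_idx], bp_end = profile$start[down_idx],
      upstream_species = r$values[a], downstream_species = r$values[b],
      support_up = r$lengths[a], support_down = r$lengths[b])
  }
  if (length(events) == 0) return(empty)
  bind_rows(events)
}

#' Detect switches across all units of a trio
#'
#' Builds profiles and runs [detect_switches()] for every
#' (genome, chromosome, haplotype). By default only complementary event
#' pairs are kept: a genuine haplotype switch exchanges material between
#' the two haplotypes, so it flips the assignment signal of both at the
#' same locus boundary with swapped species, whereas a switch in a
#' *foreign* genome perturbs the votes of only one haplotype of the genome
#' under test. Requiring the mirrored partner therefore rejects
#' foreign-genome artifacts.
#'
#' @inheritParams build_profile
#' @inheritParams detect_switches
#' @param require_complementary Keep only events mirrored (swapped species,
#'   same boundary rank within `rank_slack`) on the sibling haplotype.
#' @param rank_slack Boundary-rank tolerance when pairing mirrored events.
#' @return List with `profiles` (all profiles bound), `events` (filtered),
#'   and `unpaired_events` (rejected single-haplotype flips).
#' @export
detect_all_switches <- function(hits, labeling, design, catalog,
                                window = 5L, min_run = 3L,
                                max_ambiguous_frac = 0.5,
                                ambiguous_margin = 0.002,
                                require_complementary = TRUE,
                                rank_slack = 1L) {
  pairs <- catalog %>% distinct(.data$genome, .data$chrom)
  profs <- list(); evs <- list()
  for (i in seq_len(nrow(pairs))) {
    u <- pairs[i, ]
    p1 <- build_profile(hits, labeling, design, u$genome, u$chrom, 1L,
                        catalog, ambiguous_margin = ambiguous_margin)
    p2 <- build_profile(hits, labeling, design, u$genome, u$chrom, 2L,
                        catalog, ambiguous_margin = ambiguous_margin)
    # complementarity constraint: the two haplotypes carry different parental
    # species, so at any rank their votes must differ; equal confident votes
    # indicate a degraded locus (e.g. a long indel in the shared foreign
    # copy) and are demoted to ambiguous on both haplotypes
    common <- intersect(p1$rank, p2$rank)
    v1 <- p1$vote[match(common, p1$rank)]
    v2 <- p2$vote[match(common, p2$rank)]
    bad <- common[v1 == v2 & v1 != "ambiguous"]
    p1$vote[p1$rank %in% bad] <- "ambiguous"
    p2$vote[p2$rank %in% bad] <- "ambiguous"
    profs[[length(profs) + 1L]] <- p1
    profs[[length(profs) + 1L]] <- p2
    evs[[length(evs) + 1L]] <- detect_switches(p1, window, min_run, max_ambiguous_frac)
    evs[[length(evs) + 1L]] <- detect_switches(p2, window, min_run, max_ambiguous_frac)
  }
  events <- bind_rows(evs)
  unpaired <- events[0, ]
  if (require_complementary && nrow(events) > 0) {
    has_mirror <- vapply(seq_len(nrow(events)), function(i) {
      e <- events[i, ]
      any(events$genome == e$genome & events$chrom == e$chrom &
            events$haplotype == 3L - e$haplotype &
            abs(events$upstream_rank - e$upstream_rank) <= rank_slack &
            events$upstream_species == e$downstream_species &
            events$downstream_species == e$upstream_species)
    }, TRUE)
    unpaired <- events[!has_mirror, , drop = FALSE]
    events <- events[has_mirror, , drop = FALSE]
  }
  list(profiles = bind_rows(profs), events = events,
       unpaired_events = unpaired)
}
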