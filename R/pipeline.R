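# Orchestration: simulate -> score -> assign -> detect -> correct ->
# divergence statistics -> colinearity, with truth evaluation and a
# reproducible report.

#' Pipeline run configuration
#'
#' Bundles the simulation model, pedigree design and all thresholds of the
#' downstream stages; validated up front and serialized into the report for
#' provenance.
#'
#' @param model An [ancestor_model()].
#' @param design A [hybrid_design()].
#' @param k_switches Switches injected per genome.
#' @param noise_factor Within-species haplotype noise factor.
#' @param min_identity,min_coverage Best-hit floors used for colinearity
#'   anchors.
#' @param window,min_run,max_ambiguous_frac Switch-detector parameters.
#' @param vote_margin,label_margin Ambiguity margins for locus votes and
#'   chromosome labeling.
#' @param snap_distance Junction snap distance for correction plans (bp).
#' @param match_size,max_gap Colinear-block chaining parameters.
#' @param seed Seed for the full run (overrides `model$seed`).
#' @param out_dir Optional output directory for [write_outputs()].
#' @param force,permissive Overwrite outputs / tolerate uncallable
#'   chromosomes.
#' @return A `run_config` list.
#' @export
run_config <- function(model = ancestor_model(), design = hybrid_design(),
                       k_switches = 5L, noise_factor = 0.2,
                       min_identity = 0.8, min_coverage = 0.8,
                       window = 5L, min_run = 3L, max_ambiguous_frac = 0.5,
                       vote_margin = 0.002, label_margin = 0.005,
                       snap_distance = 50000L, match_size = 10L, max_gap = 5L,
                       seed = 1L, out_dir = NULL, force = FALSE,
                       permissive = FALSE) {
  stopifnot(inherits(model, "ancestor_model"),
            k_switches >= 0, noise_factor >= 0, noise_factor <= 1,
            min_identity >= 0, min_identity <= 1,
            min_coverage >= 0, min_coverage <= 1,
            window >= 1, min_run >= 1,
            max_ambiguous_frac > 0, max_ambiguous_frac <= 1,
            vote_margin >= 0, label_margin >= 0, snap_distance >= 0,
            match_size >= 1, max_gap >= 0)
  if (!inherits(design, "hybrid_design")) {
    design <- hybrid_design(design)  # refuses non-triangle pedigrees
  }
  structure(as.list(environment()), class = "run_config")
}

#' Best hits across all genome pairs of a trio
#'
#' For every genome, extracts the locus sequences and computes best hits
#' against the loci of the two other genomes.
#'
#' @param assemblies Named list of [diploid_assembly()] objects.
#' @param catalog Locus catalog of the trio.
#' @param include_sibling Also compute each locus' best hit on the other
#'   haplotype of its own genome (needed for sibling-pair colinearity; the
#'   parentage stages only use cross-genome hits).
#' @param ... Passed to [best_hits()].
#' @return Combined best-hit tibble.
#' @export
trio_best_hits <- function(assemblies, catalog, include_sibling = FALSE, ...) {
  genomes <- names(assemblies)
  seqs <- purrr::map(genomes, function(g)
    extract_locus_sequences(assemblies[[g]], catalog))
  names(seqs) <- genomes
  cross <- purrr::map_dfr(genomes, function(g) {
    others <- setdiff(genomes, g)
    fseqs <- unlist(unname(seqs[others]))
    best_hits(seqs[[g]],
              dplyr::filter(catalog, .data$genome == g),
              fseqs,
              dplyr::filter(catalog, .data$genome %in% others),
              ...)
  })
  if (!include_sibling) return(cross)
  sib <- purrr::map_dfr(genomes, function(g) {
    best_hits(seqs[[g]],
              dplyr::filter(catalog, .data$genome == g),
              seqs[[g]],
              dplyr::filter(catalog, .data$genome == g),
              ...) %>%
      filter(.data$target_haplotype != .data$query_haplotype)
  })
  bind_rows(cross, sib)
}

#' Compare predicted switches against truth
#'
#' Greedy nearest matching per (genome, chromosome) within `tolerance_bp`
#' of the predicted breakpoint interval (a truth breakpoint inside the
#' interval has distance zero, i.e. it is localized within one intergenic
#' interval). Unmatched predictions count against precision, unmatched
#' truths against recall. Events mirrored on the two haplotypes are merged
#' by their boundary rank first.
#'
#' @param predicted Event tibble from [detect_all_switches()].
#' @param truth Truth tibble from [inject_switches()].
#' @param tolerance_bp Extra slack around the breakpoint interval.
#' @param rank_slack Mirrored per-haplotype events whose boundary ranks
#'   differ by at most this are merged into one predicted boundary.
#' @return List: `precision`, `recall`, `n_predicted`, `n_truth`,
#'   `breakpoint_error` (bp distance per matched truth), `matches`
#'   (per-truth match table), `flagged` (zero predictions against a
#'   non-empty truth).
#' @export
evaluate_against_truth <- function(predicted, truth, tolerance_bp = 0L,
                                   rank_slack = 2L) {
  if (nrow(predicted) == 0) {
    n_tru <- nrow(truth)
    if (n_tru == 0) {
      return(list(precision = 1, recall = 1, n_predicted = 0L, n_truth = 0L,
                  breakpoint_error = numeric(0), matches = tibble(),
                  flagged = FALSE))
    }
    return(list(precision = 0, recall = 0, n_predicted = 0L, n_truth = n_tru,
                breakpoint_error = numeric(0), matches = tibble(),
                flagged = TRUE))
  }
  # merge mirrored per-haplotype events into one boundary per rank cluster
  pred <- predicted %>%
    arrange(.data$genome, .data$chrom, .data$upstream_rank) %>%
    group_by(.data$genome, .data$chrom) %>%
    mutate(cluster = cumsum(c(1L, as.integer(diff(.data$upstream_rank) > rank_slack)))) %>%
    group_by(.data$genome, .data$chrom, .data$cluster) %>%
    summarise(
      hap = min(.data$haplotype),
      bp_start = .data$bp_start[.data$haplotype == min(.data$haplotype)][1],
      bp_end = .data$bp_end[.data$haplotype == min(.data$haplotype)][1],
      upstream_rank = .data$upstream_rank[.data$haplotype == min(.data$haplotype)][1],
      .groups = "drop")
  n_pred <- nrow(pred); n_tru <- nrow(truth)
  if (n_pred == 0 && n_tru == 0) {
    return(list(precision = 1, recall = 1, n_predicted = 0L, n_truth = 0L,
                breakpoint_error = numeric(0), matches = tibble(),
                flagged = FALSE))
  }
  if (n_pred == 0) {
    return(list(precision = 0, recall = 0, n_predicted = 0L, n_truth = n_tru,
                breakpoint_error = numeric(0), matches = tibble(),
                flagged = TRUE))
  }
  used <- rep(FALSE, n_pred)
  rows <- list()
  if (n_tru > 0) {
    for (i in seq_len(n_tru)) {
      tr <- truth[i, ]
      cut <- if (!is.null(tr$cut_hap1)) tr$cut_hap1 else tr$cut_hap2
      cand <- which(!used & pred$genome == tr$genome & pred$chrom == tr$chrom)
      if (length(cand) == 0) next
      d <- vapply(cand, function(j) {
        cutj <- if (pred$hap[j] == 1L) tr$cut_hap1 else tr$cut_hap2
        if (cutj >= pred$bp_start[j] && cutj <= pred$bp_end[j]) 0
        else min(abs(cutj - pred$bp_start[j]), abs(cutj - pred$bp_end[j]))
      }, 1)
      jbest <- cand[which.min(d)]
      if (min(d) <= tolerance_bp) {
        used[jbest] <- TRUE
        rows[[length(rows) + 1L]] <- tibble(
          genome = tr$genome, chrom = tr$chrom, truth_rank = tr$rank,
          predicted_rank = pred$upstream_rank[jbest], distance_bp = min(d))
      }
    }
  }
  matches <- if (length(rows) > 0) bind_rows(rows) else tibble()
  n_match <- nrow(matches)
  list(precision = n_match / n_pred,
       recall = if (n_tru > 0) n_match / n_tru else 1,
       n_predicted = n_pred, n_truth = n_tru,
       breakpoint_error = if (n_match > 0) matches$distance_bp else numeric(0),
       matches = matches, flagged = FALSE)
}

#' Run the full pipeline on a synthetic trio
#'
#' Simulates a trio with injected switches, scores locus similarity,
#' assigns parental species per chromosome, detects and corrects haplotype
#' switches, evaluates against truth, recomputes assignments on the
#' corrected assemblies (residual switch check), and computes the
#' divergence and colinearity statistics. Deterministic for a fixed
#' `config$seed`.
#'
#' @param config A [run_config()].
#' @return Report list with all stage outputs and a `summary` of the
#'   headline numbers; written to `config$out_dir` when set.
#' @export
run_full <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  model <- config$model
  model$seed <- config$seed
  trio <- simulate_trio(model, config$design, k_switches = config$k_switches,
                        noise_factor = config$noise_factor)

  hits <- trio_best_hits(trio$assemblies, trio$catalog)
  chroms <- seq_len(model$n_chromosomes)
  # first-pass labels may carry reduced margins (switch segments dilute the
  # shared-species means); the post-correction pass below is the strict one
  labeling <- label_chromosomes(hits, config$design, chroms,
                                ambiguous_margin = config$label_margin)
  det <- detect_all_switches(hits, labeling, config$design, trio$catalog,
                             window = config$window, min_run = config$min_run,
                             max_ambiguous_frac = config$max_ambiguous_frac,
                             ambiguous_margin = config$vote_margin)
  evaluation <- evaluate_against_truth(det$events, trio$truth_switches)

  plans <- plan_correction(det$events, trio$assemblies, trio$catalog,
                           snap_distance = config$snap_distance)
  corrected <- apply_correction(trio$assemblies, trio$catalog, plans)

  hits2 <- trio_best_hits(corrected$assemblies, corrected$catalog,
                          include_sibling = TRUE)
  labeling2 <- label_chromosomes(hits2, config$design, chroms,
                                 ambiguous_margin = config$label_margin)
  if (any(labeling2$flagged) && !config$permissive) {
    abort("ambiguous/low-support parent labeling after correction; rerun with permissive = TRUE to continue")
  }
  det2 <- detect_all_switches(hits2, labeling2, config$design,
                              corrected$catalog,
                              window = config$window, min_run = config$min_run,
                              max_ambiguous_frac = config$max_ambiguous_frac,
                              ambiguous_margin = config$vote_margin)

  div <- grouped_similarity(corrected$assemblies, labeling2)
  col <- colinearity_analysis(hits2, corrected$catalog, corrected$assemblies,
                              labeling2,
                              min_identity = config$min_identity,
                              min_coverage = config$min_coverage,
                              match_size = config$match_size,
                              max_gap = config$max_gap)

  summary <- list(
    seed = config$seed,
    n_truth_switches = nrow(trio$truth_switches),
    n_detected_boundaries = evaluation$n_predicted,
    switch_precision = evaluation$precision,
    switch_recall = evaluation$recall,
    residual_switches_after_correction = nrow(det2$events),
    loci_dropped_at_cuts = corrected$dropped,
    shared_similarity_pct_mean = mean(div$shared_group),
    nonshared_similarity_pct_mean = mean(div$nonshared_group),
    rank_sum_W = div$test$W,
    rank_sum_p = div$test$p_value,
    rank_sum_method = div$test$method,
    colinear_locus_pct_shared = col$summary$locus_pct_shared,
    colinear_locus_pct_nonshared = col$summary$locus_pct_nonshared,
    colinear_length_pct = col$summary$length_pct_overall,
    config = config_provenance(config))

  report <- list(assemblies = corrected$assemblies, catalog = corrected$catalog,
                 truth = trio$truth_switches, truth_labels = trio$truth_labels,
                 labeling = labeling, profiles = det$profiles,
                 events = det$events, plans = plans,
                 residual_events = det2$events, evaluation = evaluation,
                 divergence = div, pair_table = div$pair_table,
                 colinearity = col, summary = summary)
  if (!is.null(config$out_dir)) {
    write_outputs(report, config$out_dir, force = config$force)
  }
  report
}

config_provenance <- function(config) {
  keep <- setdiff(names(config), c("model", "design", "out_dir"))
  c(config[keep],
    list(model = unclass(config$model),
         pedigree = purrr::map(config$design$pedigree, paste, collapse = " x ")))
}
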