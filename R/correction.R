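# Turn detected switch events into segment-exchange plans honoring contig
# boundaries, and apply them with annotation lifting.

#' Plan switch corrections
#'
#' Pairs the per-haplotype events of each (genome, chromosome), then picks a
#' cut position per haplotype: the nearest AGP component junction within
#' `snap_distance` of the breakpoint interval (distance zero when the
#' junction lies inside the interval), else the interval midpoint. Cuts are
#' anchored as offsets past the end of the last upstream locus, so a plan
#' re-locates itself correctly in corrected coordinates (a cut may split a
#' component).
#'
#' @param events Switch events from [detect_switches()] /
#'   [detect_all_switches()].
#' @param assemblies Named list of [diploid_assembly()] objects.
#' @param catalog Locus catalog of the (current, switched) assemblies.
#' @param snap_distance Maximum junction snap distance in bp.
#' @return Exchange-plan tibble: `genome`, `chrom`, `rank`, `offset_h1`,
#'   `offset_h2`, `cut_hap1`, `cut_hap2`, `at_junction_h1`, `at_junction_h2`,
#'   `side`, `upstream_species`, `downstream_species`.
#' @export
plan_correction <- function(events, assemblies, catalog,
                            snap_distance = 50000L) {
  if (nrow(events) == 0) {
    return(tibble(genome = character(), chrom = integer(), rank = integer(),
                  offset_h1 = integer(), offset_h2 = integer(),
                  cut_hap1 = integer(), cut_hap2 = integer(),
                  at_junction_h1 = logical(), at_junction_h2 = logical(),
                  side = character(), upstream_species = character(),
                  downstream_species = character()))
  }
  plans <- list()
  groups <- events %>% distinct(.data$genome, .data$chrom)
  for (i in seq_len(nrow(groups))) {
    g <- groups$genome[i]; ch <- groups$chrom[i]
    ev <- events %>% filter(.data$genome == g, .data$chrom == ch)
    # cluster the mirrored per-haplotype events of one physical boundary
    # (their ranks can differ by a locus when a boundary-adjacent locus
    # mis-votes on one haplotype); one plan per cluster
    rk <- sort(unique(ev$upstream_rank))
    cl <- cumsum(c(1L, as.integer(diff(rk) > 2L)))
    ranks <- vapply(split(rk, cl), function(x) {
      h1 <- x[x %in% ev$upstream_rank[ev$haplotype == 1L]]
      if (length(h1) > 0) h1[1] else x[1]
    }, 1L)
    rows <- purrr::map_dfr(ranks, function(r) {
      per_hap <- purrr::map(1:2, function(h) {
        e <- ev %>% filter(.data$haplotype == h) %>%
          slice_min(abs(.data$upstream_rank - r), n = 1L, with_ties = FALSE)
        loci <- catalog %>%
          filter(.data$genome == g, .data$chrom == ch, .data$haplotype == h) %>%
          arrange(.data$rank)
        iv <- if (nrow(e) == 1 && abs(e$upstream_rank - r) <= 2L) {
          c(e$bp_start, e$bp_end)
        } else {
          c(loci$end[r], loci$start[r + 1L])
        }
        jc <- agp_junctions(assemblies[[g]], ch, h)
        jc <- jc[jc >= iv[1] - snap_distance & jc <= iv[2] + snap_distance]
        if (length(jc) > 0) {
          d <- ifelse(jc >= iv[1] & jc <= iv[2], 0L,
                      pmin(abs(jc - iv[1]), abs(jc - iv[2])))
          cut <- jc[order(d, jc)][1]
          at_j <- TRUE
        } else {
          cut <- as.integer(floor((iv[1] + iv[2]) / 2))
          at_j <- FALSE
        }
        list(cut = as.integer(cut), offset = as.integer(cut - loci$end[r]),
             at_junction = at_j)
      })
      tibble(genome = g, chrom = ch, rank = r,
             offset_h1 = per_hap[[1]]$offset, offset_h2 = per_hap[[2]]$offset,
             cut_hap1 = per_hap[[1]]$cut, cut_hap2 = per_hap[[2]]$cut,
             at_junction_h1 = per_hap[[1]]$at_junction,
             at_junction_h2 = per_hap[[2]]$at_junction,
             side = "right",
             upstream_species = ev$upstream_species[1],
             downstream_species = ev$downstream_species[1])
    })
    if (any(diff(rows$cut_hap1) <= 0) || any(diff(rows$cut_hap2) <= 0)) {
      bad <- paste(rows$rank, collapse = ", ")
      abort(sprintf("plans overlap after snapping on %s chr%d (boundaries %s)", g, ch, bad))
    }
    plans[[length(plans) + 1L]] <- rows
  }
  bind_rows(plans) %>% arrange(.data$genome, .data$chrom, .data$rank)
}

#' Exchange plans from recorded truth switches
#'
#' @param truth Truth tibble from [inject_switches()].
#' @return Plan tibble usable with [apply_correction()].
#' @export
plans_from_truth <- function(truth) {
  truth %>%
    select("genome", "chrom", "rank", "offset_h1", "offset_h2",
           "cut_hap1", "cut_hap2", "side") %>%
    arrange(.data$genome, .data$chrom, .data$rank)
}

#' Apply exchange plans to a set of assemblies
#'
#' For each plan the chosen side is exchanged between haplotypes; gene loci
#' move with their sequence (coordinates shifted by the cut offset
#' difference), AGP components are reassigned (split where a cut falls
#' inside one), and the per-chromosome base multiset is conserved. Loci
#' crossing a cut are dropped from the corrected catalog with a logged
#' count. The operation is an involution: applying the same plans to the
#' corrected output restores the input.
#'
#' @param assemblies Named list of [diploid_assembly()] objects.
#' @param catalog Locus catalog matching `assemblies`.
#' @param plans Plan tibble from [plan_correction()] or [plans_from_truth()];
#'   offsets are interpreted on the input state.
#' @return List: `assemblies`, `catalog`, `dropped` (loci dropped at cuts),
#'   and `plans_undo` — the same boundaries re-anchored on the corrected
#'   state; applying them to the output restores the input byte-identically.
#' @export
apply_correction <- function(assemblies, catalog, plans) {
  dropped <- 0L
  undo <- list()
  if (nrow(plans) > 0) {
    groups <- plans %>% distinct(.data$genome, .data$chrom)
    for (i in seq_len(nrow(groups))) {
      g <- groups$genome[i]; ch <- groups$chrom[i]
      p <- plans %>% filter(.data$genome == g, .data$chrom == ch)
      side <- if ("side" %in% names(p) && p$side[1] == "left") "left" else "right"
      ex <- exchange_at_boundaries(
        assemblies[[g]], catalog, ch,
        p[, c("rank", "offset_h1", "offset_h2")], side = side)
      assemblies[[g]] <- ex$assembly
      catalog <- ex$catalog
      dropped <- dropped + ex$dropped
      undo[[length(undo) + 1L]] <- mutate(ex$seams, genome = g, chrom = ch,
                                          side = side)
    }
  }
  if (dropped > 0) {
    inform(sprintf("%d locus/loci crossed an exchange cut and were dropped", dropped))
  }
  list(assemblies = assemblies, catalog = catalog, dropped = dropped,
       plans_undo = if (length(undo) > 0) bind_rows(undo) else plans)
}
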