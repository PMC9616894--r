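# Synthetic trios of hybrid diploid assemblies with known truth.
#
# The generator emulates three parental species with controlled divergence
# (SNPs, short indels, SVs > 50 bp), gene loci along chromosomes, hybrid
# composition under a triangle pedigree, and injected haplotype switches.

#' Ancestor divergence model
#'
#' Parameters of the three-species simulation. Species A is drawn uniformly
#' at random; species B and C derive from A by independent mutation passes at
#' the stated rates, with gene loci lifted through indels and SVs so that
#' orthologous loci correspond across species by (chromosome, rank).
#'
#' @param n_chromosomes Chromosomes per haploid set.
#' @param chrom_length Chromosome length in bp.
#' @param n_genes_per_chrom Gene loci per chromosome.
#' @param gene_length Gene locus length in bp.
#' @param snp_rate Per-bp substitution probability per mutation pass.
#' @param indel_rate Per-bp indel initiation probability; lengths are uniform
#'   on `1..indel_max`.
#' @param indel_max Maximum short-indel length (<= 50 bp, the class boundary).
#' @param sv_count_per_chrom Structural variants (> 50 bp; deletions and
#'   tandem duplications, placed in intergenic space) per chromosome per pass.
#' @param sv_length_range Length range of SVs, both > 50 bp.
#' @param seed Integer seed driving all sampling.
#' @return An `ancestor_model` list.
#' @export
ancestor_model <- function(n_chromosomes = 2L, chrom_length = 500000L,
                           n_genes_per_chrom = 200L, gene_length = 2000L,
                           snp_rate = 0.01, indel_rate = 0.002,
                           indel_max = 10L, sv_count_per_chrom = 2L,
                           sv_length_range = c(100L, 1000L), seed = 1L) {
  stopifnot(snp_rate >= 0, snp_rate <= 0.2, indel_rate >= 0, indel_rate <= 0.2,
            indel_max <= 50, min(sv_length_range) > 50,
            length(sv_length_range) == 2, sv_length_range[1] <= sv_length_range[2])
  m <- list(n_chromosomes = as.integer(n_chromosomes),
            chrom_length = as.integer(chrom_length),
            n_genes_per_chrom = as.integer(n_genes_per_chrom),
            gene_length = as.integer(gene_length),
            snp_rate = snp_rate, indel_rate = indel_rate,
            indel_max = as.integer(indel_max),
            sv_count_per_chrom = as.integer(sv_count_per_chrom),
            sv_length_range = as.integer(sv_length_range),
            seed = as.integer(seed))
  min_gap <- 20L
  if ((m$n_genes_per_chrom + 1L) * min_gap + m$n_genes_per_chrom * m$gene_length >
      m$chrom_length) {
    abort("gene placement infeasible: too many/long genes for chrom_length")
  }
  structure(m, class = "ancestor_model")
}

#' Triangle pedigree of three hybrid genomes
#'
#' Each genome is a cross of two named species; each species must appear in
#' exactly two genomes, so the pairing forms a triangle.
#'
#' @param pedigree Named list mapping genome name to a character pair of
#'   parental species.
#' @return A `hybrid_design` list.
#' @export
hybrid_design <- function(pedigree = list(hybAB = c("spA", "spB"),
                                          hybBC = c("spB", "spC"),
                                          hybAC = c("spA", "spC"))) {
  if (length(pedigree) != 3 || is.null(names(pedigree))) {
    abort("pedigree must name exactly three genomes")
  }
  species <- unlist(pedigree, use.names = FALSE)
  tab <- table(species)
  if (length(tab) != 3 || any(tab != 2) || any(lengths(pedigree) != 2)) {
    abort("pedigree is not a triangle: need three species, each in exactly two genomes")
  }
  structure(list(genomes = names(pedigree), pedigree = pedigree),
            class = "hybrid_design")
}

#' Shared parental species of two genomes in a design
#' @param design A [hybrid_design()].
#' @param g1,g2 Genome names.
#' @return The shared species name.
#' @export
shared_species <- function(design, g1, g2) {
  s <- intersect(design$pedigree[[g1]], design$pedigree[[g2]])
  if (length(s) != 1) abort(sprintf("%s and %s share %d species; expected 1", g1, g2, length(s)))
  s
}

# ---- mutation machinery -----------------------------------------------------

# sample() without the scalar-x surprise
sample1 <- function(x) x[sample.int(length(x), 1L)]

# Draw an edit set for one sequence. Returns tibble(pos, ref_len, alt_len,
# alt_seq, kind) sorted by pos, overlaps resolved (first kept). `protect`
# is a tibble of 0-based half-open spans SVs must avoid.
gen_edits <- function(seq, snp_rate, indel_rate, indel_max, sv_count,
                      sv_range, protect = NULL) {
  len <- nchar(seq)
  bases <- c("A", "C", "G", "T")
  ed <- list()
  n_snp <- stats::rbinom(1, len, snp_rate)
  if (n_snp > 0) {
    pos <- sort(sample.int(len, n_snp)) - 1L
    old <- substring(seq, pos + 1L, pos + 1L)
    # rotate each base by 1-3 positions in the alphabet: always a different base
    alt <- bases[(match(old, bases) - 1L + sample.int(3L, n_snp, replace = TRUE)) %% 4L + 1L]
    ed$snp <- tibble(pos = pos, ref_len = 1L, alt_len = 1L, alt_seq = alt, kind = "SNP")
  }
  n_ind <- stats::rbinom(1, len, indel_rate)
  if (n_ind > 0) {
    pos <- sort(sample.int(len, n_ind)) - 1L
    L <- sample.int(indel_max, n_ind, replace = TRUE)
    is_ins <- runif(n_ind) < 0.5
    alt <- character(n_ind)
    alt[is_ins] <- vapply(L[is_ins], function(l)
      paste(sample(bases, l, replace = TRUE), collapse = ""), "")
    alt[!is_ins] <- ""
    ed$indel <- tibble(pos = pos,
                       ref_len = ifelse(is_ins, 0L, L),
                       alt_len = ifelse(is_ins, L, 0L),
                       alt_seq = alt, kind = "INDEL")
  }
  if (sv_count > 0) {
    free <- free_spans(len, protect)
    picked <- 0L
    rows <- list()
    guard <- 0L
    while (picked < sv_count && guard < 200L) {
      guard <- guard + 1L
      L <- sample(seq(sv_range[1], sv_range[2]), 1L)
      cand <- dplyr::filter(free, .data$end - .data$start > L + 2L)
      if (nrow(cand) == 0) break
      row <- cand[sample.int(nrow(cand), 1L), ]
      p <- row$start + sample.int(row$end - row$start - L - 1L, 1L)
      dup <- runif(1) < 0.5
      if (dup) {
        span <- substring(seq, p + 1L, p + L)
        rows[[length(rows) + 1L]] <- tibble(pos = p, ref_len = L, alt_len = 2L * L,
                                            alt_seq = paste0(span, span), kind = "SV")
      } else {
        rows[[length(rows) + 1L]] <- tibble(pos = p, ref_len = L, alt_len = 0L,
                                            alt_seq = "", kind = "SV")
      }
      # carve the used span out of the free list to keep SVs disjoint
      free <- free_spans_subtract(free, p, p + L)
      picked <- picked + 1L
    }
    if (length(rows) > 0) ed$sv <- bind_rows(rows)
  }
  out <- bind_rows(ed)
  if (nrow(out) == 0) {
    return(tibble(pos = integer(), ref_len = integer(), alt_len = integer(),
                  alt_seq = character(), kind = character()))
  }
  out <- arrange(out, .data$pos, dplyr::desc(.data$ref_len))
  # drop edits overlapping an earlier-kept edit (insertions at identical pos too)
  pos <- out$pos; ref_len <- out$ref_len
  keep <- logical(length(pos))
  prev_end <- -1L
  for (i in seq_along(pos)) {
    if (pos[i] > prev_end && pos[i] + ref_len[i] <= len) {
      keep[i] <- TRUE
      prev_end <- pos[i] + max(ref_len[i], 1L) - 1L
    }
  }
  out[keep, , drop = FALSE]
}

# Complement of `protect` spans within [0, len), with a small safety margin.
free_spans <- function(len, protect, margin = 5L) {
  if (is.null(protect) || nrow(protect) == 0) {
    return(tibble(start = 0L, end = len))
  }
  p <- arrange(protect, .data$start)
  starts <- c(0L, p$end + margin)
  ends <- c(pmax(p$start - margin, 0L), len)
  out <- tibble(start = starts, end = ends)
  dplyr::filter(out, .data$end > .data$start)
}

free_spans_subtract <- function(free, s, e) {
  out <- purrr::pmap_dfr(free, function(start, end) {
    if (e <= start || s >= end) return(tibble(start = start, end = end))
    bind_rows(tibble(start = start, end = min(end, s)),
              tibble(start = max(start, e), end = end))
  })
  dplyr::filter(out, .data$end > .data$start)
}

# Apply an edit set to a sequence.
apply_edits <- function(seq, edits) {
  if (nrow(edits) == 0) return(seq)
  n <- nrow(edits)
  keep_start <- c(0L, edits$pos + edits$ref_len)
  keep_end <- c(edits$pos, nchar(seq))
  kept <- substring(seq, keep_start + 1L, keep_end)
  pieces <- character(2L * n + 1L)
  pieces[seq(1L, 2L * n + 1L, by = 2L)] <- kept
  pieces[seq(2L, 2L * n, by = 2L)] <- edits$alt_seq
  paste(pieces, collapse = "")
}

# Map 0-based positions through an edit set (reference -> mutated
# coordinates). Positions inside a replaced span clamp into the replacement.
lift_positions <- function(pos, edits) {
  if (nrow(edits) == 0 || length(pos) == 0) return(pos)
  ends <- edits$pos + edits$ref_len
  delta <- cumsum(edits$alt_len - edits$ref_len)
  idx <- findInterval(pos, ends)          # edits fully at-or-before pos
  new <- pos + ifelse(idx > 0, delta[idx], 0L)
  # positions falling inside edit idx+1
  j <- idx + 1L
  inside <- j <= nrow(edits) & pos > edits$pos[pmin(j, nrow(edits))] &
    pos < ends[pmin(j, nrow(edits))]
  if (any(inside)) {
    jj <- j[inside]
    base <- edits$pos[jj] + ifelse(jj > 1, delta[jj - 1L], 0L)
    new[inside] <- base + pmin(pos[inside] - edits$pos[jj], edits$alt_len[jj])
  }
  as.integer(new)
}

lift_catalog <- function(catalog, edits_by_chrom) {
  out <- catalog
  for (ch in names(edits_by_chrom)) {
    sel <- out$chrom == as.integer(ch)
    if (!any(sel)) next
    ed <- edits_by_chrom[[ch]]
    out$start[sel] <- lift_positions(out$start[sel], ed)
    out$end[sel] <- lift_positions(out$end[sel], ed)
  }
  bad <- out$end <= out$start
  if (any(bad)) out <- out[!bad, , drop = FALSE]
  rank_catalog(out)
}

# ---- ancestors --------------------------------------------------------------

#' Simulate three parental species
#'
#' Species A is uniform random sequence with non-overlapping gene loci;
#' species B and C derive from A by independent mutation passes at the
#' model's rates (SVs placed in intergenic space so ortholog counts match).
#' Deterministic for a fixed `model$seed`.
#'
#' @param model An [ancestor_model()].
#' @param species Names of the three species.
#' @return List with `model`, `species` (per species: named list of
#'   chromosome sequences), `catalogs` (one locus-catalog tibble, `genome`
#'   column holding the species name), and `edits` (the realized mutation
#'   log, one row per edit).
#' @export
simulate_ancestors <- function(model, species = c("spA", "spB", "spC")) {
  stopifnot(inherits(model, "ancestor_model"), length(species) == 3)
  set.seed(model$seed)
  bases <- c("A", "C", "G", "T")
  K <- model$n_chromosomes
  len <- model$chrom_length
  nG <- model$n_genes_per_chrom
  gL <- model$gene_length
  min_gap <- 20L

  seqs_a <- list()
  cat_rows <- list()
  for (ch in seq_len(K)) {
    seqs_a[[as.character(ch)]] <- paste(sample(bases, len, replace = TRUE),
                                        collapse = "")
    # place genes: distribute free space into n+1 gaps of >= min_gap
    space <- len - nG * gL - (nG + 1L) * min_gap
    cutpts <- sort(runif(nG, 0, space))
    gaps <- diff(c(0, cutpts, space))
    starts <- as.integer(cumsum(gaps[seq_len(nG)] + min_gap) +
                           (seq_len(nG) - 1L) * gL)
    cat_rows[[ch]] <- tibble(
      gene_id = sprintf("%s_c%02dg%04d", species[1], ch, seq_len(nG)),
      genome = species[1], chrom = ch, haplotype = 1L,
      start = starts, end = starts + gL,
      strand = sample(c("+", "-"), nG, replace = TRUE)
    )
  }
  cat_a <- rank_catalog(bind_rows(cat_rows))

  out_species <- setNames(vector("list", 3), species)
  out_species[[species[1]]] <- seqs_a
  catalogs <- list(cat_a)
  edit_log <- list()
  for (sp in species[2:3]) {
    seqs <- list()
    edits_by_chrom <- list()
    for (ch in seq_len(K)) {
      genes <- dplyr::filter(cat_a, .data$chrom == ch)
      ed <- gen_edits(seqs_a[[as.character(ch)]], model$snp_rate,
                      model$indel_rate, model$indel_max,
                      model$sv_count_per_chrom, model$sv_length_range,
                      protect = genes[, c("start", "end")])
      seqs[[as.character(ch)]] <- apply_edits(seqs_a[[as.character(ch)]], ed)
      edits_by_chrom[[as.character(ch)]] <- ed
      if (nrow(ed) > 0) {
        edit_log[[length(edit_log) + 1L]] <-
          mutate(ed, species = sp, chrom = ch)
      }
    }
    out_species[[sp]] <- seqs
    cat_sp <- lift_catalog(mutate(cat_a, genome = sp,
                                  gene_id = sub(species[1], sp, .data$gene_id, fixed = TRUE)),
                           edits_by_chrom)
    if (nrow(cat_sp) != nrow(cat_a)) abort("a mutation pass removed gene loci")
    catalogs[[length(catalogs) + 1L]] <- cat_sp
  }
  list(model = model, species_names = species, species = out_species,
       catalogs = bind_rows(catalogs),
       edits = if (length(edit_log) > 0) bind_rows(edit_log) else
         tibble(pos = integer(), ref_len = integer(), alt_len = integer(),
                alt_seq = character(), kind = character(),
                species = character(), chrom = integer()))
}

# ---- hybrids ----------------------------------------------------------------

#' Compose hybrid diploid assemblies from simulated species
#'
#' Each genome's two haplotypes are mutated copies (at `noise_factor` times
#' the between-species rates, with no structural variants) of its two
#' pedigree species. Which species lands on haplotype 1 is randomized per
#' chromosome; the realized labels are returned as truth. Pseudomolecules are
#' cut into 2-6 AGP components at random positions.
#'
#' @param ancestors Output of [simulate_ancestors()].
#' @param design A [hybrid_design()]; its species must match the ancestors.
#' @param noise_factor Within-species haplotype noise as a fraction of the
#'   between-species rates (default 0.2, so shared-species similarity exceeds
#'   cross-species similarity by construction).
#' @param seed Optional seed; `NULL` continues the caller's RNG stream.
#' @return A trio list: `assemblies` (named list of [diploid_assembly()]),
#'   `catalog` (all genomes), `truth_labels` (species per genome x chromosome
#'   x haplotype), `design`, `model`.
#' @export
compose_hybrids <- function(ancestors, design = hybrid_design(),
                            noise_factor = 0.2, seed = NULL) {
  stopifnot(inherits(design, "hybrid_design"))
  if (!all(unlist(design$pedigree) %in% ancestors$species_names)) {
    abort("design pedigree names species absent from the ancestors")
  }
  if (!is.null(seed)) set.seed(seed)
  model <- ancestors$model
  K <- model$n_chromosomes
  assemblies <- list()
  cat_all <- list()
  labels <- list()
  for (g in design$genomes) {
    parents <- design$pedigree[[g]]
    seqs <- character()
    agp_rows <- list()
    comp_counter <- 0L
    for (ch in seq_len(K)) {
      ord <- if (sample(c(TRUE, FALSE), 1L)) parents else rev(parents)
      for (h in 1:2) {
        sp <- ord[h]
        src <- ancestors$species[[sp]][[as.character(ch)]]
        genes_sp <- dplyr::filter(ancestors$catalogs, .data$genome == sp,
                                  .data$chrom == ch)
        ed <- gen_edits(src, model$snp_rate * noise_factor,
                        model$indel_rate * noise_factor, model$indel_max,
                        sv_count = round(model$sv_count_per_chrom * noise_factor),
                        sv_range = model$sv_length_range,
                        protect = genes_sp[, c("start", "end")])
        s <- apply_edits(src, ed)
        nm <- seq_name(ch, h)
        seqs[[nm]] <- s
        lifted <- lift_catalog(
          mutate(genes_sp, genome = g, haplotype = h,
                 gene_id = sprintf("%s_c%02dh%d_g%04d", g, ch, h,
                                   dplyr::row_number())),
          setNames(list(ed), as.character(ch)))
        cat_all[[length(cat_all) + 1L]] <- lifted
        labels[[length(labels) + 1L]] <-
          tibble(genome = g, chrom = ch, haplotype = h, species = sp)
        # contig composition: 2-6 components
        ncomp <- sample(2:6, 1L)
        slen <- nchar(s)
        cut_lo <- max(1L, min(5000L, slen %/% 10L))
        cand <- seq(cut_lo, slen - cut_lo)
        ncomp <- min(ncomp, length(cand) + 1L)
        cuts <- if (ncomp > 1L) sort(sample(cand, ncomp - 1L)) else integer(0)
        bounds <- c(0L, cuts, slen)
        for (j in seq_len(ncomp)) {
          comp_counter <- comp_counter + 1L
          agp_rows[[length(agp_rows) + 1L]] <- tibble(
            object_id = nm, start = bounds[j], end = bounds[j + 1L],
            component_id = sprintf("%s_h%dtg%06dl", g, h, comp_counter),
            orientation = "+", is_gap = FALSE)
        }
      }
    }
    assemblies[[g]] <- diploid_assembly(g, seqs, agp = bind_rows(agp_rows))
  }
  list(assemblies = assemblies,
       catalog = rank_catalog(bind_rows(cat_all)),
       truth_labels = bind_rows(labels),
       design = design, model = model)
}

# ---- segment exchange (shared by injection and correction) ------------------

# Exchange alternating segments between the two haplotypes of one chromosome.
# `boundaries` is a tibble with columns rank (gene rank of the last upstream
# locus), offset_h1, offset_h2 (bp past that locus' end on each haplotype),
# sorted by rank. Cut positions are anchored to gene ends so the operation is
# an involution: re-applying the same boundaries restores the input even when
# the exchanged segments differ in length.
exchange_at_boundaries <- function(assembly, catalog, chrom, boundaries,
                                   side = "right") {
  g <- assembly$genome
  boundaries <- arrange(boundaries, .data$rank)
  if (any(duplicated(boundaries$rank))) abort("nested/duplicate exchange boundaries")
  cuts <- list()
  for (h in 1:2) {
    cat_h <- catalog %>%
      filter(.data$genome == g, .data$chrom == !!chrom, .data$haplotype == h) %>%
      arrange(.data$rank)
    ends <- cat_h$end[match(boundaries$rank, cat_h$rank)]
    if (anyNA(ends)) abort("exchange boundary rank not present in catalog")
    off <- boundaries[[paste0("offset_h", h)]]
    cc <- as.integer(ends + off)
    slen <- nchar(assembly_seq(assembly, chrom, h))
    if (any(cc <= 0L | cc >= slen)) abort("exchange cut outside the pseudomolecule")
    if (is.unsorted(cc, strictly = TRUE)) abort("exchange cuts overlap after anchoring")
    cuts[[h]] <- cc
  }
  nseg <- length(cuts[[1]]) + 1L
  swap <- rep(c(side == "left", side == "right"), length.out = nseg)

  split_at <- function(s, cc) {
    b <- c(0L, cc, nchar(s))
    substring(s, b[-length(b)] + 1L, b[-1])
  }
  s1 <- assembly_seq(assembly, chrom, 1)
  s2 <- assembly_seq(assembly, chrom, 2)
  segs1 <- split_at(s1, cuts[[1]])
  segs2 <- split_at(s2, cuts[[2]])
  new1 <- paste(ifelse(swap, segs2, segs1), collapse = "")
  new2 <- paste(ifelse(swap, segs1, segs2), collapse = "")

  old_start <- list(c(0L, cuts[[1]]), c(0L, cuts[[2]]))
  len1 <- ifelse(swap, nchar(segs2), nchar(segs1))
  len2 <- ifelse(swap, nchar(segs1), nchar(segs2))
  new_start1 <- c(0L, cumsum(len1))[seq_len(nseg)]
  new_start2 <- c(0L, cumsum(len2))[seq_len(nseg)]

  # move loci with their segments; loci crossing a cut are dropped
  dropped <- 0L
  move_cat <- function(cat_tbl) {
    sel <- cat_tbl$genome == g & cat_tbl$chrom == chrom
    rest <- cat_tbl[!sel, , drop = FALSE]
    cc <- cat_tbl[sel, , drop = FALSE]
    hcuts <- cuts
    out <- cc
    for (h in 1:2) {
      hsel <- cc$haplotype == h
      si <- findInterval(cc$start[hsel], hcuts[[h]]) + 1L
      se <- findInterval(cc$end[hsel] - 1L, hcuts[[h]]) + 1L
      cross <- si != se
      dropped <<- dropped + sum(cross)
      new_h <- ifelse(swap[si], 3L - h, h)
      # segment j of old hap h lands at slot j of the haplotype it now
      # belongs to
      dest_start <- ifelse(swap[si],
                           (if (h == 1) new_start2 else new_start1)[si],
                           (if (h == 1) new_start1 else new_start2)[si])
      shift <- dest_start - old_start[[h]][si]
      out$haplotype[hsel] <- ifelse(cross, NA_integer_, new_h)
      out$start[hsel] <- out$start[hsel] + shift
      out$end[hsel] <- out$end[hsel] + shift
    }
    out <- out[!is.na(out$haplotype), , drop = FALSE]
    rank_catalog(bind_rows(rest, out))
  }
  new_catalog <- move_cat(catalog)

  # AGP: split components at cuts, reassemble alternating, recompute spans
  split_agp <- function(obj, cc) {
    a <- arrange(dplyr::filter(assembly$agp, .data$object_id == obj), .data$start)
    segs <- vector("list", length(cc) + 1L)
    b <- c(0L, cc, a$end[nrow(a)])
    for (j in seq_along(segs)) {
      lo <- b[j]; hi <- b[j + 1L]
      part <- dplyr::filter(a, .data$end > lo, .data$start < hi)
      part <- mutate(part,
                     component_id = ifelse(.data$start < lo | .data$end > hi,
                                           paste0(.data$component_id, ":",
                                                  pmax(.data$start, lo), "-",
                                                  pmin(.data$end, hi)),
                                           .data$component_id),
                     start = pmax(.data$start, lo), end = pmin(.data$end, hi))
      segs[[j]] <- part
    }
    segs
  }
  nm1 <- seq_name(chrom, 1); nm2 <- seq_name(chrom, 2)
  parts1 <- split_agp(nm1, cuts[[1]])
  parts2 <- split_agp(nm2, cuts[[2]])
  rebuild <- function(obj, chosen) {
    rows <- bind_rows(chosen)
    lens <- rows$end - rows$start
    tibble(object_id = obj,
           start = c(0L, cumsum(lens))[seq_len(nrow(rows))],
           end = cumsum(lens),
           component_id = rows$component_id,
           orientation = rows$orientation, is_gap = rows$is_gap)
  }
  pick <- function(a, b) purrr::map(seq_along(swap),
                                    function(j) if (swap[j]) b[[j]] else a[[j]])
  new_agp1 <- rebuild(nm1, pick(parts1, parts2))
  new_agp2 <- rebuild(nm2, pick(parts2, parts1))
  agp <- bind_rows(dplyr::filter(assembly$agp, !.data$object_id %in% c(nm1, nm2)),
                   new_agp1, new_agp2)

  assembly$seqs[[nm1]] <- new1
  assembly$seqs[[nm2]] <- new2
  assembly$agp <- agp
  # seams in output coordinates, re-anchored to the (possibly moved) upstream
  # gene of the output catalog: these offsets are the ones that undo the
  # exchange when applied to the output state
  post_off <- purrr::map(1:2, function(h) {
    cat_h <- new_catalog %>%
      filter(.data$genome == g, .data$chrom == !!chrom, .data$haplotype == h) %>%
      arrange(.data$rank)
    seam <- if (h == 1) new_start1[-1] else new_start2[-1]
    as.integer(seam - cat_h$end[match(boundaries$rank, cat_h$rank)])
  })
  list(assembly = assembly, catalog = new_catalog, dropped = dropped,
       seams = tibble(rank = boundaries$rank,
                      cut_hap1 = new_start1[-1], cut_hap2 = new_start2[-1],
                      offset_h1 = post_off[[1]], offset_h2 = post_off[[2]]))
}

# ---- switch injection -------------------------------------------------------

#' Inject haplotype switches into a trio
#'
#' For each truth switch, the sequence right of the breakpoint is exchanged
#' between haplotypes 1 and 2 of the same chromosome; annotations are lifted
#' and the truth recorded. Breakpoints are taken from AGP component junctions
#' with probability `junction_prob` (when a junction falls in an admissible
#' intergenic interval), otherwise uniformly inside an intergenic interval.
#' Switch boundaries keep at least `min_sep` gene intervals between them and
#' `edge_margin` loci from chromosome ends so that each exchanged segment is
#' resolvable by the downstream detector.
#'
#' @param trio Output of [compose_hybrids()].
#' @param k_per_genome Switches to inject per genome.
#' @param seed Optional seed; `NULL` continues the caller's RNG stream.
#' @param junction_prob Probability of preferring a component junction.
#' @param min_sep Minimum separation between boundaries, in gene intervals.
#' @param edge_margin Minimum distance of a boundary from chromosome ends,
#'   in loci.
#' @return The trio with switched `assemblies`/`catalog` plus
#'   `truth_switches`: one row per switch with the boundary rank, per-
#'   haplotype offsets and absolute cut positions (post-injection
#'   coordinates), and whether the cut sits on a component junction.
#' @export
inject_switches <- function(trio, k_per_genome, seed = NULL,
                            junction_prob = 0.8, min_sep = 10L,
                            edge_margin = 10L) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(k_per_genome >= 0)
  truth <- list()
  if (k_per_genome == 0) {
    trio$truth_switches <- tibble(genome = character(), chrom = integer(),
                                  rank = integer(), offset_h1 = integer(),
                                  offset_h2 = integer(), cut_hap1 = integer(),
                                  cut_hap2 = integer(), at_junction = logical(),
                                  side = character())
    return(trio)
  }
  K <- trio$model$n_chromosomes
  for (g in names(trio$assemblies)) {
    n_per <- trio$catalog %>%
      filter(.data$genome == g, .data$haplotype == 1L) %>%
      count(.data$chrom)
    chosen <- tibble(chrom = integer(), rank = integer())
    guard <- 0L
    while (nrow(chosen) < k_per_genome && guard < 1000L) {
      guard <- guard + 1L
      ch <- sample.int(K, 1L)
      n <- n_per$n[n_per$chrom == ch]
      r <- sample1(seq(edge_margin, n - edge_margin))
      close_by <- any(chosen$chrom == ch & abs(chosen$rank - r) < min_sep)
      if (close_by) {
        inform(sprintf("switch boundary near an existing one (%s chr%d rank %d); resampled",
                       g, ch, r))
        next
      }
      chosen <- bind_rows(chosen, tibble(chrom = ch, rank = r))
    }
    if (nrow(chosen) < k_per_genome) abort("could not place the requested switches")
    for (ch in sort(unique(chosen$chrom))) {
      ranks <- sort(chosen$rank[chosen$chrom == ch])
      cat1 <- trio$catalog %>%
        filter(.data$genome == g, .data$chrom == ch, .data$haplotype == 1L) %>%
        arrange(.data$rank)
      cat2 <- trio$catalog %>%
        filter(.data$genome == g, .data$chrom == ch, .data$haplotype == 2L) %>%
        arrange(.data$rank)
      juncs <- agp_junctions(trio$assemblies[[g]], ch, 1L)
      b_rows <- purrr::map_dfr(ranks, function(r) {
        i1s <- cat1$end[r]; i1e <- cat1$start[r + 1L]
        i2s <- cat2$end[r]; i2e <- cat2$start[r + 1L]
        jc <- juncs[juncs > i1s & juncs < i1e]
        use_j <- length(jc) > 0 && runif(1) < junction_prob
        cut1 <- if (use_j) sample1(jc) else
          i1s + sample1(seq_len(max(1L, i1e - i1s - 1L)))
        frac <- (cut1 - i1s) / (i1e - i1s)
        cut2 <- i2s + max(1L, min(i2e - i2s - 1L, round(frac * (i2e - i2s))))
        tibble(rank = r, offset_h1 = as.integer(cut1 - i1s),
               offset_h2 = as.integer(cut2 - i2s), at_junction = use_j)
      })
      ex <- exchange_at_boundaries(trio$assemblies[[g]], trio$catalog, ch,
                                   b_rows[, c("rank", "offset_h1", "offset_h2")])
      trio$assemblies[[g]] <- ex$assembly
      trio$catalog <- ex$catalog
      # truth carries post-injection coordinates and offsets (the state any
      # downstream detector or corrector sees)
      truth[[length(truth) + 1L]] <- mutate(
        dplyr::left_join(b_rows[, c("rank", "at_junction")], ex$seams, by = "rank"),
        genome = g, chrom = ch, side = "right")
    }
  }
  trio$truth_switches <- bind_rows(truth) %>%
    select("genome", "chrom", "rank", "offset_h1", "offset_h2",
           "cut_hap1", "cut_hap2", "at_junction", "side") %>%
    arrange(.data$genome, .data$chrom, .data$rank)
  trio
}

#' Simulate a complete synthetic trio with injected switches
#'
#' Convenience wrapper: ancestors, hybrid composition, and switch injection
#' in one deterministic chain seeded by `model$seed`. The pre-injection state
#' is kept for truth-based evaluation.
#'
#' @inheritParams compose_hybrids
#' @inheritParams inject_switches
#' @param model An [ancestor_model()].
#' @param k_switches Switches per genome.
#' @return The trio list of [inject_switches()], plus `pre` holding the
#'   pre-injection `assemblies` and `catalog`.
#' @export
simulate_trio <- function(model = ancestor_model(), design = hybrid_design(),
                          k_switches = 5L, noise_factor = 0.2,
                          junction_prob = 0.8, min_sep = 10L,
                          edge_margin = 10L) {
  anc <- simulate_ancestors(model)
  trio <- compose_hybrids(anc, design, noise_factor = noise_factor)
  pre <- list(assemblies = trio$assemblies, catalog = trio$catalog)
  trio <- inject_switches(trio, k_switches, junction_prob = junction_prob,
                          min_sep = min_sep, edge_margin = edge_margin)
  trio$pre <- pre
  trio$ancestors <- anc
  trio
}
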