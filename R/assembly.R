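#' Diploid assembly container
#'
#' Holds one genome's haplotype-resolved pseudomolecules as plain uppercase
#' character sequences keyed by `chr<NN>_hap<H>` names, plus unplaced
#' sequences and the contig composition (AGP) of each pseudomolecule. All
#' coordinates stored in the object (AGP spans, locus catalogs) are 0-based
#' half-open; conversion to 1-based inclusive happens only when files are
#' written.
#'
#' @param genome Genome name.
#' @param seqs Named character vector of pseudomolecule sequences; names must
#'   follow the `chr<NN>_hap<H>` convention and every `(chrom, 1)` must have a
#'   matching `(chrom, 2)`.
#' @param unplaced Named character vector of unplaced sequences (may be empty).
#' @param agp Tibble of components with columns `object_id`, `start`, `end`
#'   (0-based half-open on the object), `component_id`, `orientation`,
#'   `is_gap`. When `NULL`, each pseudomolecule becomes a single component.
#' @return An object of class `diploid_assembly`.
#' @export
diploid_assembly <- function(genome, seqs, unplaced = character(), agp = NULL) {
  stopifnot(is.character(seqs), length(seqs) > 0, !is.null(names(seqs)))
  info <- parse_seq_ids(names(seqs))
  if (any(!info$placed)) {
    abort(paste0("non-pseudomolecule ids in `seqs`: ",
                 paste(info$seq_name[!info$placed], collapse = ", "),
                 " (pass them via `unplaced`)"))
  }
  k <- max(info$chrom)
  need <- tidyr::expand_grid(chrom = seq_len(k), haplotype = 1:2)
  have <- dplyr::anti_join(need, info, by = c("chrom", "haplotype"))
  if (nrow(have) > 0) {
    abort(sprintf("haplotype pairing incomplete: missing %s",
                  paste(seq_name(have$chrom, have$haplotype), collapse = ", ")))
  }
  seqs <- toupper(seqs)
  if (is.null(agp)) {
    agp <- tibble(
      object_id = names(seqs),
      start = 0L,
      end = nchar(seqs),
      component_id = paste0(genome, "_", names(seqs), "_c1"),
      orientation = "+",
      is_gap = FALSE
    )
  }
  validate_agp(agp, seqs)
  structure(
    list(genome = genome, n_chrom = k, seqs = seqs,
         unplaced = toupper(unplaced), agp = agp),
    class = "diploid_assembly"
  )
}

validate_agp <- function(agp, seqs) {
  stopifnot(all(c("object_id", "start", "end", "component_id",
                  "orientation", "is_gap") %in% names(agp)))
  by_obj <- split(agp, agp$object_id)
  for (obj in names(by_obj)) {
    a <- dplyr::arrange(by_obj[[obj]], .data$start)
    if (any(a$start >= a$end)) abort(sprintf("AGP %s: empty component span", obj))
    if (nrow(a) > 1 && any(a$start[-1] != a$end[-nrow(a)])) {
      abort(sprintf("AGP components do not tile object %s", obj))
    }
    if (!obj %in% names(seqs)) next
    if (a$start[1] != 0L || a$end[nrow(a)] != nchar(seqs[[obj]])) {
      abort(sprintf("AGP span does not cover object %s", obj))
    }
  }
  invisible(agp)
}

#' @export
print.diploid_assembly <- function(x, ...) {
  cat(sprintf("<diploid_assembly> %s: %d chromosome(s) x 2 haplotypes, %d unplaced\n",
              x$genome, x$n_chrom, length(x$unplaced)))
  cat(sprintf("  pseudomolecule bp: %s; components: %d\n",
              format(sum(nchar(x$seqs)), big.mark = ","), nrow(x$agp)))
  invisible(x)
}

#' Get one haplotype sequence of a diploid assembly
#'
#' @param assembly A `diploid_assembly`.
#' @param chrom Chromosome index.
#' @param haplotype Haplotype (1 or 2).
#' @return A character scalar.
#' @export
assembly_seq <- function(assembly, chrom, haplotype) {
  nm <- seq_name(chrom, haplotype)
  if (!nm %in% names(assembly$seqs)) abort(sprintf("no sequence %s", nm))
  assembly$seqs[[nm]]
}

#' Component junction positions of one pseudomolecule
#'
#' Internal breakpoints between consecutive AGP components (0-based
#' positions), excluding the object ends.
#'
#' @inheritParams assembly_seq
#' @return Sorted integer vector of junction positions.
#' @export
agp_junctions <- function(assembly, chrom, haplotype) {
  nm <- seq_name(chrom, haplotype)
  a <- dplyr::arrange(dplyr::filter(assembly$agp, .data$object_id == nm), .data$start)
  if (nrow(a) <= 1) return(integer(0))
  sort(a$end[-nrow(a)])
}

# Per-chromosome base multiset fingerprint (hap1 + hap2 pooled), used by the
# conservation invariants: exchanging segments between haplotypes must not
# change it.
chrom_base_multiset <- function(assembly, chrom) {
  s <- paste0(assembly_seq(assembly, chrom, 1), assembly_seq(assembly, chrom, 2))
  table(strsplit(s, "", fixed = TRUE)[[1]])
}
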