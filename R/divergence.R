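# Inter-haplotype variant detection at desk scale, the unaffected-length
# similarity statistic, and the shared- vs non-shared-species rank-sum
# comparison.

#' Align two haplotype sequences and call variants
#'
#' Desk-scale whole-sequence comparison: unique shared k-mers (k = 21)
#' anchor the alignment, anchors are chained by longest increasing
#' subsequence on both coordinates, inter-anchor gaps are closed by banded
#' global alignment when both sides are at most `max_gap_close` bp, and
#' larger gaps are emitted as SV spans. Variants are classified as SNP
#' (single substituted base), INDEL (affected span <= 50 bp) or SV
#' (affected span > 50 bp, the larger of the two sides). Unaligned
#' terminal/interior reference spans count as SV-affected.
#'
#' @param ref_seq,other_seq Sequences to compare (each <= 10 Mbp; use the
#'   MUMmer import path beyond that).
#' @param k Anchor k-mer size.
#' @param max_gap_close Maximum per-side gap closed by alignment.
#' @param band_frac Band width fraction for gap closure.
#' @return Variant tibble: `kind`, `ref_start`, `ref_end`, `other_start`,
#'   `other_end` (0-based half-open; insertions have an empty ref span).
#' @export
align_haplotypes <- function(ref_seq, other_seq, k = 21L,
                             max_gap_close = 20000L, band_frac = 0.2) {
  nr <- nchar(ref_seq); no <- nchar(other_seq)
  if (nr > 1e7 || no > 1e7) {
    abort("sequences exceed the 10 Mbp desk-scale guard; import MUMmer tables instead")
  }
  empty <- tibble(kind = character(), ref_start = integer(), ref_end = integer(),
                  other_start = integer(), other_end = integer())
  if (identical(ref_seq, other_seq)) return(empty)

  anchors <- .cpp_shared_unique_anchors(ref_seq, other_seq, k)
  if (nrow(anchors) == 0) {
    warn("no alignment anchors found; emitting the whole sequence as one SV span")
    return(tibble(kind = "SV", ref_start = 0L, ref_end = nr,
                  other_start = 0L, other_end = no))
  }
  keep <- .cpp_lis(anchors[, 2])
  pa <- anchors[keep, 1]; pb <- anchors[keep, 2]
  n <- length(pa)

  # gap coordinates between consecutive chained anchors, plus the two ends
  rs <- c(0L, pa + k); re <- c(pa, nr)
  os <- c(0L, pb + k); oe <- c(pb, no)
  # trim inconsistent anchor overlaps (anchor interiors match exactly, so
  # trimming back into them is safe)
  t <- pmax(0L, rs - re, os - oe)
  rs <- rs - t; os <- os - t
  gr <- re - rs; go <- oe - os

  # accumulate variant rows as integer matrices (kind coded 1=SNP, 2=INDEL,
  # 3=SV); a tibble per gap would dominate the runtime
  acc <- vector("list", 512L); nacc <- 0L
  emit <- function(kc, r1, r2, o1, o2) {
    nacc <<- nacc + 1L
    if (nacc > length(acc)) length(acc) <<- 2L * nacc
    acc[[nacc]] <<- cbind(kc, r1, r2, o1, o2)
  }
  classify <- function(span) ifelse(span > 50L, 3L, 2L)
  todo <- which(!(gr == 0L & go == 0L))
  for (i in todo) {
    gri <- gr[i]; goi <- go[i]
    if (gri == 1L && goi == 1L) {
      # single-base gap: a substitution unless the bases happen to agree
      if (substr(ref_seq, rs[i] + 1L, rs[i] + 1L) !=
          substr(other_seq, os[i] + 1L, os[i] + 1L)) {
        emit(1L, rs[i], rs[i] + 1L, os[i], os[i] + 1L)
      }
      next
    }
    if (gri > max_gap_close || goi > max_gap_close) {
      emit(3L, rs[i], re[i], os[i], oe[i])
      next
    }
    if (gri == 0L || goi == 0L) {
      # pure insertion/deletion between anchors
      emit(classify(max(gri, goi)), rs[i], re[i], os[i], oe[i])
      next
    }
    al <- .cpp_band_align(substring(ref_seq, rs[i] + 1L, re[i]),
                          substring(other_seq, os[i] + 1L, oe[i]),
                          band_frac = max(band_frac, 0.5), mode = 0L)
    rp <- rs[i]; op <- os[i]
    ops <- al$ops
    for (j in seq_len(nrow(ops))) {
      opc <- ops[j, 1]; L <- ops[j, 2]
      if (opc == 0L) {            # match
        rp <- rp + L; op <- op + L
      } else if (opc == 1L) {     # substitution run -> per-position SNPs
        emit(1L, rp + seq_len(L) - 1L, rp + seq_len(L),
             op + seq_len(L) - 1L, op + seq_len(L))
        rp <- rp + L; op <- op + L
      } else if (opc == 2L) {     # bases only in `other` (insertion)
        emit(classify(L), rp, rp, op, op + L)
        op <- op + L
      } else {                    # bases only in `ref` (deletion)
        emit(classify(L), rp, rp + L, op, op)
        rp <- rp + L
      }
    }
  }
  if (nacc == 0L) return(empty)
  m <- do.call(rbind, acc[seq_len(nacc)])
  out <- tibble(kind = c("SNP", "INDEL", "SV")[m[, 1]],
                ref_start = as.integer(m[, 2]), ref_end = as.integer(m[, 3]),
                other_start = as.integer(m[, 4]), other_end = as.integer(m[, 5]))
  arrange(out, .data$ref_start, .data$other_start)
}

#' Unaffected-length similarity statistic
#'
#' Percentage of the reference haploid sequence set not covered by any
#' variant: affected spans (SNP positions, indel spans, SV spans; a
#' zero-length insertion point counts as 1 bp) are unioned per reference
#' sequence so overlaps count once, then
#' `100 * (1 - affected / haploid_length)`.
#'
#' @param variants Variant tibble with columns `ref_name`, `ref_start`,
#'   `ref_end` (0-based half-open).
#' @param ref_lengths Named vector of reference sequence lengths (all
#'   sequences of the haploid set, including variant-free ones).
#' @return One-row tibble: `affected_bp`, `haploid_length`, `similarity_pct`.
#' @export
unaffected_fraction <- function(variants, ref_lengths) {
  total_len <- sum(ref_lengths)
  affected <- 0L
  if (nrow(variants) > 0) {
    if (!all(variants$ref_name %in% names(ref_lengths))) {
      abort("variant on a reference sequence absent from ref_lengths")
    }
    v <- variants %>%
      mutate(ref_end = ifelse(.data$ref_end > .data$ref_start,
                              .data$ref_end, .data$ref_start + 1L))
    if (any(v$ref_start < 0) ||
        any(v$ref_end > ref_lengths[v$ref_name] + 0L)) {
      abort("variant span outside the reference bounds")
    }
    affected <- sum(vapply(split(v, v$ref_name), function(vv) {
      ir <- IRanges::IRanges(start = vv$ref_start + 1L, end = vv$ref_end)
      sum(IRanges::width(IRanges::reduce(ir)))
    }, 1))
  }
  tibble(affected_bp = affected, haploid_length = total_len,
         similarity_pct = 100 * (1 - affected / total_len))
}

# normal approximation (tie- and continuity-corrected) for the two-sided
# Mann-Whitney p-value at statistic W with group sizes n1, n2. `tie_term` is
# sum(t^3 - t) over tie groups of the pooled sample.
rank_sum_normal_p <- function(W, n1, n2, tie_term = 0) {
  N <- n1 + n2
  mu <- n1 * n2 / 2
  sig2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (sig2 <= 0) return(1)
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
  min(1, 2 * pnorm(-abs(z)))
}

#' Unpaired two-sample rank-sum test
#'
#' The statistic `W` is the Mann-Whitney count of pairs (x in group 1,
#' y in group 2) with x > y, ties counted one half. The two-sided p-value
#' is computed by exhaustive permutation enumeration when `n1 + n2 <= 20`
#' (extremeness measured as distance of W from its null mean), otherwise by
#' normal approximation with tie and continuity corrections.
#'
#' @param group1,group2 Numeric vectors (both non-empty).
#' @param method `"auto"` (size-based, the default), `"exact"` or
#'   `"normal_approx"`.
#' @return A `haplotrio_rank_sum` object with elements `W`, `p_value`,
#'   `method`, `n1`, `n2`.
#' @export
rank_sum_test <- function(group1, group2, method = c("auto", "exact", "normal_approx")) {
  method <- match.arg(method)
  n1 <- length(group1); n2 <- length(group2)
  if (n1 == 0 || n2 == 0) abort("both groups must be non-empty")
  pooled <- c(group1, group2)
  r <- rank(pooled)
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (method == "auto") method <- if (n1 + n2 <= 20) "exact" else "normal_approx"
  mu <- n1 * n2 / 2
  if (method == "exact") {
    idx <- combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(W - mu) - 1e-9)
  } else {
    tt <- table(pooled)
    tie_term <- sum(tt^3 - tt)
    p <- rank_sum_normal_p(W, n1, n2, tie_term)
  }
  structure(list(W = W, p_value = p, method = method, n1 = n1, n2 = n2,
                 mean1 = mean(group1), mean2 = mean(group2)),
            class = "haplotrio_rank_sum")
}

#' @export
print.haplotrio_rank_sum <- function(x, ...) {
  cat(sprintf("Rank-sum test (%s): W = %g, n = %d vs %d, two-sided p = %.4g\n",
              x$method, x$W, x$n1, x$n2, x$p_value))
  invisible(x)
}

#' Shared- vs non-shared-species similarity comparison
#'
#' Builds the six species-coherent haploid units (per genome, the set of
#' per-chromosome haplotype sequences labeled with one parental species),
#' compares every ordered pair of units (30 directional comparisons for a
#' full trio: 6 shared-species, 24 non-shared), computes the
#' unaffected-length similarity of each, and applies [rank_sum_test()] to
#' the two groups. Both directions of a pair are reported, never averaged.
#'
#' @param assemblies Named list of [diploid_assembly()] objects.
#' @param labeling Per-chromosome labeling from [label_chromosomes()].
#' @param ... Passed to [align_haplotypes()].
#' @return A `haplotrio_group_comparison`: `pair_table` (one row per
#'   directional comparison), `test` (the rank-sum result), and the two
#'   group vectors.
#' @export
grouped_similarity <- function(assemblies, labeling, ...) {
  if (nrow(labeling) == 0) abort("parent labeling is required")
  units <- labeling %>% distinct(.data$genome, .data$species) %>%
    arrange(.data$genome, .data$species)
  chroms <- sort(unique(labeling$chrom))
  unit_seq <- function(g, sp, ch) {
    h <- labeling$haplotype[labeling$genome == g & labeling$species == sp &
                              labeling$chrom == ch]
    if (length(h) != 1) abort(sprintf("labeling missing for %s/%s chr%d", g, sp, ch))
    assembly_seq(assemblies[[g]], ch, h)
  }
  # align each unordered unit pair (including the sibling pair within each
  # genome) once per chromosome; derive both directions
  rows <- list()
  for (i in seq_len(nrow(units) - 1L)) {
    for (j in seq((i + 1L), nrow(units))) {
      ga <- units$genome[i]; sa <- units$species[i]
      gb <- units$genome[j]; sb <- units$species[j]
      va <- list(); vb <- list()
      len_a <- c(); len_b <- c()
      for (ch in chroms) {
        a <- unit_seq(ga, sa, ch); b <- unit_seq(gb, sb, ch)
        v <- align_haplotypes(a, b, ...)
        nm <- seq_name(ch, 1L)
        va[[as.character(ch)]] <- mutate(v, ref_name = nm)
        vb[[as.character(ch)]] <- v %>%
          select(kind = "kind", ref_start = "other_start", ref_end = "other_end",
                 other_start = "ref_start", other_end = "ref_end") %>%
          mutate(ref_name = nm)
        len_a[nm] <- nchar(a); len_b[nm] <- nchar(b)
      }
      ua <- unaffected_fraction(bind_rows(va), len_a)
      ub <- unaffected_fraction(bind_rows(vb), len_b)
      shared <- sa == sb
      rows[[length(rows) + 1L]] <- tibble(
        ref_genome = c(ga, gb), ref_species = c(sa, sb),
        other_genome = c(gb, ga), other_species = c(sb, sa),
        shared = shared,
        affected_bp = c(ua$affected_bp, ub$affected_bp),
        haploid_length = c(ua$haploid_length, ub$haploid_length),
        similarity_pct = c(ua$similarity_pct, ub$similarity_pct))
    }
  }
  pair_table <- bind_rows(rows) %>%
    arrange(dplyr::desc(.data$shared), .data$ref_genome, .data$other_genome)
  g1 <- pair_table$similarity_pct[pair_table$shared]
  g2 <- pair_table$similarity_pct[!pair_table$shared]
  structure(list(pair_table = pair_table,
                 shared_group = g1, nonshared_group = g2,
                 test = rank_sum_test(g1, g2)),
            class = "haplotrio_group_comparison")
}

#' @export
print.haplotrio_group_comparison <- function(x, ...) {
  cat(sprintf("Haplotype-pair similarity: shared %0.2f%% (n=%d) vs non-shared %0.2f%% (n=%d)\n",
              mean(x$shared_group), length(x$shared_group),
              mean(x$nonshared_group), length(x$nonshared_group)))
  print(x$test)
  invisible(x)
}
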