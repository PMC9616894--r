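# Readers/writers for the on-disk formats the pipeline touches.
#
# Coordinate conventions: everything held in memory is 0-based half-open;
# GFF3 and AGP are converted to/from 1-based inclusive at the file boundary;
# PAF and BED are natively 0-based half-open and pass through unchanged.

#' Read a FASTA file
#'
#' Wraps [Biostrings::readBStringSet()] with the pipeline's normalization:
#' sequences are uppercased and the alphabet is restricted to A, C, G, T, N.
#'
#' @param path FASTA file.
#' @param keep_mask If `TRUE`, lowercase (soft-masked) runs are recorded and
#'   attached as attribute `"softmask"` (a tibble of 0-based half-open spans)
#'   before uppercasing.
#' @return Named character vector of uppercase sequences, in file order.
#' @export
read_fasta <- function(path, keep_mask = FALSE) {
  stopifnot(file.exists(path))
  ss <- Biostrings::readBStringSet(path)
  ids <- names(ss)
  # FASTA descriptions: id is the first token
  ids <- sub("\\s.*$", "", ids)
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate sequence id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  seqs <- as.character(ss)
  names(seqs) <- ids
  if (any(nchar(seqs) == 0)) {
    abort(paste0("empty sequence(s): ",
                 paste(ids[nchar(seqs) == 0], collapse = ", ")))
  }
  mask <- NULL
  if (keep_mask) {
    mask <- purrr::map_dfr(ids, function(id) {
      r <- gregexpr("[acgtn]+", seqs[[id]])[[1]]
      if (r[1] == -1) return(tibble(seq_name = character(), start = integer(), end = integer()))
      tibble(seq_name = id, start = as.integer(r) - 1L,
             end = as.integer(r) - 1L + attr(r, "match.length"))
    })
  }
  seqs <- toupper(seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    abort(paste0("sequence(s) with characters outside {A,C,G,T,N}: ",
                 paste(names(seqs)[bad], collapse = ", ")))
  }
  if (keep_mask) attr(seqs, "softmask") <- mask
  seqs
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output file.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, filepath = path, width = width)
  invisible(path)
}

#' Read gene loci from a GFF3 file
#'
#' Imports `gene` features via [rtracklayer::import()] and converts them to
#' the internal 0-based half-open convention. Ranks are assigned per
#' (chromosome, haplotype) by start position, ties broken by `gene_id`.
#'
#' @param path GFF3 file (1-based inclusive coordinates, per the format).
#' @param genome Genome name recorded in the catalog.
#' @param pattern Sequence-id convention, see [parse_seq_ids()].
#' @return A locus-catalog tibble with columns `gene_id`, `genome`, `chrom`,
#'   `haplotype`, `start`, `end`, `strand`, `rank`.
#' @export
read_gff3 <- function(path, genome = "genome", pattern = .hap_seq_regex) {
  stopifnot(file.exists(path))
  raw <- readLines(path)
  body <- raw[!startsWith(raw, "#") & nzchar(raw)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9)) {
    abort(sprintf("GFF3 row %d has %d column(s); 9 required",
                  which(nf < 9)[1], nf[which(nf < 9)[1]]))
  }
  is_gene <- vapply(fields, function(f) f[3] == "gene", TRUE)
  bad <- vapply(fields[is_gene], function(f) as.numeric(f[5]) < as.numeric(f[4]), TRUE)
  if (any(bad)) {
    abort(sprintf("gene with end < start at GFF3 row %d", which(is_gene)[bad][1]))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids)) abort("gene feature(s) without an ID attribute")
  info <- parse_seq_ids(as.character(GenomicRanges::seqnames(gr)), pattern)
  if (any(!info$placed)) {
    abort(paste0("unknown seqid(s) in GFF3: ",
                 paste(unique(info$seq_name[!info$placed]), collapse = ", ")))
  }
  cat_tbl <- tibble(
    gene_id = as.character(ids),
    genome = genome,
    chrom = info$chrom,
    haplotype = info$haplotype,
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  cat_tbl$strand[!cat_tbl$strand %in% c("+", "-")] <- "+"
  if (anyDuplicated(cat_tbl$gene_id)) {
    abort(paste0("duplicate gene_id(s): ",
                 paste(unique(cat_tbl$gene_id[duplicated(cat_tbl$gene_id)]), collapse = ", ")))
  }
  rank_catalog(cat_tbl)
}

#' Recompute locus ranks
#'
#' Ranks are 1..n per (chromosome, haplotype), ordered by start position with
#' ties broken by lexicographic `gene_id`.
#'
#' @param catalog Locus-catalog tibble.
#' @return The catalog, re-sorted with a fresh `rank` column.
#' @export
rank_catalog <- function(catalog) {
  catalog %>%
    arrange(.data$genome, .data$chrom, .data$haplotype, .data$start, .data$gene_id) %>%
    group_by(.data$genome, .data$chrom, .data$haplotype) %>%
    mutate(rank = row_number()) %>%
    ungroup()
}

#' Write a locus catalog as GFF3
#'
#' @param catalog Locus-catalog tibble (internal 0-based half-open).
#' @param path Output file.
#' @param source Value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(catalog, path, source = "haplotrio") {
  catalog <- arrange(catalog, .data$chrom, .data$haplotype, .data$start, .data$gene_id)
  lines <- c("##gff-version 3",
             sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     seq_name(catalog$chrom, catalog$haplotype), source,
                     catalog$start + 1L, catalog$end, catalog$strand,
                     catalog$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' Read a PAF alignment file
#'
#' Parses the 12 mandatory PAF columns and derives `identity`
#' (matches / block length) and `coverage_query` (aligned query span /
#' query length). PAF is natively 0-based half-open.
#'
#' @param path PAF file.
#' @return Tibble of alignment records in file order.
#' @export
read_paf <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(query_id = character(), query_len = integer(),
                  query_start = integer(), query_end = integer(),
                  strand = character(), target_id = character(),
                  target_len = integer(), target_start = integer(),
                  target_end = integer(), matches = integer(),
                  block_len = integer(), mapq = integer(),
                  identity = double(), coverage_query = double()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12)) {
    abort(sprintf("PAF line %d has %d column(s); 12 required",
                  which(nf < 12)[1], nf[which(nf < 12)[1]]))
  }
  col <- function(i) vapply(fields, `[[`, "", i)
  out <- tibble(
    query_id = col(1), query_len = as.integer(col(2)),
    query_start = as.integer(col(3)), query_end = as.integer(col(4)),
    strand = col(5), target_id = col(6),
    target_len = as.integer(col(7)), target_start = as.integer(col(8)),
    target_end = as.integer(col(9)), matches = as.integer(col(10)),
    block_len = as.integer(col(11)), mapq = as.integer(col(12))
  )
  out %>% mutate(
    identity = ifelse(.data$block_len > 0, .data$matches / .data$block_len, 0),
    coverage_query = ifelse(.data$query_len > 0,
                            (.data$query_end - .data$query_start) / .data$query_len, 0)
  )
}

#' Write alignment records as PAF
#'
#' @param paf Tibble as returned by [read_paf()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_paf <- function(paf, path) {
  lines <- sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d",
                   paf$query_id, paf$query_len, paf$query_start, paf$query_end,
                   paf$strand, paf$target_id, paf$target_len, paf$target_start,
                   paf$target_end, paf$matches, paf$block_len, paf$mapq)
  writeLines(lines, path)
  invisible(path)
}

#' Read MUMmer variant tables
#'
#' Parses a `show-snps` table (as produced with `-Clr -x`) and a `show-diff`
#' feature table into one variant set on reference coordinates. Consecutive
#' single-base indel rows (`.` allele) are merged by run length into single
#' INDEL/SV records; `show-diff` features become SV spans.
#'
#' @param snps_path `show-snps` output (may be empty or missing header rows).
#' @param diff_path `show-diff` output.
#' @param ref_name Reference unit name recorded on each variant.
#' @return A variant tibble with columns `kind`, `ref_name`, `ref_start`,
#'   `ref_end` (0-based half-open), `alt_len`.
#' @export
read_mummer_tables <- function(snps_path, diff_path, ref_name = "ref") {
  parse_body <- function(path) {
    if (!file.exists(path)) abort(sprintf("file not found: %s", path))
    lines <- readLines(path)
    keep <- vapply(lines, function(l) {
      t <- strsplit(trimws(l), "\\s+")[[1]]
      length(t) >= 4 && !is.na(suppressWarnings(as.numeric(t[1])))
    }, TRUE, USE.NAMES = FALSE)
    lines[keep]
  }

  variants <- list()

  snp_lines <- parse_body(snps_path)
  if (length(snp_lines) > 0) {
    tok <- strsplit(trimws(snp_lines), "\\s+")
    p1 <- vapply(tok, function(t) as.numeric(t[1]), 1)
    rb <- vapply(tok, function(t) t[2], "")
    qb <- vapply(tok, function(t) t[3], "")
    if (anyNA(p1)) abort(sprintf("unparseable show-snps row %d", which(is.na(p1))[1]))
    is_ins <- rb == "."           # base present in query only
    is_del <- qb == "."           # base present in reference only
    is_snp <- !is_ins & !is_del
    variants$snp <- tibble(kind = "SNP", ref_name = ref_name,
                           ref_start = as.integer(p1[is_snp]) - 1L,
                           ref_end = as.integer(p1[is_snp]),
                           alt_len = 1L)
    merge_runs <- function(pos) {
      # group consecutive rows whose reference position advances by <= 1
      if (length(pos) == 0) return(integer(0))
      cumsum(c(1L, as.integer(diff(pos) > 1)))
    }
    if (any(is_ins)) {
      pos <- as.integer(p1[is_ins])
      grp <- merge_runs(pos)
      ins <- tibble(pos = pos, grp = grp) %>%
        group_by(.data$grp) %>%
        summarise(ref_start = first(.data$pos) - 1L, alt_len = n(), .groups = "drop")
      variants$ins <- tibble(kind = ifelse(ins$alt_len > 50, "SV", "INDEL"),
                             ref_name = ref_name, ref_start = ins$ref_start,
                             ref_end = ins$ref_start, alt_len = ins$alt_len)
    }
    if (any(is_del)) {
      pos <- as.integer(p1[is_del])
      grp <- merge_runs(pos)
      del <- tibble(pos = pos, grp = grp) %>%
        group_by(.data$grp) %>%
        summarise(ref_start = first(.data$pos) - 1L, ref_end = last(.data$pos),
                  .groups = "drop")
      span <- del$ref_end - del$ref_start
      variants$del <- tibble(kind = ifelse(span > 50, "SV", "INDEL"),
                             ref_name = ref_name, ref_start = del$ref_start,
                             ref_end = del$ref_end, alt_len = 0L)
    }
  }

  diff_lines <- parse_body_diff(diff_path)
  if (length(diff_lines) > 0) {
    tok <- strsplit(trimws(diff_lines), "\\s+")
    ok <- vapply(tok, function(t) length(t) >= 4 &&
                   !is.na(suppressWarnings(as.numeric(t[3]))) &&
                   !is.na(suppressWarnings(as.numeric(t[4]))), TRUE)
    if (any(!ok)) abort(sprintf("unparseable show-diff row %d", which(!ok)[1]))
    s1 <- vapply(tok, function(t) as.numeric(t[3]), 1)
    e1 <- vapply(tok, function(t) as.numeric(t[4]), 1)
    lo <- pmin(s1, e1); hi <- pmax(s1, e1)
    span <- hi - lo + 1
    variants$diff <- tibble(kind = ifelse(span > 50, "SV", "INDEL"),
                            ref_name = ref_name,
                            ref_start = as.integer(lo) - 1L,
                            ref_end = as.integer(hi),
                            alt_len = 0L)
  }

  out <- bind_rows(variants)
  if (nrow(out) == 0) {
    return(tibble(kind = character(), ref_name = character(),
                  ref_start = integer(), ref_end = integer(), alt_len = integer()))
  }
  arrange(out, .data$ref_name, .data$ref_start, .data$kind)
}

parse_body_diff <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  keep <- vapply(lines, function(l) {
    t <- strsplit(trimws(l), "\\s+")[[1]]
    # show-diff rows: seq-id, feature type, then numeric coordinates
    length(t) >= 4 && t[2] %in% c("GAP", "BRK", "JMP", "INV", "SEQ", "DUP") &&
      !is.na(suppressWarnings(as.numeric(t[3])))
  }, TRUE, USE.NAMES = FALSE)
  lines[keep]
}

#' Write a table of genomic intervals as BED
#'
#' Intervals are already 0-based half-open internally, so they are written
#' unchanged. A comment header names the columns; an empty table yields a
#' header-only file.
#'
#' @param tbl Tibble with columns `seq_name`, `start`, `end`, and optionally
#'   `name`, `score`, `strand`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(tbl, path) {
  header <- "#chrom\tstart\tend\tname\tscore\tstrand"
  if (nrow(tbl) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  nm <- if ("name" %in% names(tbl)) tbl$name else "."
  sc <- if ("score" %in% names(tbl)) tbl$score else 0
  st <- if ("strand" %in% names(tbl)) tbl$strand else "."
  writeLines(c(header, sprintf("%s\t%d\t%d\t%s\t%s\t%s", tbl$seq_name,
                               as.integer(tbl$start), as.integer(tbl$end),
                               nm, as.character(sc), st)), path)
  invisible(path)
}

#' Write AGP v2.1
#'
#' @param agp Internal AGP tibble (0-based half-open object coordinates).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_agp <- function(agp, path) {
  agp <- arrange(agp, .data$object_id, .data$start)
  agp <- agp %>% group_by(.data$object_id) %>%
    mutate(part = row_number()) %>% ungroup()
  lines <- c("##agp-version\t2.1",
             sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%s",
                     agp$object_id, agp$start + 1L, agp$end, agp$part,
                     ifelse(agp$is_gap, "N", "W"), agp$component_id,
                     1L, agp$end - agp$start, agp$orientation))
  writeLines(lines, path)
  invisible(path)
}

#' Read AGP v2.1
#'
#' @param path AGP file.
#' @return Internal AGP tibble (0-based half-open object coordinates).
#' @export
read_agp <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(object_id = character(), start = integer(), end = integer(),
                  component_id = character(), orientation = character(),
                  is_gap = logical()))
  }
  tok <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(tok)
  if (any(nf < 9)) abort(sprintf("AGP row %d has fewer than 9 columns", which(nf < 9)[1]))
  tibble(
    object_id = vapply(tok, `[[`, "", 1),
    start = as.integer(vapply(tok, `[[`, "", 2)) - 1L,
    end = as.integer(vapply(tok, `[[`, "", 3)),
    component_id = vapply(tok, `[[`, "", 6),
    orientation = vapply(tok, function(t) if (t[5] == "W") t[9] else "+", ""),
    is_gap = vapply(tok, `[[`, "", 5) %in% c("N", "U")
  )
}

#' Write the full result set of a pipeline run
#'
#' Emits corrected FASTA/GFF3/AGP per genome, truth and predicted switch BED
#' files, per-pair divergence and colinearity TSVs, and a JSON summary.
#' Output is byte-deterministic for identical inputs.
#'
#' @param results Report list as returned by [run_full()].
#' @param out_dir Output directory.
#' @param force Overwrite an existing non-empty directory.
#' @return Character vector of files written, invisibly.
#' @export
write_outputs <- function(results, out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force) {
    abort(sprintf("output directory %s exists and is not empty (use force = TRUE)", out_dir))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  w_tsv <- function(tbl, name) {
    p <- file.path(out_dir, name)
    utils::write.table(tbl, p, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, p)
  }
  for (g in names(results$assemblies)) {
    asm <- results$assemblies[[g]]
    p <- file.path(out_dir, paste0(g, ".corrected.fasta"))
    write_fasta(c(asm$seqs, asm$unplaced), p)
    files <- c(files, p)
    p <- file.path(out_dir, paste0(g, ".corrected.agp"))
    write_agp(asm$agp, p)
    files <- c(files, p)
    p <- file.path(out_dir, paste0(g, ".corrected.gff3"))
    write_gff3(dplyr::filter(results$catalog, .data$genome == g), p)
    files <- c(files, p)
  }
  pred <- results$events
  pred_bed <- if (nrow(pred) > 0) {
    tibble(seq_name = paste0(pred$genome, ":", seq_name(pred$chrom, pred$haplotype)),
           start = pred$bp_start, end = pred$bp_end,
           name = paste0(pred$upstream_species, ">", pred$downstream_species))
  } else tibble(seq_name = character(), start = integer(), end = integer())
  p <- file.path(out_dir, "switches.predicted.bed"); write_bed(pred_bed, p)
  files <- c(files, p)
  tru <- results$truth
  tru_bed <- if (!is.null(tru) && nrow(tru) > 0) {
    tibble(seq_name = paste0(tru$genome, ":", seq_name(tru$chrom, 1L)),
           start = tru$cut_hap1, end = tru$cut_hap1 + 1L, name = "truth_switch")
  } else tibble(seq_name = character(), start = integer(), end = integer())
  p <- file.path(out_dir, "switches.truth.bed"); write_bed(tru_bed, p)
  files <- c(files, p)
  if (!is.null(results$profiles)) w_tsv(results$profiles, "assignment_profiles.tsv")
  if (!is.null(results$pair_table)) w_tsv(results$pair_table, "similarity_pairs.tsv")
  if (!is.null(results$colinearity$pair_stats)) {
    w_tsv(results$colinearity$pair_stats, "colinearity_pairs.tsv")
  }
  p <- file.path(out_dir, "summary.json")
  jsonlite::write_json(results$summary, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, p)
  invisible(files)
}
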