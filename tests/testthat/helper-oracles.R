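# Independent oracles and shared fixtures for the test suite. Oracles are
# deliberately written with different machinery than the implementation:
# Biostrings for alignment, per-base marking for interval unions, exhaustive
# enumeration for chaining and rank-sum p-values.

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Global-alignment identity oracle with the package's scoring scheme
# (match 2, mismatch -2, linear gap 3 per base).
oracle_global_identity <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(
    a, b, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(2, -2),
    gapOpening = 0, gapExtension = 3)
  Biostrings::nmatch(pa) / Biostrings::nchar(pa)
}

# Per-base brute-force oracle for the unaffected-length statistic.
oracle_unaffected_pct <- function(variants, ref_lengths) {
  total <- sum(ref_lengths)
  affected <- 0L
  for (nm in names(ref_lengths)) {
    hit <- rep(FALSE, ref_lengths[[nm]])
    v <- variants[variants$ref_name == nm, , drop = FALSE]
    for (i in seq_len(nrow(v))) {
      s <- v$ref_start[i]; e <- v$ref_end[i]
      if (e <= s) e <- s + 1L
      hit[(s + 1L):e] <- TRUE
    }
    affected <- affected + sum(hit)
  }
  100 * (1 - affected / total)
}

# Exhaustive two-sided rank-sum p-value: enumerate every assignment of the
# pooled values to group 1, count pairs with half ties.
oracle_rank_sum <- function(g1, g2) {
  pooled <- c(g1, g2)
  n1 <- length(g1)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_of(g1, g2)
  mu <- n1 * length(g2) / 2
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  list(W = u_obs, p = mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9))
}

# Exhaustive optimal-chain oracle: depth-first enumeration of every valid
# chain under the rank-gap rule, both orientations; returns the maximum
# chain length.
oracle_best_chain <- function(rank_a, rank_b, max_gap) {
  n <- length(rank_a)
  if (n == 0) return(0L)
  best <- 0L
  for (anti in c(FALSE, TRUE)) {
    ext <- function(i, len) {
      best <<- max(best, len)
      for (j in seq_len(n)) {
        ok_a <- rank_a[j] > rank_a[i] && rank_a[j] - rank_a[i] <= max_gap + 1L
        ok_b <- if (anti) {
          rank_b[j] < rank_b[i] && rank_b[i] - rank_b[j] <= max_gap + 1L
        } else {
          rank_b[j] > rank_b[i] && rank_b[j] - rank_b[i] <= max_gap + 1L
        }
        if (ok_a && ok_b) ext(j, len + 1L)
      }
    }
    for (i in seq_len(n)) ext(i, 1L)
  }
  best
}

# Brute-force change point: cut position maximizing flank vote purity.
oracle_change_point <- function(votes, up, down) {
  n <- length(votes)
  score <- vapply(seq_len(n - 1L), function(c) {
    sum(votes[seq_len(c)] == up) + sum(votes[(c + 1L):n] == down)
  }, 1)
  which.max(score)
}

# Small cached trio used across unit tests (1 chromosome, 40 loci).
tiny_model <- function(seed = 42L) {
  ancestor_model(n_chromosomes = 1L, chrom_length = 120000L,
                 n_genes_per_chrom = 40L, seed = seed)
}

.trio_cache <- new.env(parent = emptyenv())
cached_trio <- function(key, expr) {
  if (!exists(key, envir = .trio_cache)) {
    assign(key, force(expr), envir = .trio_cache)
  }
  get(key, envir = .trio_cache)
}

tiny_trio <- function() {
  cached_trio("tiny", suppressMessages(
    simulate_trio(tiny_model(), k_switches = 2L, min_sep = 8L,
                  edge_margin = 6L)))
}

tiny_noise0_trio <- function() {
  cached_trio("noise0", {
    m <- ancestor_model(n_chromosomes = 1L, chrom_length = 80000L,
                        n_genes_per_chrom = 25L, seed = 7L)
    anc <- simulate_ancestors(m)
    compose_hybrids(anc, noise_factor = 0)
  })
}

tiny_hits <- function() {
  cached_trio("tiny_hits", {
    trio <- tiny_trio()
    trio_best_hits(trio$assemblies, trio$catalog)
  })
}
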