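# broom-style accessors and ggplot2 views of result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @describeIn rank_sum_test One row per group with its summary.
#' @param x A `haplotrio_rank_sum` object.
#' @param ... Unused.
#' @export
tidy.haplotrio_rank_sum <- function(x, ...) {
  tibble(group = c("group1", "group2"), n = c(x$n1, x$n2),
         mean = c(x$mean1, x$mean2))
}

#' @describeIn rank_sum_test One-row model summary (`W`, `p.value`, method).
#' @export
glance.haplotrio_rank_sum <- function(x, ...) {
  tibble(statistic = x$W, p.value = x$p_value, method = x$method,
         n1 = x$n1, n2 = x$n2)
}

#' @describeIn grouped_similarity Per-comparison table.
#' @param x A `haplotrio_group_comparison` object.
#' @param ... Unused.
#' @export
tidy.haplotrio_group_comparison <- function(x, ...) x$pair_table

#' @describeIn grouped_similarity One-row summary with group means and the
#'   rank-sum test.
#' @export
glance.haplotrio_group_comparison <- function(x, ...) {
  tibble(shared_mean = mean(x$shared_group),
         nonshared_mean = mean(x$nonshared_group),
         n_shared = length(x$shared_group),
         n_nonshared = length(x$nonshared_group),
         statistic = x$test$W, p.value = x$test$p_value,
         method = x$test$method)
}

#' @describeIn grouped_similarity Similarity distributions of shared- vs
#'   non-shared-species haplotype pairs.
#' @param object A `haplotrio_group_comparison`.
#' @export
autoplot.haplotrio_group_comparison <- function(object, ...) {
  d <- object$pair_table %>%
    mutate(group = if_else(.data$shared, "shared species", "different species"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$similarity_pct,
                                  fill = .data$group)) +
    ggplot2::geom_boxplot(alpha = 0.6, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.12, height = 0, size = 1.5) +
    ggplot2::labs(x = NULL, y = "similarity (% length unaffected by variants)",
                  title = sprintf("W = %g, p = %.2g (%s)", object$test$W,
                                  object$test$p_value, object$test$method)) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Plot a per-locus assignment profile
#'
#' Mirrors the track structure of a haplotype-similarity plot: one point per
#' locus at its position, colored by the parental-species vote, faceted by
#' haplotype. Switch events, if supplied, are drawn as vertical breakpoint
#' intervals.
#'
#' @param profiles Profile tibble from [detect_all_switches()] (one genome,
#'   one chromosome; filter first if needed).
#' @param events Optional event tibble to overlay.
#' @return A ggplot object.
#' @export
plot_profile <- function(profiles, events = NULL) {
  p <- ggplot2::ggplot(profiles,
                       ggplot2::aes(x = (.data$start + .data$end) / 2,
                                    y = factor(.data$haplotype),
                                    color = .data$vote)) +
    ggplot2::geom_point(shape = 15, size = 2) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$genome, .data$chrom)) +
    ggplot2::labs(x = "position (bp)", y = "haplotype",
                  color = "parental vote") +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events) > 0) {
    p <- p + ggplot2::geom_vline(data = events,
                                 ggplot2::aes(xintercept = (.data$bp_start + .data$bp_end) / 2),
                                 linetype = "dashed")
  }
  p
}
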