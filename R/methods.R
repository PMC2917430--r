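# broom-style accessors and plotting methods for the result types.

#' Glance at a fitted DE table
#'
#' @param x a `de_table` from [fit_moderated_t()].
#' @param p_adj_max significance cutoff used for the `n_signif` count.
#' @param ... unused.
#' @return a one-row tibble: gene count, group sizes, residual and prior
#'   degrees of freedom, prior variance, whether the prior df were capped,
#'   and the number of significant genes.
#' @method glance de_table
#' @export
glance.de_table <- function(x, p_adj_max = 0.05, ...) {
  prior <- attr(x, "prior")
  groups <- attr(x, "groups")
  tibble::tibble(
    n_genes = nrow(x),
    n_ref = groups$n1, n_other = groups$n2,
    d = prior$d, d0 = prior$d0, s0_sq = prior$s0_sq,
    d0_capped = prior$d0_capped, df_total = groups$df,
    n_signif = sum(x$p_adj < p_adj_max)
  )
}

#' Tidy the hit positions of an enrichment result
#'
#' @param x an `enrichment_result` from [enrich_signature()].
#' @param ... unused.
#' @return a tibble with one row per query gene found in the ranking:
#'   `gene_id`, `position`, and the cumulative hit fraction at that
#'   position.
#' @method tidy enrichment_result
#' @export
tidy.enrichment_result <- function(x, ...) {
  tibble::tibble(
    gene_id = x$gene_ids,
    position = x$positions,
    hit_fraction = seq_along(x$positions) / x$k
  )
}

#' One-row summary of an enrichment result
#'
#' @param x an `enrichment_result`.
#' @param ... unused.
#' @method glance enrichment_result
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble::tibble(
    n = x$n, k = x$k, ks = x$ks,
    n_perm = x$n_perm, count_ge = x$count_ge,
    p_empirical = x$p_empirical, p_conservative = x$p_conservative,
    seed = x$seed, mode = x$mode
  )
}

#' One-row summary of a meta-profiling run
#'
#' @param x a `meta_profiling` object from [run_meta_profiling()].
#' @param ... unused.
#' @method glance meta_profiling
#' @export
glance.meta_profiling <- function(x, ...) {
  tibble::tibble(
    n_cellline_in = x$variation_report$n_in,
    n_cellline_kept = x$variation_report$n_kept,
    n_signature = length(x$signature$gene_ids),
    n_compendium_in = x$compendium_report$n_in,
    n_compendium_kept = x$compendium_report$n_kept,
    n_mapped = nrow(x$mapping),
    n_ranked = x$enrichment$n,
    k = x$enrichment$k,
    ks = x$enrichment$ks,
    p_empirical = x$enrichment$p_empirical,
    p_conservative = x$enrichment$p_conservative,
    n_top = nrow(x$top)
  )
}

#' Running-sum enrichment plot
#'
#' Draws the hit/miss running sum across the ranked list, with a rug of the
#' query-gene positions and a marker at the maximum (the KS score).
#'
#' @param object an `enrichment_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, ...) {
  n <- object$n; k <- object$k
  step <- rep(-1 / (n - k), n)
  step[object$positions] <- 1 / k
  running <- cumsum(step)
  df <- tibble::tibble(position = seq_len(n), running_sum = running)
  peak <- which.max(c(0, running))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position,
                                   y = .data$running_sum)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_rug(
      data = tibble::tibble(position = object$positions),
      ggplot2::aes(x = .data$position), inherit.aes = FALSE,
      sides = "b", colour = "firebrick", length = ggplot2::unit(0.04, "npc")) +
    ggplot2::annotate("point", x = max(peak - 1, 1), y = object$ks,
                      colour = "firebrick") +
    ggplot2::labs(
      x = "rank (ascending Pearson distance to reference)",
      y = "running sum",
      title = sprintf("KS = %.3f, p = %g (%d of %d permutations)",
                      object$ks, object$p_empirical, object$count_ge,
                      object$n_perm)) +
    ggplot2::theme_minimal()
}

#' Volcano plot of a DE table
#'
#' @param object a `de_table`.
#' @param p_adj_max,fold_min thresholds used to colour selected genes.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot de_table
#' @export
autoplot.de_table <- function(object, p_adj_max = 0.05, fold_min = 2, ...) {
  df <- tibble::as_tibble(object)
  df$selected <- df$p_adj < p_adj_max & df$signed_fc >= fold_min
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(.data$p_adj),
                                   colour = .data$selected)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick"),
                                 name = "in signature") +
    ggplot2::geom_hline(yintercept = -log10(p_adj_max),
                        linetype = "dashed", colour = "grey60") +
    ggplot2::labs(x = "log2 fold change (reference / other)",
                  y = "-log10 adjusted p") +
    ggplot2::theme_minimal()
}

#' Distance-vs-rank plot of a neighbor ranking
#'
#' @param object a `neighbor_ranking`.
#' @param query optional gene ids to highlight.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot neighbor_ranking
#' @export
autoplot.neighbor_ranking <- function(object, query = NULL, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rank,
                                        y = .data$distance)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::labs(x = "rank", y = "Pearson distance to reference",
                  title = sprintf("reference: %s",
                                  attr(object, "reference_gene"))) +
    ggplot2::theme_minimal()
  if (!is.null(query)) {
    ids <- if (inherits(query, "signature_query")) query$gene_ids else query
    p <- p + ggplot2::geom_point(
      data = df[df$gene_id %in% ids, , drop = FALSE],
      colour = "firebrick", size = 1.5)
  }
  p
}

#' Write a DE table as TSV
#'
#' Fixed column set: `gene_id mean_ref mean_other log2fc signed_fc t_mod
#' p_raw p_adj`.
#'
#' @param de a `de_table`.
#' @param path output path.
#' @export
write_de_table <- function(de, path) {
  cols <- c("gene_id", "mean_ref", "mean_other", "log2fc", "signed_fc",
            "t_mod", "p_raw", "p_adj")
  utils::write.table(as.data.frame(de)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a neighbor ranking as TSV (`rank gene_id distance`)
#'
#' @param ranking a `neighbor_ranking`.
#' @param path output path.
#' @export
write_ranking <- function(ranking, path) {
  utils::write.table(as.data.frame(ranking)[, c("rank", "gene_id", "distance")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a filter report as TSV (removed genes tagged with their rule)
#'
#' @param report a `filter_report`.
#' @param path output path.
#' @export
write_filter_report <- function(report, path) {
  abort_if(!inherits(report, "filter_report"),
           "`report` must be a filter_report")
  utils::write.table(as.data.frame(report$removed), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
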