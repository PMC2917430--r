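# End-to-end meta-profiling: cell-line DE signature -> compendium ranking
# -> positional KS enrichment.

#' Parameters of the meta-profiling pipeline
#'
#' Collects every analysis constant in one validated object: the variation
#' filter (log2 IQR > 0.5, one sample > 100), the compendium filter (< 50 /
#' > 15000 in a strict majority of arrays; >= 2-fold and >= 50-unit spread),
#' the signature thresholds (adjusted p < 0.05, >= 2-fold up in the
#' reference condition), the number of nearest signature genes to report
#' (14) and the permutation budget (100,000).
#'
#' @param p_adj_max,fold_min signature-selection thresholds.
#' @param k_select how many nearest signature genes to report (capped at the
#'   mapped signature size at run time).
#' @param n_perm permutations for the KS null.
#' @param low,high,majority,comp_fold_min,comp_diff_min compendium-filter
#'   thresholds.
#' @param iqr_min,intensity_min variation-filter thresholds.
#' @param mode permutation mode, `"sampled"` or `"exhaustive"`.
#' @param seed integer seed governing the permutation draws; required.
#' @return a validated `pipeline_params` object.
#' @export
pipeline_params <- function(p_adj_max = 0.05, fold_min = 2, k_select = 14,
                            n_perm = 100000, low = 50, high = 15000,
                            majority = 0.5, comp_fold_min = 2,
                            comp_diff_min = 50, iqr_min = 0.5,
                            intensity_min = 100,
                            mode = c("sampled", "exhaustive"), seed) {
  abort_if(missing(seed), "`seed` is required")
  mode <- match.arg(mode)
  abort_if(k_select < 1, "`k_select` must be >= 1")
  abort_if(any(c(p_adj_max, fold_min, n_perm, low, high, majority,
                 comp_fold_min, comp_diff_min, iqr_min, intensity_min) <= 0),
           "all thresholds must be positive")
  structure(
    list(p_adj_max = p_adj_max, fold_min = fold_min, k_select = k_select,
         n_perm = n_perm, low = low, high = high, majority = majority,
         comp_fold_min = comp_fold_min, comp_diff_min = comp_diff_min,
         iqr_min = iqr_min, intensity_min = intensity_min,
         mode = mode, seed = as.integer(seed)),
    class = "pipeline_params"
  )
}

#' Run the full coexpression-signature meta-profiling pipeline
#'
#' Stages, in order: variation-filter the cell-line matrix; fit the
#' moderated t and BH-adjust; select the up-in-reference signature
#' (excluding the reference gene itself); compendium-filter the tumor
#' matrix; map signature ids onto the compendium; rank compendium genes by
#' Pearson distance to the reference gene; score the mapped signature's
#' positions with the running-sum KS statistic and a permutation null drawn
#' from the filtered gene universe (the ranking excludes the reference);
#' report the `k_select` signature genes nearest the reference.
#'
#' @param cellline_matrix two-condition genes x arrays intensity matrix.
#' @param cellline_classes its class labels (tibble or vector).
#' @param compendium_matrix tumor-compendium genes x specimens matrix.
#' @param reference_gene id of the reference gene (present in the
#'   compendium).
#' @param params a [pipeline_params()].
#' @param reference_class reference condition label in the cell-line
#'   experiment (default: first label encountered).
#' @param verbose emit stage-tagged counts to standard error.
#' @return a `meta_profiling` object: `de` (DE table), `signature`,
#'   `mapping`, `ranking`, `top` (nearest signature genes), `enrichment`,
#'   per-filter reports, a stage `log` tibble and the params used.
#' @export
run_meta_profiling <- function(cellline_matrix, cellline_classes,
                               compendium_matrix, reference_gene,
                               params, reference_class = NULL,
                               verbose = TRUE) {
  abort_if(!inherits(params, "pipeline_params"),
           "`params` must come from pipeline_params()")
  abort_if(!reference_gene %in% rownames(compendium_matrix),
           sprintf("reference gene '%s' absent from the compendium",
                   reference_gene))
  log <- list()
  say <- function(stage, fmt, ...) {
    msg <- sprintf(fmt, ...)
    log[[length(log) + 1]] <<- tibble::tibble(stage = stage, detail = msg)
    if (verbose) message(sprintf("[%s] %s", stage, msg))
  }

  vf <- variation_filter(cellline_matrix, iqr_min = params$iqr_min,
                         intensity_min = params$intensity_min)
  say("variation_filter", "n_in=%d n_kept=%d", vf$report$n_in,
      vf$report$n_kept)

  de <- fit_moderated_t(vf$matrix, cellline_classes,
                        reference_class = reference_class)
  say("differential_expression", "genes=%d signif(p_adj<%g)=%d",
      nrow(de), params$p_adj_max, sum(de$p_adj < params$p_adj_max))

  signature <- select_coexpressed_signature(
    de, p_adj_max = params$p_adj_max, fold_min = params$fold_min,
    reference_gene = reference_gene)
  say("signature", "selected=%d (up in reference)",
      length(signature$gene_ids))

  cf <- compendium_filter(compendium_matrix, low = params$low,
                          high = params$high, majority = params$majority,
                          fold_min = params$comp_fold_min,
                          diff_min = params$comp_diff_min)
  say("compendium_filter", "n_in=%d n_kept=%d", cf$report$n_in,
      cf$report$n_kept)
  ref_removed <- cf$report$removed[
    cf$report$removed$gene_id == reference_gene, , drop = FALSE]
  abort_if(nrow(ref_removed) > 0,
           sprintf("reference gene '%s' removed by the compendium filter (rule: %s)",
                   reference_gene, ref_removed$rule[1]))

  mapping <- map_gene_ids(signature$gene_ids, cf$matrix)
  say("mapping", "signature=%d mapped=%d dropped=%d",
      length(signature$gene_ids), nrow(mapping),
      length(attr(mapping, "dropped")))
  abort_if(nrow(mapping) < 2,
           sprintf("mapped signature has %d gene(s); need at least 2",
                   nrow(mapping)))

  ranking <- rank_neighbors(cf$matrix, reference_gene)
  say("ranking", "genes ranked=%d", nrow(ranking))

  enrichment <- enrich_signature(ranking, mapping$target_row,
                                 n_perm = params$n_perm,
                                 seed = params$seed, mode = params$mode)
  say("enrichment", "k=%d ks=%.4f p_empirical=%g p_conservative=%g",
      enrichment$k, enrichment$ks, enrichment$p_empirical,
      enrichment$p_conservative)

  k_eff <- min(params$k_select, enrichment$k)
  if (k_eff < params$k_select) {
    say("top_k", "k_select=%d capped at mapped signature size %d",
        params$k_select, enrichment$k)
    warning(sprintf("k_select = %d capped at mapped signature size %d",
                    params$k_select, enrichment$k), call. = FALSE)
  }
  top <- select_top_k(ranking, enrichment$gene_ids, k_eff)
  say("top_k", "reported %d nearest signature genes", nrow(top))

  structure(
    list(de = de, signature = signature, mapping = mapping,
         ranking = ranking, top = top, enrichment = enrichment,
         variation_report = vf$report, compendium_report = cf$report,
         log = dplyr::bind_rows(log), params = params),
    class = "meta_profiling"
  )
}

#' @export
print.meta_profiling <- function(x, ...) {
  cat("<meta_profiling>\n")
  cat(sprintf("  cell line: %d/%d genes past variation filter, %d in signature\n",
              x$variation_report$n_kept, x$variation_report$n_in,
              length(x$signature$gene_ids)))
  cat(sprintf("  compendium: %d/%d genes past filter, %d signature genes mapped\n",
              x$compendium_report$n_kept, x$compendium_report$n_in,
              nrow(x$mapping)))
  cat(sprintf("  KS = %.4f, p_empirical = %g (%d permutations)\n",
              x$enrichment$ks, x$enrichment$p_empirical,
              x$enrichment$n_perm))
  cat(sprintf("  top %d genes: %s\n", nrow(x$top),
              paste(head(x$top$gene_id, 14), collapse = ", ")))
  invisible(x)
}
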