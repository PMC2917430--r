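# Pearson-distance neighbor ranking around a reference gene.

#' Pearson distance between two expression profiles
#'
#' `1 - r`, where `r` is the Pearson correlation; 0 for identical patterns,
#' 2 for perfect anticorrelation. Small distance = coexpressed.
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return the distance in \[0, 2\].
#' @export
pearson_distance <- function(x, y) {
  abort_if(length(x) != length(y), "profiles must have equal length")
  abort_if(length(x) < 3, "profiles need at least 3 samples")
  abort_if(sd(x) == 0 || sd(y) == 0,
           "undefined correlation: constant profile")
  1 - cor(x, y)
}

#' Rank all genes by Pearson distance to a reference gene
#'
#' Every non-reference, non-constant gene receives
#' `distance = 1 - cor(gene, reference)` and an ascending 1-based rank.
#' Ties are broken by lexicographic gene id. Constant genes are excluded
#' with a warning and listed in the `"excluded"` attribute.
#'
#' @param matrix genes x samples intensity matrix (typically already passed
#'   through [compendium_filter()]).
#' @param reference_gene row id of the reference gene.
#' @param log2_scale correlate log2 intensities instead of the raw scale
#'   (default `FALSE`, matching GeneNeighbors-era practice).
#' @return a `neighbor_ranking` tibble (`rank`, `gene_id`, `distance`) with
#'   the reference gene id attached as an attribute.
#' @examples
#' m <- rbind(R = c(1, 2, 3, 4), A = c(1, 3, 2, 4),
#'            B = c(4, 3, 2, 1), C = c(2, 3, 4, 5))
#' colnames(m) <- paste0("s", 1:4)
#' rank_neighbors(m, "R")
#' @export
rank_neighbors <- function(matrix, reference_gene, log2_scale = FALSE) {
  check_expression_matrix(matrix)
  abort_if(!reference_gene %in% rownames(matrix),
           sprintf("reference gene '%s' not in matrix", reference_gene))
  vals <- if (log2_scale) log2(pmax(matrix, 1)) else matrix
  ref <- vals[reference_gene, ]
  abort_if(sd(ref) == 0, "reference gene has a constant profile")

  others <- vals[setdiff(rownames(vals), reference_gene), , drop = FALSE]
  sds <- apply(others, 1, sd)
  constant <- rownames(others)[sds == 0]
  if (length(constant) > 0) {
    warning(sprintf("%d constant gene(s) excluded from ranking",
                    length(constant)), call. = FALSE)
    others <- others[sds > 0, , drop = FALSE]
  }
  distance <- as.numeric(1 - cor(ref, t(others)))
  ord <- order(distance, rownames(others), method = "radix")
  out <- tibble::tibble(
    rank = seq_along(ord),
    gene_id = rownames(others)[ord],
    distance = distance[ord]
  )
  attr(out, "reference_gene") <- reference_gene
  attr(out, "excluded") <- constant
  class(out) <- c("neighbor_ranking", class(out))
  out
}

#' Select the k query genes nearest to the reference
#'
#' @param ranking a `neighbor_ranking` from [rank_neighbors()].
#' @param query a `signature_query` or a character vector of gene ids.
#' @param k how many of the query genes to keep (their smallest distances,
#'   ascending); must not exceed the number of query genes in the ranking.
#' @return a tibble (`rank`, `gene_id`, `distance`) of the k closest query
#'   genes.
#' @export
select_top_k <- function(ranking, query, k) {
  ids <- if (inherits(query, "signature_query")) query$gene_ids else query
  hits <- ranking[ranking$gene_id %in% ids, , drop = FALSE]
  abort_if(k > nrow(hits),
           sprintf("k = %d exceeds the %d query genes present in the ranking",
                   k, nrow(hits)))
  out <- head(hits[order(hits$distance, hits$gene_id), , drop = FALSE], k)
  tibble::as_tibble(out)
}
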