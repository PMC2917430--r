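# Running-sum KS positional statistic and its permutation null.

#' Running-sum KS score of hit positions in a ranked list
#'
#' Walking the ranked list from position 1 to n, the running sum gains
#' `+1/k` at each hit (query-gene) position and `-1/(n-k)` elsewhere. The
#' score is the maximum of the running sum over all prefixes, including the
#' empty prefix (value 0), so it lies in \[0, 1\]: 1 when all hits are
#' front-loaded, 0 when the sum never rises above the start. This is the
#' one-sided D+ deviation of the hit positions' empirical distribution from
#' discrete uniform, in the unweighted running-sum convention.
#'
#' @param positions sorted 1-based hit positions (strictly increasing).
#' @param n ranked-list length.
#' @param k query size (defaults to `length(positions)`; must satisfy
#'   `1 <= k < n`).
#' @return the KS score in \[0, 1\].
#' @examples
#' ks_score(c(1, 3), n = 4)  # prefix sums 0.5, 0, 0.5, 0 -> 0.5
#' @export
ks_score <- function(positions, n, k = length(positions)) {
  abort_if(k == 0 || k >= n,
           "KS statistic undefined: need 1 <= k < n")
  abort_if(length(positions) != k,
           "`positions` must have length k")
  abort_if(any(positions < 1 | positions > n) ||
             any(diff(positions) <= 0),
           "`positions` must be strictly increasing within [1, n]")
  i <- seq_len(k)
  # the running sum peaks immediately after a hit:
  # value after the i-th hit = i/k - (positions[i] - i)/(n - k)
  max(0, max(i / k - (positions - i) / (n - k)))
}

# Same statistic for a batch of sorted position matrices (rows = draws).
ks_score_rows <- function(pos_sorted, n, k) {
  i <- seq_len(k)
  dev <- matrix(i / k, nrow(pos_sorted), k, byrow = TRUE) -
    sweep(pos_sorted, 2, i) / (n - k)
  pmax(0, apply(dev, 1, max))
}

#' Empirical p-values from a permutation tail count
#'
#' @param count_ge number of permutations whose score equalled or exceeded
#'   the observed one.
#' @param n_perm total permutations.
#' @return a list with `p_empirical = count_ge / n_perm` (the plain
#'   frequency, which can be 0) and the add-one conservative
#'   `p_conservative = (count_ge + 1) / (n_perm + 1)`.
#' @export
empirical_pvalue <- function(count_ge, n_perm) {
  abort_if(n_perm < 1 || count_ge < 0 || count_ge > n_perm,
           "need 0 <= count_ge <= n_perm, n_perm >= 1")
  list(p_empirical = count_ge / n_perm,
       p_conservative = (count_ge + 1) / (n_perm + 1))
}

#' Permutation null for the KS score
#'
#' In `"sampled"` mode, draws `n_perm` uniform k-subsets of `{1..n}`
#' (without replacement within a draw, independent across draws under
#' `seed`) and counts how often their KS score equals or exceeds the
#' observed one (with an absolute tolerance of 1e-12 against float-order
#' artifacts). In `"exhaustive"` mode, enumerates all `choose(n, k)` subsets
#' and returns the exact tail fraction.
#'
#' @param n ranked-list length.
#' @param k query size.
#' @param observed_ks observed KS score.
#' @param n_perm number of permutations (sampled mode).
#' @param seed integer seed (sampled mode).
#' @param mode `"sampled"` or `"exhaustive"`.
#' @param exhaustive_cap refuse exhaustive enumeration beyond this many
#'   subsets (default 1e6); the error suggests sampled mode.
#' @return a list with `n_perm` (subsets scored), `count_ge`, `p_empirical`,
#'   `p_conservative` (equal to `p_empirical` in exhaustive mode, where the
#'   tail fraction is exact), `seed` and `mode`.
#' @export
permutation_pvalue <- function(n, k, observed_ks, n_perm = 100000,
                               seed = NULL,
                               mode = c("sampled", "exhaustive"),
                               exhaustive_cap = 1e6) {
  mode <- match.arg(mode)
  abort_if(k == 0 || k >= n, "need 1 <= k < n")
  tol <- 1e-12
  if (mode == "exhaustive") {
    total <- choose(n, k)
    abort_if(total > exhaustive_cap,
             sprintf(paste0("choose(%d, %d) = %g exceeds the exhaustive cap",
                            " (%g); use mode = 'sampled'"),
                     n, k, total, exhaustive_cap))
    subsets <- combn(n, k)
    scores <- apply(subsets, 2, ks_score, n = n, k = k)
    count_ge <- sum(scores >= observed_ks - tol)
    p <- count_ge / total
    return(list(n_perm = total, count_ge = count_ge,
                p_empirical = p, p_conservative = p,
                seed = NA_integer_, mode = "exhaustive"))
  }
  abort_if(n_perm < 1, "sampled mode needs n_perm >= 1")
  abort_if(is.null(seed), "sampled mode needs a `seed`")
  count_ge <- with_rng(seed, {
    .ks_perm_count_ge(as.integer(n), as.integer(k), observed_ks - tol,
                      as.integer(n_perm))
  })
  pv <- empirical_pvalue(count_ge, n_perm)
  list(n_perm = n_perm, count_ge = count_ge,
       p_empirical = pv$p_empirical, p_conservative = pv$p_conservative,
       seed = as.integer(seed), mode = "sampled")
}

#' Score a query gene set's positional enrichment in a neighbor ranking
#'
#' Locates the query genes in the ranking, computes the running-sum KS score
#' of their positions and attaches a permutation p-value.
#'
#' @param ranking a `neighbor_ranking` from [rank_neighbors()].
#' @param query a `signature_query` or character vector of gene ids; genes
#'   absent from the ranking are ignored.
#' @param n_perm,seed,mode,exhaustive_cap passed to [permutation_pvalue()].
#' @return an `enrichment_result`: list-length `n`, query size `k`, sorted
#'   hit `positions`, matching `gene_ids`, `ks`, and the permutation-null
#'   fields of [permutation_pvalue()].
#' @export
enrich_signature <- function(ranking, query, n_perm = 100000, seed = NULL,
                             mode = c("sampled", "exhaustive"),
                             exhaustive_cap = 1e6) {
  mode <- match.arg(mode)
  ids <- if (inherits(query, "signature_query")) query$gene_ids else query
  hits <- ranking[ranking$gene_id %in% ids, , drop = FALSE]
  n <- nrow(ranking)
  k <- nrow(hits)
  abort_if(k < 1, "no query genes present in the ranking")
  abort_if(k >= n, "query covers the whole ranking; KS undefined")
  ord <- order(hits$rank)
  positions <- hits$rank[ord]
  ks <- ks_score(positions, n = n, k = k)
  perm <- permutation_pvalue(n, k, ks, n_perm = n_perm, seed = seed,
                             mode = mode, exhaustive_cap = exhaustive_cap)
  structure(
    c(list(n = n, k = k, positions = positions,
           gene_ids = hits$gene_id[ord], ks = ks), perm),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> k = %d hits in a list of %d\n", x$k, x$n))
  cat(sprintf("  KS score:        %.4f\n", x$ks))
  cat(sprintf("  permutations:    %d (%s), %d with KS >= observed\n",
              x$n_perm, x$mode, x$count_ge))
  cat(sprintf("  p (frequency):   %.6g\n", x$p_empirical))
  cat(sprintf("  p (add-one):     %.6g\n", x$p_conservative))
  invisible(x)
}
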