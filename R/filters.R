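# Gene filters and gene-identifier mapping.

new_filter_report <- function(n_in, removed) {
  structure(
    list(n_in = n_in, n_kept = n_in - nrow(removed), removed = removed),
    class = "filter_report"
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %d in, %d kept, %d removed\n",
              x$n_in, x$n_kept, nrow(x$removed)))
  if (nrow(x$removed) > 0) print(dplyr::count(x$removed, .data$rule))
  invisible(x)
}

#' Variation filter for informative genes
#'
#' Keeps a gene iff the interquartile range of its log2 intensities (values
#' floored at 1 before the log, type-7 quantiles) exceeds `iqr_min` and at
#' least one sample exceeds `intensity_min` on the raw scale. Input gene
#' order is preserved.
#'
#' @param matrix genes x samples intensity matrix.
#' @param iqr_min minimum log2-scale interquartile range (exclusive;
#'   default 0.5).
#' @param intensity_min raw intensity at least one sample must exceed
#'   (exclusive; default 100).
#' @param log2_scale compute the IQR on log2 intensities (default) or on the
#'   raw scale.
#' @return a list with the filtered `matrix` and a `report` (counts plus a
#'   tibble of removed genes tagged with the rule each one failed).
#' @examples
#' m <- rbind(flat = rep(500, 4), dim = c(80, 90, 70, 60),
#'            ok = c(100, 150, 300, 800))
#' colnames(m) <- paste0("s", 1:4)
#' variation_filter(m)$report
#' @export
variation_filter <- function(matrix, iqr_min = 0.5, intensity_min = 100,
                             log2_scale = TRUE) {
  check_expression_matrix(matrix)
  abort_if(nrow(matrix) == 0, "empty matrix")
  vals <- if (log2_scale) log2(pmax(matrix, 1)) else matrix
  q <- apply(vals, 1, quantile, probs = c(0.25, 0.75), names = FALSE,
             type = 7)
  iqr_ok <- (q[2, ] - q[1, ]) > iqr_min
  int_ok <- apply(matrix, 1, max) > intensity_min
  keep <- iqr_ok & int_ok
  rule <- dplyr::case_when(
    !int_ok ~ "max_intensity",
    !iqr_ok ~ "iqr",
    TRUE ~ NA_character_
  )
  removed <- tibble::tibble(gene_id = rownames(matrix)[!keep],
                            rule = rule[!keep])
  list(matrix = matrix[keep, , drop = FALSE],
       report = new_filter_report(nrow(matrix), removed))
}

#' Compendium intensity and dynamic-range filter
#'
#' First removes genes whose expression is overly low or overly high in a
#' strict majority of samples (fraction of samples `< low` exceeding
#' `majority`, or fraction `> high` exceeding `majority`). Of the survivors
#' it keeps a gene iff its fold spread `max / max(min, 1)` is at least
#' `fold_min` and its absolute spread `max - min` is at least `diff_min`.
#' Input gene order is preserved.
#'
#' @param matrix genes x samples intensity matrix.
#' @param low,high intensity bounds (defaults 50 and 15000 relative units).
#' @param majority fraction of samples that must violate a bound for removal
#'   (strict; default 0.5).
#' @param fold_min minimum max/min fold spread (default 2); the denominator
#'   is clamped at 1.
#' @param diff_min minimum max - min spread (default 50 relative units).
#' @return a list with the filtered `matrix` and a `report` tagging each
#'   removed gene with `mostly_low`, `mostly_high`, `fold` or `diff`.
#' @export
compendium_filter <- function(matrix, low = 50, high = 15000, majority = 0.5,
                              fold_min = 2, diff_min = 50) {
  check_expression_matrix(matrix)
  abort_if(nrow(matrix) == 0, "empty matrix")
  frac_low <- rowMeans(matrix < low)
  frac_high <- rowMeans(matrix > high)
  mx <- apply(matrix, 1, max)
  mn <- apply(matrix, 1, min)
  fold_ok <- mx / pmax(mn, 1) >= fold_min
  diff_ok <- (mx - mn) >= diff_min
  rule <- dplyr::case_when(
    frac_low > majority ~ "mostly_low",
    frac_high > majority ~ "mostly_high",
    !fold_ok ~ "fold",
    !diff_ok ~ "diff",
    TRUE ~ NA_character_
  )
  keep <- is.na(rule)
  removed <- tibble::tibble(gene_id = rownames(matrix)[!keep],
                            rule = rule[!keep])
  list(matrix = matrix[keep, , drop = FALSE],
       report = new_filter_report(nrow(matrix), removed))
}

#' Map source gene identifiers onto the rows of a target expression table
#'
#' Matches symbols case-insensitively. Source ids absent from the target are
#' dropped and reported. When several target rows carry the same symbol
#' (multiple probe sets per gene), the `collapse` policy decides:
#' `"max_mean"` keeps the row with the greatest mean intensity, `"first"`
#' the first occurrence, `"error"` refuses.
#'
#' @param source_ids character vector of query identifiers.
#' @param target_matrix genes/probes x samples matrix; rownames are probe or
#'   row ids.
#' @param target_symbols symbol per target row (defaults to the rownames;
#'   pass a symbol column to map probe-level tables).
#' @param collapse duplicate-symbol policy: `"max_mean"`, `"first"` or
#'   `"error"`.
#' @return a tibble with `source_id`, `target_row` (rowname in the target)
#'   and `symbol`; dropped source ids are kept in the `"dropped"` attribute.
#'   An empty intersection yields an empty mapping with a warning.
#' @export
map_gene_ids <- function(source_ids, target_matrix,
                         target_symbols = rownames(target_matrix),
                         collapse = c("max_mean", "first", "error")) {
  collapse <- match.arg(collapse)
  abort_if(!is.matrix(target_matrix) || is.null(rownames(target_matrix)),
           "`target_matrix` must be a matrix with rownames")
  abort_if(length(target_symbols) != nrow(target_matrix),
           "`target_symbols` must have one entry per target row")
  src <- unique(as.character(source_ids))
  key_t <- toupper(target_symbols)

  pick_row <- function(sym) {
    rows <- which(key_t == sym)
    if (length(rows) > 1) {
      if (collapse == "error")
        stop(sprintf("symbol %s matches %d target rows", sym, length(rows)),
             call. = FALSE)
      if (collapse == "max_mean")
        rows <- rows[which.max(rowMeans(target_matrix[rows, , drop = FALSE]))]
      else rows <- rows[1]
    }
    rows
  }

  key_s <- toupper(src)
  found <- key_s %in% key_t
  hits <- vapply(key_s[found], pick_row, integer(1))
  mapping <- tibble::tibble(
    source_id = src[found],
    target_row = rownames(target_matrix)[hits],
    symbol = target_symbols[hits]
  )
  dropped <- src[!found]
  if (length(src) > 0 && nrow(mapping) == 0) {
    warning("no source ids could be mapped onto the target", call. = FALSE)
  }
  attr(mapping, "dropped") <- dropped
  mapping
}
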