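# Two-group moderated-t differential expression with empirical-Bayes
# variance shrinkage, plus the signed fold-change convention, BH adjustment,
# signature selection and the delta-delta-Ct qPCR utility.

#' Construct a moderated-variance prior
#'
#' The per-gene variance is shrunk toward `s0_sq` with `d0` prior degrees of
#' freedom: `s2_tilde = (d0 * s0_sq + d * s2) / (d0 + d)`. `d0 = 0` recovers
#' the ordinary pooled-variance t-test.
#'
#' @param d0 prior degrees of freedom (>= 0).
#' @param s0_sq prior variance (> 0 whenever `d0 > 0`).
#' @param d residual degrees of freedom per gene (may be `NA` until fitted).
#' @param d0_capped whether `d0` was substituted by a finite ceiling because
#'   the moment estimate diverged.
#' @return a `moderated_prior` object.
#' @export
moderated_prior <- function(d0, s0_sq, d = NA_real_, d0_capped = FALSE) {
  abort_if(!is.numeric(d0) || d0 < 0, "`d0` must be >= 0")
  abort_if(d0 > 0 && (!is.numeric(s0_sq) || s0_sq <= 0),
           "`s0_sq` must be > 0 when d0 > 0")
  structure(list(d0 = d0, s0_sq = s0_sq, d = d, d0_capped = d0_capped),
            class = "moderated_prior")
}

# Newton inversion of the trigamma function (solves trigamma(x) = y, y > 0).
trigamma_inverse <- function(y) {
  stopifnot(is.finite(y), y > 0)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-8) break
  }
  x
}

#' Estimate the empirical-Bayes variance prior from per-gene variances
#'
#' Moment matching under the scaled-inverse-chi-squared model: on the log
#' scale, `log(s2)` is a shifted log-F with `var(log s2)` equal to
#' `trigamma(d/2) + trigamma(d0/2)`. The prior df solve the trigamma
#' equation; when the observed spread of `log(s2)` does not exceed its
#' theoretical minimum the estimate diverges and `d0` is set to `d0_cap`
#' (flagged in the result).
#'
#' @param sample_variances per-gene sample variances (only positive values
#'   enter the moment fit; at least 10 required).
#' @param d residual degrees of freedom shared by the variances.
#' @param d0_cap finite ceiling used when the estimate diverges
#'   (default `10 * d`).
#' @return a [moderated_prior()] with estimated `d0` and `s0_sq`.
#' @export
estimate_prior <- function(sample_variances, d, d0_cap = 10 * d) {
  abort_if(!is.numeric(d) || length(d) != 1 || d <= 0,
           "`d` must be a positive scalar")
  s2 <- sample_variances[is.finite(sample_variances) & sample_variances > 0]
  abort_if(all(sample_variances == 0),
           "degenerate model: all sample variances are zero")
  abort_if(length(s2) < 10,
           "need at least 10 genes with positive sample variance")
  z <- log(s2)
  zbar <- mean(z)
  rhs <- var(z) - trigamma(d / 2)
  if (is.finite(rhs) && rhs > 0) {
    d0 <- 2 * trigamma_inverse(rhs)
    s0_sq <- exp(zbar - digamma(d / 2) + log(d / 2) +
                   digamma(d0 / 2) - log(d0 / 2))
    capped <- FALSE
    if (d0 > d0_cap) {
      d0 <- d0_cap
      capped <- TRUE
    }
  } else {
    d0 <- d0_cap
    s0_sq <- exp(zbar)
    capped <- TRUE
  }
  moderated_prior(d0 = d0, s0_sq = s0_sq, d = d, d0_capped = capped)
}

#' Moderated two-group differential expression
#'
#' Fits the two-group contrast on log2 intensities. Per gene, the log2
#' difference of group means `delta = mean(log2 ref) - mean(log2 other)` is
#' standardized by the shrunken variance
#' `s2_tilde = (d0 * s0_sq + d * s2) / (d0 + d)` to give
#' `t_mod = delta / sqrt(s2_tilde * (1/n1 + 1/n2))`, with two-sided p-values
#' from the t distribution on `d0 + d` degrees of freedom. Fold changes are
#' reported from raw-scale group means, both as `log2fc` and as the signed
#' array-era convention of [signed_fold_change()]. `p_adj` is the
#' Benjamini-Hochberg adjustment of `p_raw`.
#'
#' @param matrix genes x samples positive intensity matrix.
#' @param classes sample class labels (two classes, >= 2 samples each):
#'   a tibble with `sample_id`/`label` or a vector aligned with the columns.
#' @param reference_class label of the reference condition (group 1);
#'   defaults to the first label encountered.
#' @param prior a [moderated_prior()] to use as-is, or `NULL` to estimate it
#'   from the data with [estimate_prior()].
#' @return a `de_table` tibble (one row per gene: `gene_id`, `mean_ref`,
#'   `mean_other`, `log2fc`, `signed_fc`, `s2`, `t_mod`, `p_raw`, `p_adj`)
#'   carrying the fitted prior and group sizes as attributes; see
#'   [glance.de_table()].
#' @export
fit_moderated_t <- function(matrix, classes, reference_class = NULL,
                            prior = NULL) {
  check_expression_matrix(matrix)
  abort_if(any(matrix <= 0), "intensities must be > 0 (log2 is taken internally)")
  labels <- normalize_class_labels(classes, colnames(matrix))
  lv <- unique(labels)
  abort_if(length(lv) != 2,
           sprintf("exactly two classes required, found %d", length(lv)))
  reference_class <- reference_class %||% lv[1]
  abort_if(!reference_class %in% lv,
           sprintf("reference class '%s' not among labels", reference_class))
  g1 <- labels == reference_class
  n1 <- sum(g1); n2 <- sum(!g1)
  abort_if(n1 < 2 || n2 < 2,
           "insufficient replication: each class needs >= 2 samples")

  lm1 <- log2(matrix[, g1, drop = FALSE])
  lm2 <- log2(matrix[, !g1, drop = FALSE])
  delta <- rowMeans(lm1) - rowMeans(lm2)
  d <- n1 + n2 - 2
  v1 <- apply(lm1, 1, var)
  v2 <- apply(lm2, 1, var)
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d

  if (is.null(prior)) {
    prior <- estimate_prior(s2, d)
  } else {
    abort_if(!inherits(prior, "moderated_prior"),
             "`prior` must come from moderated_prior()")
    prior$d <- d
  }
  d0 <- prior$d0
  abort_if(d0 == 0 && all(s2 == 0),
           "degenerate model: zero within-group variance everywhere with d0 = 0")
  s0_sq <- if (d0 > 0) prior$s0_sq else 0
  s2_tilde <- if (is.infinite(d0)) {
    rep(s0_sq, length(s2))  # full shrinkage to the prior variance
  } else {
    (d0 * s0_sq + d * s2) / (d0 + d)
  }
  se <- sqrt(s2_tilde * (1 / n1 + 1 / n2))
  t_mod <- ifelse(se > 0, delta / se,
                  ifelse(delta == 0, 0, sign(delta) * Inf))
  df <- d0 + d
  p_raw <- 2 * pt(-abs(t_mod), df = df)

  mean_ref <- rowMeans(matrix[, g1, drop = FALSE])
  mean_other <- rowMeans(matrix[, !g1, drop = FALSE])
  out <- tibble::tibble(
    gene_id = rownames(matrix),
    mean_ref = unname(mean_ref),
    mean_other = unname(mean_other),
    log2fc = unname(log2(mean_ref / mean_other)),
    signed_fc = unname(signed_fold_change(mean_ref, mean_other)),
    s2 = unname(s2),
    t_mod = unname(t_mod),
    p_raw = unname(p_raw),
    p_adj = unname(bh_adjust(p_raw))
  )
  attr(out, "prior") <- prior
  attr(out, "groups") <- list(reference = reference_class,
                              other = setdiff(lv, reference_class),
                              n1 = n1, n2 = n2, df = df)
  class(out) <- c("de_table", class(out))
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values raw p-values in \[0, 1\].
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  abort_if(any(!is.finite(p_values) | p_values < 0 | p_values > 1),
           "p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Signed fold change between two positive group means
#'
#' The array-era convention: the ratio `r = mean_ref / mean_other` is
#' reported as `r` when `r >= 1` and as `-1/r` otherwise, so a 4-fold drop
#' in the reference condition prints as -4.
#'
#' @param mean_ref,mean_other positive group means (vectorized).
#' @return signed fold changes.
#' @export
signed_fold_change <- function(mean_ref, mean_other) {
  abort_if(any(mean_ref <= 0 | mean_other <= 0),
           "group means must be > 0")
  r <- mean_ref / mean_other
  ifelse(r >= 1, r, -1 / r)
}

#' Select the coexpressed (up-in-reference) signature from a DE table
#'
#' Keeps genes with `p_adj < p_adj_max` and `signed_fc >= fold_min`, i.e.
#' genes expressed at least `fold_min`-fold higher in the reference
#' condition with adjusted significance. The reference gene itself, when
#' given, is excluded from the query set.
#'
#' @param de a `de_table` from [fit_moderated_t()].
#' @param p_adj_max adjusted-p cutoff (exclusive; default 0.05).
#' @param fold_min minimum signed fold change (inclusive; default 2).
#' @param reference_gene optional id to exclude from the signature.
#' @return a `signature_query` (gene ids plus the thresholds used). An empty
#'   selection warns instead of failing.
#' @export
select_coexpressed_signature <- function(de, p_adj_max = 0.05, fold_min = 2,
                                         reference_gene = NULL) {
  abort_if(!all(c("gene_id", "signed_fc", "p_adj") %in% names(de)),
           "`de` must be a DE table with gene_id, signed_fc and p_adj")
  keep <- de$p_adj < p_adj_max & de$signed_fc >= fold_min
  ids <- de$gene_id[keep]
  if (!is.null(reference_gene)) ids <- setdiff(ids, reference_gene)
  if (length(ids) == 0) {
    warning("signature selection returned no genes", call. = FALSE)
  }
  structure(
    list(gene_ids = ids, direction = "up_in_reference",
         p_adj_max = p_adj_max, fold_min = fold_min,
         reference_gene = reference_gene),
    class = "signature_query"
  )
}

#' @export
print.signature_query <- function(x, ...) {
  cat(sprintf(
    "<signature_query> %d genes up in reference (p_adj < %g, fold >= %g)\n",
    length(x$gene_ids), x$p_adj_max, x$fold_min))
  invisible(x)
}

#' Relative expression by the 2^-ddCt method
#'
#' `ddCt = (Ct_target_trt - Ct_ref_trt) - (Ct_target_ctl - Ct_ref_ctl)`;
#' the relative expression of the target gene in the treated sample,
#' normalized to a reference gene and a control sample, is `2^-ddCt`.
#'
#' @param ct_target_trt,ct_ref_trt Ct values of target and reference gene in
#'   the treated/test sample.
#' @param ct_target_ctl,ct_ref_ctl Ct values in the control/calibrator
#'   sample.
#' @return relative expression (1 means no change; vectorized).
#' @export
ddct_relative_expression <- function(ct_target_trt, ct_ref_trt,
                                     ct_target_ctl, ct_ref_ctl) {
  ddct <- (ct_target_trt - ct_ref_trt) - (ct_target_ctl - ct_ref_ctl)
  abort_if(any(!is.finite(ddct)), "Ct values must be finite")
  2^(-ddct)
}
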