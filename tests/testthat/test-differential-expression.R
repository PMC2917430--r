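make_two_group <- function(n_genes = 50, n_per_group = 3, seed = 1) {
  withr::with_seed(seed, {
    m <- toy_matrix(matrix(2^rnorm(n_genes * 2 * n_per_group, 8, 1),
                           n_genes, 2 * n_per_group))
    classes <- rep(c("a", "b"), each = n_per_group)
    list(matrix = m, classes = classes)
  })
}

test_that("identical groups give zero effect and p = 1", {
  vals <- matrix(2^c(1, 2, 3, 1, 2, 3), 4, 6, byrow = TRUE)
  m <- toy_matrix(vals)
  de <- fit_moderated_t(m, rep(c("a", "b"), each = 3),
                        prior = moderated_prior(d0 = 4, s0_sq = 0.1))
  expect_equal(de$log2fc, rep(0, 4))
  expect_equal(de$t_mod, rep(0, 4))
  expect_equal(de$p_raw, rep(1, 4))
})

test_that("d0 = 0 reproduces the ordinary pooled-variance t-test", {
  tg <- make_two_group(n_genes = 50, seed = 2)
  de <- fit_moderated_t(tg$matrix, tg$classes,
                        prior = moderated_prior(d0 = 0, s0_sq = 1))
  lm <- log2(tg$matrix)
  for (i in seq_len(nrow(lm))) {
    expect_equal(de$t_mod[i],
                 oracle_pooled_t(lm[i, 1:3], lm[i, 4:6]),
                 tolerance = 1e-10)
  }
  # and the t-distribution p-values on d df match t.test
  pt_ref <- apply(lm, 1, function(v)
    t.test(v[1:3], v[4:6], var.equal = TRUE)$p.value)
  expect_equal(de$p_raw, pt_ref, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("a fixed prior reproduces the hand-worked moderated t", {
  # log2 values (1,1,1) vs (2,2,2): s2 = 0, d = 4, d0 = 4, s0_sq = 0.1
  # -> s2_tilde = 0.4/8 = 0.05, t = -1 / sqrt(0.05 * 2/3) ~ -5.477, df 8
  m <- toy_matrix(matrix(2^c(rep(1, 3), rep(2, 3)), 2, 6, byrow = TRUE))
  de <- fit_moderated_t(m, rep(c("g1", "g2"), each = 3),
                        prior = moderated_prior(d0 = 4, s0_sq = 0.1),
                        reference_class = "g1")
  expect_equal(de$t_mod[1], -1 / sqrt(0.05 * (2 / 3)), tolerance = 1e-12)
  expect_equal(de$t_mod[1], -5.477226, tolerance = 1e-6)
  expect_equal(de$p_raw[1], 2 * pt(-5.477226, df = 8), tolerance = 1e-6)
})

test_that("moderated t agrees with limma's empirical-Bayes pipeline", {
  skip_if_not_installed("limma")
  tg <- make_two_group(n_genes = 200, seed = 3)
  lm2 <- log2(tg$matrix)
  design <- cbind(1, tg$classes == "a")
  fit <- limma::lmFit(lm2, design)
  efit <- limma::eBayes(fit)
  # feed limma's own prior through our formula: t statistics must agree
  de <- fit_moderated_t(tg$matrix, tg$classes, reference_class = "a",
                        prior = moderated_prior(d0 = efit$df.prior,
                                                s0_sq = efit$s2.prior))
  expect_equal(de$t_mod, unname(efit$t[, 2]), tolerance = 1e-8)
  # limma caps its total df at the summed residual df, so p-values can
  # differ in far decimals when the prior df estimate is huge
  expect_equal(de$p_raw, unname(efit$p.value[, 2]), tolerance = 1e-3)
})

test_that("prior estimation recovers known hyperparameters", {
  d0_true <- 4; s0_true <- 0.05; d <- 4
  est <- sapply(1:20, function(seed) {
    withr::with_seed(seed, {
      sigma2 <- d0_true * s0_true / rchisq(5000, d0_true)
      s2 <- sigma2 * rchisq(5000, d) / d
      p <- estimate_prior(s2, d)
      c(p$d0, p$s0_sq)
    })
  })
  expect_gte(median(est[1, ]), 2.5)
  expect_lte(median(est[1, ]), 6.5)
  expect_lt(abs(median(est[2, ]) - s0_true) / s0_true, 0.25)
})

test_that("prior estimation agrees with limma's fitFDist moment matching", {
  skip_if_not_installed("limma")
  withr::with_seed(7, {
    s2 <- 0.05 * 4 / rchisq(2000, 4) * rchisq(2000, 6) / 6
  })
  ours <- estimate_prior(s2, d = 6)
  ref <- limma::fitFDist(s2, df1 = 6)
  expect_equal(ours$d0, ref$df2, tolerance = 1e-6)
  expect_equal(ours$s0_sq, ref$scale, tolerance = 1e-6)
})

test_that("degenerate variance inputs are handled as specified", {
  expect_error(estimate_prior(rep(0, 100), d = 4), "zero")
  expect_error(estimate_prior(c(rep(0, 95), runif(5)), d = 4), "at least 10")
  p <- estimate_prior(rep(0.3, 100), d = 4)
  expect_true(p$d0_capped)
  expect_equal(p$d0, 40)
  expect_equal(p$s0_sq, 0.3, tolerance = 1e-12)
})

test_that("shrinkage strengthens with d0 and converges to the prior scale", {
  tg <- make_two_group(n_genes = 30, seed = 5)
  s0 <- 0.5
  t_inf <- {
    lm2 <- log2(tg$matrix)
    delta <- rowMeans(lm2[, 1:3]) - rowMeans(lm2[, 4:6])
    delta / (sqrt(s0) * sqrt(2 / 3))
  }
  de_big <- fit_moderated_t(tg$matrix, tg$classes,
                            prior = moderated_prior(d0 = 1e8, s0_sq = s0))
  expect_equal(de_big$t_mod, unname(t_inf), tolerance = 1e-4)
})

test_that("insufficient replication and bad intensities are rejected", {
  m <- toy_matrix(matrix(2^rnorm(30), 10, 3))
  expect_error(fit_moderated_t(m, c("a", "a", "b")),
               "insufficient replication")
  m2 <- toy_matrix(matrix(c(-1, 1, 1, 1, 1, 1, 1, 1), 2, 4))
  expect_error(fit_moderated_t(m2, c("a", "a", "b", "b")), "> 0")
})

test_that("BH adjustment matches hand-worked cases and a brute-force oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.005, 0.5)), c(0.01, 0.5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  base_p <- c(0.001, 0.02, 0.04, 0.2, 0.5, 0.9)
  perms <- rbind(seq_along(base_p),
                 rev(seq_along(base_p)),
                 c(3, 1, 6, 2, 5, 4), c(2, 6, 1, 5, 3, 4))
  for (r in seq_len(nrow(perms))) {
    p <- base_p[perms[r, ]]
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p))
    # monotone: adjusted order preserves raw order
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
    expect_true(all(adj >= p))
  }
})

test_that("signed fold change follows the array-era convention", {
  expect_equal(signed_fold_change(4, 1), 4)
  expect_equal(signed_fold_change(1, 4), -4)
  expect_equal(signed_fold_change(3, 2), 1.5)
  expect_equal(signed_fold_change(5, 5), 1)
  expect_error(signed_fold_change(0, 1), "> 0")
  # antisymmetry across random positive pairs
  withr::with_seed(1, {
    a <- runif(100, 0.1, 50); b <- runif(100, 0.1, 50)
  })
  expect_equal(signed_fold_change(a, b), -signed_fold_change(b, a))
})

test_that("signature selection applies both thresholds and excludes the reference", {
  de <- tibble::tibble(
    gene_id = paste0("gene", 1:5),
    signed_fc = c(4, -4, 1.5, 4, 2.1),
    p_adj = c(0.01, 0.01, 0.01, 0.2, 0.04)
  )
  sig <- select_coexpressed_signature(de)
  expect_setequal(sig$gene_ids, c("gene1", "gene5"))

  expect_warning(
    empty <- select_coexpressed_signature(
      dplyr::mutate(de, p_adj = 1)), "no genes")
  expect_length(empty$gene_ids, 0)

  all_up <- select_coexpressed_signature(de, p_adj_max = 1 + 1e-9,
                                         fold_min = 1)
  expect_setequal(all_up$gene_ids,
                  de$gene_id[de$signed_fc >= 1])

  no_ref <- select_coexpressed_signature(de, reference_gene = "gene1")
  expect_setequal(no_ref$gene_ids, "gene5")
})

test_that("planted differential genes are recovered at controlled FDR", {
  hits <- sapply(1:10, function(seed) {
    sim <- simulate_two_group_experiment(
      two_group_sim_config(n_genes = 2000, n_de_up = 100, n_de_down = 0,
                           fixed_fold = 4, noise_log2_sd = 0.35,
                           seed = seed))
    de <- fit_moderated_t(sim$matrix, sim$classes)
    sig <- select_coexpressed_signature(de)
    up <- sim$truth$de_genes$gene_id
    c(recovery = mean(up %in% sig$gene_ids),
      fdr = mean(!(sig$gene_ids %in% up)))
  })
  expect_gte(median(hits["recovery", ]), 0.9)
  expect_lte(median(hits["fdr", ]), 0.1)
})

test_that("ddCt relative expression follows 2^-ddCt", {
  expect_equal(ddct_relative_expression(20, 20, 20, 20), 1)
  expect_equal(ddct_relative_expression(25, 20, 24, 20), 0.5)
  expect_equal(ddct_relative_expression(24, 20, 25, 20), 2)
  expect_error(ddct_relative_expression(NA, 20, 24, 20), "finite")
})

test_that("glance on a fitted DE table reports the prior and group sizes", {
  tg <- make_two_group(n_genes = 100, seed = 6)
  de <- fit_moderated_t(tg$matrix, tg$classes)
  g <- glance(de)
  expect_identical(g$n_genes, 100L)
  expect_identical(c(g$n_ref, g$n_other), c(3L, 3L))
  expect_equal(g$df_total, g$d0 + g$d)
})
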