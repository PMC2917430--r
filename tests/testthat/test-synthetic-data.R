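test_that("two-group simulation honours configured dimensions and truth counts", {
  cfg <- two_group_sim_config(n_genes = 100, n_per_group = 3,
                              n_de_up = 10, n_de_down = 10, seed = 1)
  sim <- simulate_two_group_experiment(cfg)
  expect_identical(dim(sim$matrix), c(100L, 6L))
  expect_identical(nrow(sim$truth$de_genes), 20L)
  expect_identical(sum(sim$truth$de_genes$direction == "up"), 10L)
  expect_true(all(sim$truth$de_genes$gene_id %in% rownames(sim$matrix)))
  expect_true(all(is.finite(sim$matrix)) && all(sim$matrix > 0))
  expect_identical(sim$classes$sample_id, colnames(sim$matrix))
  expect_identical(length(unique(sim$classes$label)), 2L)
})

test_that("identical seeds reproduce the simulation exactly; different seeds differ", {
  cfg1 <- two_group_sim_config(n_genes = 50, seed = 1,
                               n_de_up = 5, n_de_down = 5)
  cfg2 <- two_group_sim_config(n_genes = 50, seed = 2,
                               n_de_up = 5, n_de_down = 5)
  a <- simulate_two_group_experiment(cfg1)
  b <- simulate_two_group_experiment(cfg1)
  c <- simulate_two_group_experiment(cfg2)
  expect_identical(a, b)
  expect_false(identical(a$matrix, c$matrix))

  ccfg <- compendium_sim_config(n_genes = 200, n_samples = 30, seed = 9)
  expect_identical(simulate_tumor_compendium(ccfg),
                   simulate_tumor_compendium(ccfg))
})

test_that("invalid simulation configs are rejected", {
  expect_error(two_group_sim_config(n_genes = 10, n_de_up = 8, n_de_down = 5,
                                    seed = 1), "exceed")
  expect_error(two_group_sim_config(noise_log2_sd = 0, seed = 1), "> 0")
  expect_error(two_group_sim_config(fold_range = c(0.5, 2), seed = 1),
               "fold_range")
  expect_error(two_group_sim_config(n_genes = 100), "seed")
  expect_error(compendium_sim_config(rho = 1.2, seed = 1), "rho")
  expect_error(compendium_sim_config(n_genes = 10, module_size = 20, seed = 1),
               "exceed")
})

test_that("with no planted genes, per-gene t-test p-values are uniform", {
  sim <- simulate_two_group_experiment(
    two_group_sim_config(n_genes = 2000, n_de_up = 0, n_de_down = 0,
                         seed = 11))
  lab <- sim$classes$label
  lm <- log2(sim$matrix)
  ps <- apply(lm, 1, function(v) {
    t.test(v[lab == lab[1]], v[lab != lab[1]], var.equal = TRUE)$p.value
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("planted fold changes match construction means within the noise model", {
  sim <- simulate_two_group_experiment(
    two_group_sim_config(n_genes = 500, n_de_up = 50, n_de_down = 50,
                         n_per_group = 50, noise_log2_sd = 0.2, seed = 4))
  lab <- sim$classes$label
  up <- sim$truth$de_genes[sim$truth$de_genes$direction == "up", ]
  realized <- rowMeans(log2(sim$matrix[up$gene_id, lab == lab[1]])) -
    rowMeans(log2(sim$matrix[up$gene_id, lab != lab[1]]))
  expect_equal(realized, log2(up$fold), tolerance = 0.1,
               ignore_attr = TRUE)
})

test_that("embedded module hits the target correlation", {
  ref <- 2^rnorm(190, 10, 1)
  exact <- embed_correlated_module(ref, rho = 1, n_genes = 5, noise_seed = 1)
  for (i in 1:5) {
    expect_equal(cor(exact[i, ], ref), 1, tolerance = 1e-12)
  }
  indep <- embed_correlated_module(ref, rho = 0, n_genes = 500, noise_seed = 2)
  r0 <- as.numeric(cor(ref, t(indep)))
  # unbiased around zero; |r| itself has sampling sd ~ 1/sqrt(189)
  expect_lt(abs(mean(r0)), 0.02)
  expect_lt(mean(abs(r0)), 3 / sqrt(189))
  mid <- embed_correlated_module(ref, rho = 0.6, n_genes = 200, noise_seed = 3)
  expect_equal(mean(as.numeric(cor(ref, t(mid)))), 0.6, tolerance = 0.05)
  expect_true(all(indep > 0) && all(mid > 0))
})

test_that("module embedding rejects degenerate inputs", {
  expect_error(embed_correlated_module(rep(5, 10), 0.5, 3, 1), "constant")
  expect_error(embed_correlated_module(c(1, 2), 0.5, 3, 1), "at least 3")
  expect_error(embed_correlated_module(1:10, 1.5, 3, 1), "rho")
})

test_that("compendium truth counts match config and ids resolve to rows", {
  comp <- simulate_tumor_compendium(
    compendium_sim_config(n_genes = 2000, module_size = 20, rho = 0.7,
                          seed = 7))
  expect_identical(length(comp$truth$module_genes), 20L)
  expect_identical(nrow(comp$truth$violator_genes), 30L)
  all_ids <- c(comp$truth$module_genes, comp$truth$violator_genes$gene_id,
               comp$truth$reference_gene)
  expect_true(all(all_ids %in% rownames(comp$matrix)))
  expect_identical(dim(comp$matrix), c(2000L, 190L))
  expect_identical(length(unique(comp$classes$label)), 14L)
  expect_true(all(is.finite(comp$matrix)) && all(comp$matrix > 0))
})

test_that("planted violators fail the compendium filter and background survives", {
  comp <- simulate_tumor_compendium(
    compendium_sim_config(n_genes = 2000, module_size = 20, rho = 0.7,
                          seed = 7))
  cf <- compendium_filter(comp$matrix)
  expect_true(all(comp$truth$violator_genes$gene_id %in%
                    cf$report$removed$gene_id))
  bg <- setdiff(rownames(comp$matrix),
                c(comp$truth$module_genes, comp$truth$reference_gene,
                  comp$truth$violator_genes$gene_id))
  expect_gte(mean(bg %in% rownames(cf$matrix)), 0.95)
  # removal reasons line up with the planted rule classes
  removed <- cf$report$removed
  low_rules <- removed$rule[match(
    comp$truth$violator_genes$gene_id[comp$truth$violator_genes$rule == "low"],
    removed$gene_id)]
  expect_true(all(low_rules == "mostly_low"))
})

test_that("a strongly correlated planted module ranks nearest the reference", {
  for (seed in 1:10) {
    comp <- simulate_tumor_compendium(
      compendium_sim_config(n_genes = 2000, module_size = 20, rho = 0.9,
                            seed = seed))
    cf <- compendium_filter(comp$matrix)
    rk <- rank_neighbors(cf$matrix, comp$truth$reference_gene)
    expect_true(all(comp$truth$module_genes %in% head(rk$gene_id, 40)),
                label = sprintf("module in top 40 (seed %d)", seed))
  }
})

test_that("truth records round-trip through the TSV writer", {
  comp <- simulate_tumor_compendium(
    compendium_sim_config(n_genes = 100, n_samples = 20, module_size = 5,
                          n_low_violators = 2, n_high_violators = 2,
                          n_flat_violators = 2, seed = 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_planted_truth(comp$truth, path)
  tab <- read.delim(path)
  expect_identical(sum(tab$role == "module"), 5L)
  expect_identical(sum(tab$role == "violator"), 6L)
  expect_identical(sum(tab$role == "reference"), 1L)
})
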