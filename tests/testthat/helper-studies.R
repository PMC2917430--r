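# Builds a linked study: a tumor compendium with a planted coexpression
# module around the reference gene, and a cell-line experiment in the same
# gene universe where those module genes (plus the reference) are planted up
# in the reference condition.
make_linked_study <- function(seed, n_genes = 2000, module_size = 20,
                              rho = 0.8, fold = 4) {
  comp <- simulate_tumor_compendium(
    compendium_sim_config(n_genes = n_genes, module_size = module_size,
                          rho = rho, seed = seed))
  ids <- rownames(comp$matrix)
  cell <- simulate_two_group_experiment(
    two_group_sim_config(
      n_genes = n_genes, gene_ids = ids,
      de_up_ids = c(comp$truth$module_genes, comp$truth$reference_gene),
      n_de_down = 50, fixed_fold = fold, seed = seed + 10000))
  list(comp = comp, cell = cell)
}

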