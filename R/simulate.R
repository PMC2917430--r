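#' Configuration for the two-condition cell-line simulation
#'
#' Describes a two-group microarray-style experiment (a control line versus a
#' knockdown line, a few replicate arrays each) with a chosen number of genes
#' planted as differentially expressed. Background genes get a gene-level
#' log2 baseline mean; differential genes have the group-1 (reference
#' condition) mean shifted by `log2(fold)` up or down; replicate noise is
#' Gaussian on the log2 scale and intensities are exponentiated back to the
#' positive scale.
#'
#' @param n_genes number of genes.
#' @param n_per_group replicate arrays per condition (default 3, triplicates).
#' @param n_de_up,n_de_down genes planted higher in group 1 / group 2.
#'   Ignored when `de_up_ids` / `de_down_ids` are supplied.
#' @param fold_range multiplicative effect bounds; planted folds are drawn
#'   log-uniformly in this interval. Lower bound must be >= 1.
#' @param baseline_log2_mean,baseline_log2_sd background gene-level intensity
#'   distribution on the log2 scale.
#' @param noise_log2_sd replicate noise standard deviation (log2 scale).
#' @param seed integer seed; required, never implicit.
#' @param group_labels two condition labels; the first is the reference
#'   (HO-1-expressing-like) condition.
#' @param gene_ids optional explicit gene identifiers (length `n_genes`);
#'   lets the cell-line experiment share a gene universe with a simulated
#'   compendium.
#' @param de_up_ids,de_down_ids optional explicit ids of the planted genes
#'   (must be among `gene_ids`).
#' @param fixed_fold optional single fold applied to every planted gene
#'   instead of drawing from `fold_range`.
#'
#' @return a validated config object (class `two_group_sim_config`).
#' @export
two_group_sim_config <- function(n_genes = 2000, n_per_group = 3,
                                 n_de_up = 100, n_de_down = 100,
                                 fold_range = c(2, 8),
                                 baseline_log2_mean = 8,
                                 baseline_log2_sd = 1.5,
                                 noise_log2_sd = 0.35,
                                 seed,
                                 group_labels = c("LMP", "miHO1"),
                                 gene_ids = NULL,
                                 de_up_ids = NULL, de_down_ids = NULL,
                                 fixed_fold = NULL) {
  abort_if(missing(seed), "`seed` is required")
  if (!is.null(gene_ids)) {
    abort_if(length(gene_ids) != n_genes || anyDuplicated(gene_ids) > 0,
             "`gene_ids` must be `n_genes` unique identifiers")
  }
  if (!is.null(de_up_ids)) n_de_up <- length(de_up_ids)
  if (!is.null(de_down_ids)) n_de_down <- length(de_down_ids)
  abort_if(n_genes < 1 || n_per_group < 1,
           "invalid config: counts must be positive")
  abort_if(n_de_up < 0 || n_de_down < 0 || n_de_up + n_de_down > n_genes,
           "invalid config: n_de_up + n_de_down must not exceed n_genes")
  abort_if(baseline_log2_sd <= 0 || noise_log2_sd <= 0,
           "invalid config: standard deviations must be > 0")
  abort_if(length(fold_range) != 2 || fold_range[1] < 1 ||
             fold_range[2] < fold_range[1],
           "invalid config: fold_range must be an increasing pair with low >= 1")
  abort_if(!is.null(fixed_fold) && fixed_fold < 1,
           "invalid config: fixed_fold must be >= 1")
  abort_if(length(group_labels) != 2 || anyDuplicated(group_labels) > 0,
           "invalid config: group_labels must be two distinct labels")
  structure(
    list(n_genes = n_genes, n_per_group = n_per_group,
         n_de_up = n_de_up, n_de_down = n_de_down, fold_range = fold_range,
         baseline_log2_mean = baseline_log2_mean,
         baseline_log2_sd = baseline_log2_sd,
         noise_log2_sd = noise_log2_sd, seed = as.integer(seed),
         group_labels = group_labels, gene_ids = gene_ids,
         de_up_ids = de_up_ids, de_down_ids = de_down_ids,
         fixed_fold = fixed_fold),
    class = "two_group_sim_config"
  )
}

new_planted_truth <- function(de_genes = NULL, module_genes = character(),
                              reference_gene = NA_character_,
                              violator_genes = NULL) {
  if (is.null(de_genes)) {
    de_genes <- tibble::tibble(gene_id = character(),
                               direction = character(), fold = double())
  }
  if (is.null(violator_genes)) {
    violator_genes <- tibble::tibble(gene_id = character(), rule = character())
  }
  structure(
    list(de_genes = de_genes, module_genes = module_genes,
         reference_gene = reference_gene, violator_genes = violator_genes),
    class = "planted_truth"
  )
}

#' Simulate a two-condition expression experiment with planted fold changes
#'
#' @param config a [two_group_sim_config()].
#' @return a list with `matrix` (genes x samples intensities), `classes`
#'   (tibble `sample_id`, `label`) and `truth` (a `planted_truth` record of
#'   the planted genes, their direction and fold).
#' @examples
#' sim <- simulate_two_group_experiment(
#'   two_group_sim_config(n_genes = 50, n_de_up = 5, n_de_down = 5, seed = 1))
#' dim(sim$matrix)
#' @export
simulate_two_group_experiment <- function(config) {
  abort_if(!inherits(config, "two_group_sim_config"),
           "`config` must come from two_group_sim_config()")
  with_rng(config$seed, {
    n <- config$n_genes
    ids <- config$gene_ids %||% sprintf("G%05d", seq_len(n))
    up_ids <- config$de_up_ids %||%
      sample(ids, config$n_de_up)
    down_ids <- config$de_down_ids %||%
      sample(setdiff(ids, up_ids), config$n_de_down)
    abort_if(length(intersect(up_ids, down_ids)) > 0,
             "a gene cannot be planted both up and down")
    abort_if(!all(c(up_ids, down_ids) %in% ids),
             "planted ids must be among gene_ids")

    n_de <- length(up_ids) + length(down_ids)
    folds <- if (!is.null(config$fixed_fold)) {
      rep(config$fixed_fold, n_de)
    } else {
      2^runif(n_de, log2(config$fold_range[1]), log2(config$fold_range[2]))
    }

    mu <- rnorm(n, config$baseline_log2_mean, config$baseline_log2_sd)
    names(mu) <- ids
    n_rep <- config$n_per_group
    # group-1 shift: +log2(fold) for up-planted, -log2(fold) for down-planted
    shift <- stats::setNames(rep(0, n), ids)
    de_ids <- c(up_ids, down_ids)
    shift[de_ids] <- log2(folds) *
      rep(c(1, -1), c(length(up_ids), length(down_ids)))

    log2m <- cbind(
      matrix(mu + shift, n, n_rep),
      matrix(mu, n, n_rep)
    ) + matrix(rnorm(n * 2 * n_rep, 0, config$noise_log2_sd), n, 2 * n_rep)
    m <- 2^log2m
    rownames(m) <- ids
    colnames(m) <- paste0(rep(config$group_labels, each = n_rep),
                          "_", rep(seq_len(n_rep), 2))

    classes <- tibble::tibble(
      sample_id = colnames(m),
      label = rep(config$group_labels, each = n_rep)
    )
    truth <- new_planted_truth(
      de_genes = tibble::tibble(
        gene_id = de_ids,
        direction = rep(c("up", "down"), c(length(up_ids), length(down_ids))),
        fold = folds
      )
    )
    list(matrix = m, classes = classes, truth = truth)
  })
}

#' Build gene profiles with a target Pearson correlation to a reference
#'
#' Each output row is constructed on the standardized scale as
#' `rho * z_ref + sqrt(1 - rho^2) * eps` with independent standard normal
#' noise, then affinely mapped (positive slope) into a positive intensity
#' range, so the expected Pearson correlation with the reference equals
#' `rho` and the in-sample correlation is unchanged by the mapping.
#'
#' @param reference_profile intensity vector (length >= 3, non-constant).
#' @param rho target Pearson correlation in \[0, 1\].
#' @param n_genes number of module gene profiles to generate.
#' @param noise_seed integer seed for the noise draws.
#' @param target_mean,intensity_floor anchors of the affine map: rows are
#'   centred at `target_mean` and scaled so no value drops below
#'   `intensity_floor`.
#' @return an `n_genes` x `length(reference_profile)` matrix.
#' @export
embed_correlated_module <- function(reference_profile, rho, n_genes,
                                    noise_seed,
                                    target_mean = 1000,
                                    intensity_floor = 50) {
  abort_if(!is.numeric(rho) || length(rho) != 1 || rho < 0 || rho > 1,
           "invalid config: `rho` must lie in [0, 1]")
  abort_if(length(reference_profile) < 3,
           "`reference_profile` needs at least 3 entries")
  abort_if(sd(reference_profile) == 0,
           "degenerate input: constant reference profile")
  abort_if(n_genes < 1, "`n_genes` must be positive")
  z <- as.numeric(scale(reference_profile))
  ns <- length(z)
  with_rng(noise_seed, {
    eps <- matrix(rnorm(n_genes * ns), n_genes, ns)
    g <- rho * matrix(z, n_genes, ns, byrow = TRUE) + sqrt(1 - rho^2) * eps
    t(apply(g, 1, function(row) {
      amp <- max(abs(row))
      a <- if (amp > 0) (target_mean - intensity_floor) / amp else 1
      target_mean + a * row
    }))
  })
}

#' Configuration for the simulated multi-tumor expression compendium
#'
#' Emulates the shape of a pan-cancer compendium (by default 190 specimens of
#' 14 tumor types): one designated reference gene, a module of genes built to
#' correlate with it at a target Pearson `rho`, background genes independent
#' of the reference, and genes deliberately constructed to fail each of the
#' compendium filter rules (mostly-low, mostly-high, flat).
#'
#' @param n_genes total gene count.
#' @param n_samples number of tumor specimens (default 190).
#' @param n_types number of tumor-type labels (default 14); labels are
#'   decorative for the ranking pipeline.
#' @param module_size genes in the planted coexpression module.
#' @param rho target Pearson correlation of module genes to the reference.
#' @param n_low_violators,n_high_violators,n_flat_violators counts of genes
#'   built to fail the low-intensity, high-intensity and flatness rules.
#' @param intensity_floor,intensity_ceiling scale anchors (defaults 50 and
#'   15000, matching the filter bounds); intensities saturate at the ceiling.
#' @param type_effect_sd optional per-type mean shift (log2 scale) to stress
#'   the ranking; 0 disables it.
#' @param reference_gene identifier given to the reference gene.
#' @param seed integer seed; required.
#' @return a validated config object (class `compendium_sim_config`).
#' @export
compendium_sim_config <- function(n_genes = 2000, n_samples = 190,
                                  n_types = 14, module_size = 20, rho = 0.8,
                                  n_low_violators = 10, n_high_violators = 10,
                                  n_flat_violators = 10,
                                  intensity_floor = 50,
                                  intensity_ceiling = 15000,
                                  type_effect_sd = 0,
                                  reference_gene = "HMOX1",
                                  seed) {
  abort_if(missing(seed), "`seed` is required")
  n_viol <- n_low_violators + n_high_violators + n_flat_violators
  abort_if(n_genes < 1 || n_samples < 3 || n_types < 1 || module_size < 0,
           "invalid config: counts must be positive")
  abort_if(module_size + n_viol + 1 > n_genes,
           "invalid config: module_size + violators (+ reference) exceed n_genes")
  abort_if(rho < 0 || rho > 1, "invalid config: `rho` must lie in [0, 1]")
  abort_if(intensity_floor <= 0 || intensity_ceiling <= intensity_floor,
           "invalid config: intensity anchors must satisfy 0 < floor < ceiling")
  structure(
    list(n_genes = n_genes, n_samples = n_samples, n_types = n_types,
         module_size = module_size, rho = rho,
         n_low_violators = n_low_violators,
         n_high_violators = n_high_violators,
         n_flat_violators = n_flat_violators,
         intensity_floor = intensity_floor,
         intensity_ceiling = intensity_ceiling,
         type_effect_sd = type_effect_sd,
         reference_gene = reference_gene, seed = as.integer(seed)),
    class = "compendium_sim_config"
  )
}

#' Simulate a multi-tumor expression compendium with a planted module
#'
#' @param config a [compendium_sim_config()].
#' @return a list with `matrix` (genes x specimens), `classes` (tibble of
#'   tumor-type labels) and `truth` (module gene ids, reference gene id and
#'   the filter-violating genes with the rule each one breaks).
#' @export
simulate_tumor_compendium <- function(config) {
  abort_if(!inherits(config, "compendium_sim_config"),
           "`config` must come from compendium_sim_config()")
  with_rng(config$seed, {
    ns <- config$n_samples
    floor_ <- config$intensity_floor
    ceil_ <- config$intensity_ceiling

    type_labels <- sprintf("type%02d", rep_len(seq_len(config$n_types), ns))
    type_shift <- if (config$type_effect_sd > 0) {
      rnorm(config$n_types, 0, config$type_effect_sd)[
        rep_len(seq_len(config$n_types), ns)]
    } else {
      rep(0, ns)
    }

    ref <- 2^(rnorm(ns, 10, 1.2) + type_shift)

    module <- if (config$module_size > 0) {
      embed_correlated_module(
        ref, config$rho, config$module_size,
        noise_seed = sample.int(.Machine$integer.max, 1),
        target_mean = 1000, intensity_floor = floor_
      )
    } else {
      matrix(numeric(), 0, ns)
    }

    n_bg <- config$n_genes - 1 - config$module_size -
      config$n_low_violators - config$n_high_violators -
      config$n_flat_violators
    bg_mu <- runif(n_bg, 8, 11.5)
    bg <- 2^(matrix(bg_mu, n_bg, ns) +
               matrix(rnorm(n_bg * ns, 0, 0.8), n_bg, ns) +
               matrix(type_shift, n_bg, ns, byrow = TRUE))

    low <- matrix(runif(config$n_low_violators * ns, floor_ / 10, floor_ * 0.9),
                  config$n_low_violators, ns)
    high <- matrix(runif(config$n_high_violators * ns, ceil_ * 1.01, ceil_ * 1.2),
                   config$n_high_violators, ns)
    flat_base <- runif(config$n_flat_violators, 200, 1000)
    flat <- flat_base * matrix(runif(config$n_flat_violators * ns, 0.95, 1.05),
                               config$n_flat_violators, ns)

    ids_mod <- if (config$module_size > 0)
      sprintf("MOD%03d", seq_len(config$module_size)) else character()
    ids_low <- if (config$n_low_violators > 0)
      sprintf("LOW%03d", seq_len(config$n_low_violators)) else character()
    ids_high <- if (config$n_high_violators > 0)
      sprintf("HIGH%03d", seq_len(config$n_high_violators)) else character()
    ids_flat <- if (config$n_flat_violators > 0)
      sprintf("FLAT%03d", seq_len(config$n_flat_violators)) else character()
    ids_bg <- sprintf("G%05d", seq_len(n_bg))

    m <- rbind(matrix(ref, 1, ns), module, low, high, flat, bg)
    rownames(m) <- c(config$reference_gene, ids_mod, ids_low, ids_high,
                     ids_flat, ids_bg)
    # saturate at the ceiling, except for the deliberately-high violators
    sat <- setdiff(rownames(m), ids_high)
    m[sat, ] <- pmin(m[sat, ], ceil_)
    # shuffle row order so planted structure is not positional
    m <- m[sample.int(nrow(m)), , drop = FALSE]
    colnames(m) <- sprintf("T%03d", seq_len(ns))

    classes <- tibble::tibble(sample_id = colnames(m), label = type_labels)
    truth <- new_planted_truth(
      module_genes = ids_mod,
      reference_gene = config$reference_gene,
      violator_genes = tibble::tibble(
        gene_id = c(ids_low, ids_high, ids_flat),
        rule = rep(c("low", "high", "flat"),
                   c(length(ids_low), length(ids_high), length(ids_flat)))
      )
    )
    list(matrix = m, classes = classes, truth = truth)
  })
}

#' Write a planted-truth record as TSV (`gene_id  role  param`)
#'
#' @param truth a `planted_truth` record.
#' @param path output file path.
#' @export
write_planted_truth <- function(truth, path) {
  abort_if(!inherits(truth, "planted_truth"), "`truth` must be a planted_truth")
  tab <- as_truth_table(truth)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

as_truth_table <- function(truth) {
  rows <- list(
    tibble::tibble(gene_id = truth$de_genes$gene_id,
                   role = paste0("de_", truth$de_genes$direction),
                   param = format(truth$de_genes$fold)),
    tibble::tibble(gene_id = truth$module_genes,
                   role = "module", param = ""),
    if (!is.na(truth$reference_gene))
      tibble::tibble(gene_id = truth$reference_gene,
                     role = "reference", param = ""),
    tibble::tibble(gene_id = truth$violator_genes$gene_id,
                   role = "violator", param = truth$violator_genes$rule)
  )
  dplyr::bind_rows(rows)
}

#' @export
print.planted_truth <- function(x, ...) {
  cat("<planted_truth>\n")
  cat("  DE genes:      ", nrow(x$de_genes), "\n")
  cat("  module genes:  ", length(x$module_genes), "\n")
  cat("  reference gene:", x$reference_gene, "\n")
  cat("  violators:     ", nrow(x$violator_genes), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
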