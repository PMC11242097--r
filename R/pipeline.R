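#' Default synthetic study configuration
#'
#' The fixture emulates a staged-lymphoma transcriptomic study: four stages
#' (normal, insitu, intermediate, aggressive) with small per-group sample
#' counts, a block of genes progressively up- or down-regulated from the
#' intermediate stage on, two planted co-expression modules (one shared
#' between intermediate and aggressive, one aggressive-specific), two
#' batches with additive offsets, a scale-free interactome over the same
#' gene universe and a drug catalog with typed actions.
#'
#' @param n_genes gene count (default 120).
#' @return A [simulation_config()].
#' @export
default_study_config <- function(n_genes = 120) {
  simulation_config(
    n_genes = n_genes,
    groups = c(normal = 6, insitu = 6, intermediate = 8, aggressive = 8),
    de_spec = list(
      list(genes = 1:10, group = "insitu", effect = 2),
      list(genes = 1:18, group = "intermediate", effect = 2),
      list(genes = c(1:18, 25:34), group = "aggressive", effect = 2),
      list(genes = 41:48, group = "aggressive", effect = -2)),
    module_spec = list(
      list(genes = 61:80, groups = c("intermediate", "aggressive"), loading = 1),
      list(genes = 81:100, groups = "aggressive", loading = 1)),
    batch_spec = c(b1 = 0, b2 = 0.6),
    noise_sd = 0.5)
}

#' Run the full synthetic analysis pipeline
#'
#' Chains every stage on generated data: simulate expression, interactome
#' and drug catalog; quantile-normalize and batch-center; differential
#' expression for the stepwise stage contrasts; per-condition
#' mutual-information co-expression networks with MRNETB and hard
#' thresholding; cross-condition module alignment; over-representation
#' analysis of the top DEGs against gene sets built from the planted
#' modules; drug repurposing; and network-proximity screening of drug
#' combinations. Deterministic in `seed`.
#'
#' @param seed integer seed driving every random stage.
#' @param cfg a [simulation_config()] (default [default_study_config()]).
#' @param coexpr_groups the two conditions to compare as co-expression
#'   networks.
#' @param q hard-threshold quantile (default 0.95).
#' @param beta joint-graph coupling (default 1).
#' @param top_n disease-module size: top-N DEGs (default 100).
#' @param n_perm permutations per proximity z-score (default 200 for the
#'   desk-scale fixture).
#' @param n_drugs drugs in the synthetic catalog (default 30).
#' @param out_dir optional directory for TSV/JSON outputs.
#' @return List with every stage's objects (dataset, truth, de, networks,
#'   alignment, enrichment, repurposing, screening) plus a `summary` list of
#'   headline numbers.
#' @export
run_pipeline <- function(seed = 1, cfg = default_study_config(),
                         coexpr_groups = c("intermediate", "aggressive"),
                         q = 0.95, beta = 1, top_n = 100, n_perm = 200,
                         n_drugs = 30, out_dir = NULL) {
  sim <- simulate_expression(cfg, seed = seed)
  ds <- batch_center(quantile_normalize(sim$dataset))
  groups <- names(cfg$groups)
  contrasts <- list()
  for (i in seq_len(length(groups) - 1)) {
    de <- moderated_t_test(ds, groups[i], groups[i + 1])
    contrasts[[de$contrast]] <- de
  }
  deg_tables <- lapply(contrasts, top_degs, n = top_n)
  # co-expression networks for the two focal conditions
  cond <- lapply(coexpr_groups, function(g)
    subset_samples(ds, group_samples(ds, g)))
  mis <- lapply(cond, mi_matrix)
  nets <- lapply(mis, function(mi) hard_threshold(mrnetb(mi), q = q))
  alignment <- align_modules(nets[[1]], nets[[2]], mis[[1]], mis[[2]],
                             beta = beta, seed = derive_seed(seed, 11))
  # gene sets from the planted modules plus random background sets
  sets <- list()
  for (i in seq_along(sim$truth$modules))
    sets[[sprintf("planted_module_%d", i)]] <-
      list(description = "planted co-expression module",
           genes = sim$truth$modules[[i]]$genes)
  bg <- with_seed(derive_seed(seed, 12), replicate(5, sample(ds$gene_ids, 15),
                                                   simplify = FALSE))
  for (i in seq_along(bg))
    sets[[sprintf("background_%d", i)]] <-
      list(description = "random background set", genes = bg[[i]])
  class(sets) <- "gene_set_collection"
  focal <- names(deg_tables)[vapply(deg_tables, nrow, integer(1)) > 0]
  enrich <- lapply(deg_tables[focal], function(t)
    ora(t$gene_id, sets, ds$gene_ids))
  ppin <- simulate_ppin(length(ds$gene_ids), 2, seed = derive_seed(seed, 13),
                        node_ids = ds$gene_ids)
  catalog <- simulate_drug_catalog(ppin, n_drugs = n_drugs,
                                   targets_per_drug_range = c(2, 5),
                                   seed = derive_seed(seed, 14))
  last <- focal[length(focal)]
  repurposed <- propose_drugs(catalog, deg_tables[[last]])
  screening <- screen_combinations(
    ppin, drug_target_sets(catalog), deg_tables[[last]]$gene_id,
    n_perm = n_perm, seed = derive_seed(seed, 15))
  res <- list(dataset = ds, truth = sim$truth, contrasts = contrasts,
              deg_tables = deg_tables, mi = mis, networks = nets,
              alignment = alignment, enrichment = enrich, ppin = ppin,
              catalog = catalog, repurposing = repurposed,
              screening = screening,
              summary = list(
                n_genes = length(ds$gene_ids),
                n_samples = length(ds$sample_ids),
                degs_per_contrast = vapply(deg_tables, nrow, integer(1)),
                k_selected = alignment$k,
                n_aligned_modules = length(alignment$modules),
                n_proposed_drugs = repurposed$n_drugs,
                n_effective_pairs = sum(screening$pairs$effective)))
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

#' Write pipeline outputs as TSV plus a JSON run summary
#'
#' @param res a [run_pipeline()] result.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  write_expression(res$dataset, p("expression.tsv"), p("samples.tsv"))
  for (nm in names(res$contrasts)) write_de(res$contrasts[[nm]], p(paste0("de_", nm, ".tsv")))
  utils::write.table(res$screening$pairs, p("drug_pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(res$repurposing$pairs, p("repurposing.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_network(res$ppin, p("ppin.tsv"))
  jsonlite::write_json(res$summary, p("run_summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}
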