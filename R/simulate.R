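#' Simulation configuration for synthetic expression data
#'
#' Describes a multi-group log2-scale expression experiment with planted
#' differential expression, planted co-expression modules (latent-factor
#' model), additive batch offsets and Gaussian noise. This is the synthetic
#' stand-in for staged-lymphoma microarray series: each group plays the role
#' of a disease stage.
#'
#' @param n_genes number of genes.
#' @param groups named integer vector: samples per group (>= 2 each).
#' @param de_spec list of lists `{genes, group, effect}`: gene indices shifted
#'   by `effect` log2 units in the named group.
#' @param module_spec list of lists `{genes, groups, loading}`: gene indices
#'   sharing a per-sample latent factor (standard normal) scaled by `loading`
#'   in each listed group (condition) — active modules induce co-expression.
#' @param batch_spec named numeric vector of per-batch additive offsets;
#'   samples are assigned to batches round-robin. `NULL` for a single batch.
#' @param noise_sd Gaussian noise standard deviation (log2 units, > 0).
#' @param baseline_mean,baseline_sd distribution of per-gene baselines.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_genes, groups, de_spec = list(),
                              module_spec = list(), batch_spec = NULL,
                              noise_sd = 0.5, baseline_mean = 7,
                              baseline_sd = 1) {
  if (n_genes < 1) stopf("n_genes must be positive")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stopf("groups must be a named vector")
  if (any(groups < 2)) stopf("every group needs >= 2 samples")
  if (noise_sd <= 0) stopf("noise_sd must be > 0")
  for (d in de_spec) {
    if (any(d$genes < 1 | d$genes > n_genes)) stopf("de_spec gene index out of range")
    if (!d$group %in% names(groups)) stopf("de_spec group '%s' unknown", d$group)
  }
  for (m in module_spec) {
    if (any(m$genes < 1 | m$genes > n_genes)) stopf("module_spec gene index out of range")
    if (!all(m$groups %in% names(groups))) stopf("module_spec group unknown")
  }
  de_all <- unlist(lapply(de_spec, `[[`, "genes"))
  mod_all <- unlist(lapply(module_spec, `[[`, "genes"))
  overlap <- intersect(de_all, mod_all)
  if (length(overlap))
    msg("%d genes appear in both de_spec and module_spec", length(overlap))
  structure(list(n_genes = n_genes, groups = groups, de_spec = de_spec,
                 module_spec = module_spec, batch_spec = batch_spec,
                 noise_sd = noise_sd, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd),
            class = "simulation_config")
}

#' Simulate a multi-group expression dataset with known truth
#'
#' Values are baseline + DE shift + latent-factor module signal + batch
#' offset + Gaussian noise, deterministically from `seed`. The returned truth
#' records planted DE genes per affected group and module memberships per
#' condition, sufficient for recovery tests downstream.
#'
#' @param cfg a [simulation_config()].
#' @param seed integer RNG seed.
#' @return A list with `dataset` (an [expression_dataset()]) and `truth`
#'   (`de_genes`: named list of gene ids per affected group; `modules`: list
#'   of `{genes, groups}` with gene ids).
#' @export
simulate_expression <- function(cfg, seed) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_seed(seed, {
    gene_ids <- sprintf("g%04d", seq_len(cfg$n_genes))
    grp_names <- names(cfg$groups)
    group_of <- rep(grp_names, times = cfg$groups)
    n_samples <- length(group_of)
    sample_ids <- sprintf("s%03d_%s", seq_len(n_samples), group_of)
    baseline <- stats::rnorm(cfg$n_genes, cfg$baseline_mean, cfg$baseline_sd)
    m <- matrix(baseline, nrow = cfg$n_genes, ncol = n_samples)
    for (d in cfg$de_spec)
      m[d$genes, group_of == d$group] <- m[d$genes, group_of == d$group] + d$effect
    for (mod in cfg$module_spec) {
      for (g in mod$groups) {
        cols <- which(group_of == g)
        f <- stats::rnorm(length(cols))  # shared per-sample latent factor
        m[mod$genes, cols] <- m[mod$genes, cols] +
          mod$loading * matrix(f, nrow = length(mod$genes),
                               ncol = length(cols), byrow = TRUE)
      }
    }
    batch <- rep("b1", n_samples)
    if (!is.null(cfg$batch_spec)) {
      bn <- names(cfg$batch_spec)
      batch <- bn[(seq_len(n_samples) - 1L) %% length(bn) + 1L]
      m <- m + matrix(cfg$batch_spec[batch], nrow = cfg$n_genes,
                      ncol = n_samples, byrow = TRUE)
    }
    m <- m + matrix(stats::rnorm(length(m), 0, cfg$noise_sd), nrow = cfg$n_genes)
    dimnames(m) <- list(gene_ids, sample_ids)
    meta <- data.frame(sample_id = sample_ids, group = group_of, batch = batch,
                       stringsAsFactors = FALSE)
    de_truth <- list()
    for (d in cfg$de_spec)
      de_truth[[d$group]] <- unique(c(de_truth[[d$group]], gene_ids[d$genes]))
    modules <- lapply(cfg$module_spec, function(mod)
      list(genes = gene_ids[mod$genes], groups = mod$groups))
    list(dataset = expression_dataset(m, meta),
         truth = list(de_genes = de_truth, modules = modules))
  })
}

#' Simulate a scale-free interactome by preferential attachment
#'
#' Starts from `attach_edges` isolated seed nodes; each subsequent node
#' attaches `attach_edges` edges to distinct existing nodes chosen
#' proportionally to degree (uniformly while all degrees are zero), giving a
#' connected graph with exactly `attach_edges * (n_nodes - attach_edges)`
#' edges and a heavy-tailed degree distribution.
#'
#' @param n_nodes number of nodes (must exceed `2 * attach_edges`).
#' @param attach_edges edges added per incoming node (>= 1).
#' @param seed integer RNG seed.
#' @param node_ids optional character vector of node names (length `n_nodes`).
#' @return An undirected simple `igraph` graph.
#' @export
simulate_ppin <- function(n_nodes, attach_edges, seed, node_ids = NULL) {
  if (attach_edges < 1) stopf("attach_edges must be >= 1")
  if (n_nodes <= 2 * attach_edges)
    stopf("n_nodes must exceed 2 * attach_edges for a meaningful graph")
  if (is.null(node_ids)) node_ids <- sprintf("n%04d", seq_len(n_nodes))
  if (length(node_ids) != n_nodes) stopf("node_ids length must equal n_nodes")
  with_seed(seed, {
    m <- attach_edges
    # repeated-nodes urn: each endpoint occurrence is one ticket
    targets <- seq_len(m)
    urn <- integer(0)
    edges <- matrix(0L, nrow = m * (n_nodes - m), ncol = 2)
    row <- 1L
    for (v in (m + 1L):n_nodes) {
      for (t in targets) {
        edges[row, ] <- c(v, t)
        row <- row + 1L
      }
      urn <- c(urn, targets, rep(v, m))
      # next targets: m distinct degree-proportional draws
      targets <- integer(0)
      while (length(targets) < m) {
        cand <- urn[sample.int(length(urn), 1L)]
        if (!cand %in% targets) targets <- c(targets, cand)
      }
    }
    g <- igraph::make_empty_graph(n_nodes, directed = FALSE)
    g <- igraph::add_edges(g, t(edges))
    igraph::V(g)$name <- node_ids
    g
  })
}

#' Simulate a drug catalog against an interactome
#'
#' Every drug receives a uniform number of targets in
#' `targets_per_drug_range`, sampled without replacement from the network's
#' nodes, each with one action term drawn from `action_vocab_probs`
#' (the reserved name `"unspecified"` yields an empty actions field).
#'
#' @param network an `igraph` graph whose vertex names are gene ids.
#' @param n_drugs number of drugs.
#' @param targets_per_drug_range integer length-2 vector (min, max).
#' @param action_vocab_probs named numeric vector of action-term
#'   probabilities; normalized internally.
#' @param seed integer RNG seed.
#' @param p_approved probability a drug carries the "approved" group.
#' @param p_biotech probability a drug is a biotech entity.
#' @return A [drug_catalog()] (all interactions of category "target").
#' @export
simulate_drug_catalog <- function(network, n_drugs, targets_per_drug_range,
                                  action_vocab_probs = c(inhibitor = 0.3,
                                    antagonist = 0.1, agonist = 0.15,
                                    activator = 0.05, binder = 0.1,
                                    unspecified = 0.3),
                                  seed = 1, p_approved = 1, p_biotech = 0.1) {
  nodes <- igraph::V(network)$name
  if (!length(nodes)) stopf("network is empty")
  r <- targets_per_drug_range
  if (length(r) != 2 || r[1] < 1 || r[1] > r[2]) stopf("bad targets_per_drug_range")
  if (r[2] > length(nodes)) stopf("targets_per_drug_range upper bound exceeds node count")
  probs <- action_vocab_probs / sum(action_vocab_probs)
  with_seed(seed, {
    ids <- sprintf("D%04d", seq_len(n_drugs))
    drugs <- data.frame(
      drug_id = ids,
      name = paste0("drug_", ids),
      molecule_type = ifelse(stats::runif(n_drugs) < p_biotech,
                             "biotech", "small_molecule"),
      groups = ifelse(stats::runif(n_drugs) < p_approved, "approved",
                      "investigational"),
      indication_tags = "",
      stringsAsFactors = FALSE)
    rows <- list()
    for (i in seq_len(n_drugs)) {
      k <- sample(r[1]:r[2], 1L)
      tg <- sample(nodes, k)
      act <- sample(names(probs), k, replace = TRUE, prob = probs)
      act[act == "unspecified"] <- ""
      rows[[i]] <- data.frame(drug_id = ids[i], gene_id = tg,
                              category = "target", actions = act,
                              stringsAsFactors = FALSE)
    }
    drug_catalog(drugs, do.call(rbind, rows))
  })
}
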