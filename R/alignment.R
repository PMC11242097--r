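#' Build the joint graph of two co-expression networks
#'
#' Each gene appears twice, once per network; within-network edges carry
#' weight 1 (binary adjacency) and the two copies of every gene are coupled
#' by an edge of weight `beta`, giving the block matrix
#' `[[A_A, beta I], [beta I, A_B]]`. Larger `beta` pulls the two copies of a
#' gene together in the spectral embedding.
#'
#' @param net_a,net_b [hard_threshold()] networks pruned to a common gene
#'   universe (see [prune_isolated()]).
#' @param beta coupling weight (> 0; default 1).
#' @return Object of class `joint_graph`: list with `w` (2N x 2N symmetric
#'   matrix), `gene_ids`, `beta`; node order is genes-in-A then genes-in-B.
#' @export
build_joint_graph <- function(net_a, net_b, beta = 1) {
  if (beta <= 0) stopf("beta must be > 0")
  if (!identical(net_a$gene_ids, net_b$gene_ids))
    stopf("networks must share the same gene universe (apply prune_isolated)")
  n <- length(net_a$gene_ids)
  bi <- diag(beta, n)
  w <- rbind(cbind(net_a$adjacency, bi), cbind(bi, net_b$adjacency))
  nodes <- c(paste0(net_a$gene_ids, "::A"), paste0(net_b$gene_ids, "::B"))
  dimnames(w) <- list(nodes, nodes)
  structure(list(w = w, gene_ids = net_a$gene_ids, beta = beta),
            class = "joint_graph")
}

joint_laplacian <- function(joint) {
  w <- joint$w
  deg <- rowSums(w)
  keep <- deg > 0
  if (!all(keep)) {
    msg("dropped %d zero-degree nodes before decomposition", sum(!keep))
    w <- w[keep, keep, drop = FALSE]
    deg <- deg[keep]
  }
  inv_sqrt <- 1 / sqrt(deg)
  l <- diag(nrow(w)) - (inv_sqrt * w) * rep(inv_sqrt, each = nrow(w))
  list(l = (l + t(l)) / 2, nodes = rownames(w))
}

#' Choose the cluster count by the eigenvalue gap
#'
#' Computes the smallest eigenvalues of the symmetric normalized Laplacian
#' `L = I - D^{-1/2} W D^{-1/2}` of the joint graph and returns the `k` in
#' `[k_min, k_max]` maximizing the gap `lambda_{k+1} - lambda_k` (ties go to
#' the smallest k).
#'
#' @param joint a [build_joint_graph()] result.
#' @param k_min,k_max search range (default 2..30; `k_max` is capped below
#'   the node count).
#' @return List with `k` and `eigenvalues` (ascending, first `k_max + 1`).
#' @export
select_k_eigengap <- function(joint, k_min = 2, k_max = 30) {
  if (k_min < 2) stopf("k_min must be >= 2")
  lap <- joint_laplacian(joint)
  n <- nrow(lap$l)
  k_max <- min(k_max, n - 1)
  if (k_max < k_min) stopf("k range empty after capping at node count")
  ev <- sort(eigen(lap$l, symmetric = TRUE, only.values = TRUE)$values)
  gaps <- ev[(k_min + 1):(k_max + 1)] - ev[k_min:k_max]
  k <- (k_min:k_max)[which.max(gaps)]
  list(k = k, eigenvalues = ev[seq_len(k_max + 1)])
}

#' Joint spectral clustering of two networks
#'
#' Embeds the joint graph with the eigenvectors of the `k` smallest
#' Laplacian eigenvalues, length-normalizes the rows and clusters them with
#' seeded k-means (multiple restarts, best inertia). Each cluster becomes a
#' candidate aligned module with per-network member sets (from the node
#' copies) and their gene union.
#'
#' @param joint a [build_joint_graph()] result.
#' @param k cluster count (from [select_k_eigengap()] or user choice).
#' @param seed integer RNG seed.
#' @param nstart k-means restarts (default 10).
#' @return List of candidate modules: each a list with `id`, `genes`
#'   (union), `members_a`, `members_b`.
#' @export
spectral_align <- function(joint, k, seed = 1, nstart = 10) {
  lap <- joint_laplacian(joint)
  dec <- eigen(lap$l, symmetric = TRUE)
  n <- nrow(lap$l)
  u <- dec$vectors[, n - seq_len(k) + 1, drop = FALSE]  # k smallest
  norms <- sqrt(rowSums(u^2))
  norms[norms == 0] <- 1
  u <- u / norms
  km <- NULL
  for (attempt in 0:10) {
    km <- try(with_seed(derive_seed(seed, attempt),
                        stats::kmeans(u, centers = k, nstart = nstart,
                                      iter.max = 100)),
              silent = TRUE)
    if (!inherits(km, "try-error") && length(unique(km$cluster)) == k) break
    km <- NULL
  }
  if (is.null(km)) stopf("k-means failed to produce %d non-empty clusters", k)
  nodes <- lap$nodes
  gene <- sub("::[AB]$", "", nodes)
  net <- sub("^.*::", "", nodes)
  lapply(seq_len(k), function(cl) {
    in_cl <- km$cluster == cl
    ma <- sort(unique(gene[in_cl & net == "A"]))
    mb <- sort(unique(gene[in_cl & net == "B"]))
    list(id = cl, genes = sort(unique(c(ma, mb))), members_a = ma, members_b = mb)
  })
}

#' Filter candidate aligned modules
#'
#' Within each candidate's union-induced subgraph (edge present if in either
#' network) connected components smaller than `small_component_cutoff` are
#' removed; the module is then kept only if its gene union stays within
#' `[size_min, size_max]` and it has members from both networks. Kept
#' modules carry their induced edge list.
#'
#' @param candidates output of [spectral_align()].
#' @param net_a,net_b the two [hard_threshold()] networks.
#' @param size_min,size_max gene-union size bounds (default 8 and 800).
#' @param small_component_cutoff minimum component size (default 3).
#' @return List of aligned modules; each adds `edges` (data.frame gene1,
#'   gene2, in_a, in_b) to the candidate fields.
#' @export
filter_modules <- function(candidates, net_a, net_b, size_min = 8,
                           size_max = 800, small_component_cutoff = 3) {
  union_adj <- pmax(net_a$adjacency, net_b$adjacency)
  ids <- net_a$gene_ids
  out <- list()
  for (cand in candidates) {
    genes <- intersect(cand$genes, ids)
    if (!length(genes)) next
    sub <- union_adj[genes, genes, drop = FALSE]
    g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected")
    comp <- igraph::components(g)
    keep_comp <- which(comp$csize >= small_component_cutoff)
    genes <- genes[comp$membership %in% keep_comp]
    if (length(genes) < size_min || length(genes) > size_max) next
    ma <- intersect(cand$members_a, genes)
    mb <- intersect(cand$members_b, genes)
    if (!length(ma) || !length(mb)) next
    sub <- union_adj[genes, genes, drop = FALSE]
    idx <- which(sub == 1 & upper.tri(sub), arr.ind = TRUE)
    edges <- data.frame(gene1 = genes[idx[, 1]], gene2 = genes[idx[, 2]],
                        stringsAsFactors = FALSE)
    edges$in_a <- net_a$adjacency[cbind(edges$gene1, edges$gene2)] == 1
    edges$in_b <- net_b$adjacency[cbind(edges$gene1, edges$gene2)] == 1
    out[[length(out) + 1]] <- list(id = cand$id, genes = genes,
                                   members_a = ma, members_b = mb,
                                   edges = edges)
  }
  out
}

#' Co-expression fold change of module edges
#'
#' Annotates every module edge with `log2((MI_B + eps) / (MI_A + eps))`:
#' positive values mark gain, negative values loss of co-expression from
#' condition A to condition B.
#'
#' @param module an aligned module from [filter_modules()].
#' @param mi_a,mi_b [mi_matrix()] objects for the two conditions.
#' @param epsilon pseudo-MI stabilizer (> 0; default 1e-6).
#' @return The module with a `log2fc_coexpr` column added to `edges`.
#' @export
coexpression_fold_change <- function(module, mi_a, mi_b, epsilon = 1e-6) {
  if (epsilon <= 0) stopf("epsilon must be > 0")
  ma <- if (inherits(mi_a, "mi_matrix")) mi_a$mi else mi_a
  mb <- if (inherits(mi_b, "mi_matrix")) mi_b$mi else mi_b
  e <- module$edges
  pairs <- cbind(e$gene1, e$gene2)
  e$log2fc_coexpr <- log2((mb[pairs] + epsilon) / (ma[pairs] + epsilon))
  module$edges <- e
  module
}

#' Align modules between two co-expression networks
#'
#' Convenience wrapper: prune jointly isolated genes, build the joint graph,
#' pick `k` by eigengap (unless given), run seeded spectral clustering,
#' filter by size/connectivity, and annotate edges with co-expression fold
#' change.
#'
#' @param net_a,net_b [hard_threshold()] networks on one gene universe.
#' @param mi_a,mi_b the condition [mi_matrix()] objects.
#' @param beta copy-coupling weight (default 1).
#' @param k cluster count override (`NULL` = eigengap choice).
#' @param k_min,k_max eigengap search range.
#' @param seed integer RNG seed.
#' @param ... passed to [filter_modules()].
#' @return List with `modules`, `k`, `eigenvalues`.
#' @export
align_modules <- function(net_a, net_b, mi_a, mi_b, beta = 1, k = NULL,
                          k_min = 2, k_max = 30, seed = 1, ...) {
  pruned <- prune_isolated(net_a, net_b)
  joint <- build_joint_graph(pruned$net_a, pruned$net_b, beta = beta)
  ev <- NULL
  if (is.null(k)) {
    sel <- select_k_eigengap(joint, k_min, min(k_max, nrow(joint$w) - 1))
    k <- sel$k; ev <- sel$eigenvalues
  }
  cands <- spectral_align(joint, k, seed = seed)
  mods <- filter_modules(cands, pruned$net_a, pruned$net_b, ...)
  mods <- lapply(mods, coexpression_fold_change, mi_a = mi_a, mi_b = mi_b)
  list(modules = mods, k = k, eigenvalues = ev)
}
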