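#' Largest connected component of a network
#'
#' All proximity computations are restricted to the interactome's largest
#' connected component; genes outside it are dropped by the callers with
#' logged counts.
#'
#' @param net an undirected `igraph` graph.
#' @return The induced subgraph of the largest component.
#' @export
largest_component <- function(net) {
  comp <- igraph::components(net)
  keep <- which(comp$membership == which.max(comp$csize))
  igraph::induced_subgraph(net, keep)
}

#' Unweighted shortest-path distances between node sets
#'
#' Dijkstra on unit edge weights (equivalently breadth-first search);
#' `d(v, v) = 0`. Errors if any node is absent from the graph.
#'
#' @param net an undirected `igraph` graph (callers pre-restrict to the
#'   largest connected component).
#' @param sources,targets character vectors of node names.
#' @return Numeric matrix of distances, sources x targets.
#' @export
shortest_path_distances <- function(net, sources, targets) {
  nodes <- igraph::V(net)$name
  missing <- setdiff(c(sources, targets), nodes)
  if (length(missing))
    stopf("nodes absent from the network: %s", paste(missing, collapse = ", "))
  igraph::distances(net, v = sources, to = targets, algorithm = "dijkstra")
}

#' Separation between two node sets
#'
#' `s_AB = <d_AB> - (<d_AA> + <d_BB>) / 2`, where `<d_AB>` averages, over
#' every node of both sets, its closest distance to the other set, and
#' `<d_AA>` averages each node's closest distance to another node of its own
#' set (0 for singletons). Negative values mean the two sets overlap
#' topologically.
#'
#' @param net an undirected `igraph` graph.
#' @param a,b nonempty character vectors of node names.
#' @param dist_matrix optional precomputed all-pairs distance matrix.
#' @return The separation `s_AB` (graph-distance units).
#' @export
separation <- function(net, a, b, dist_matrix = NULL) {
  if (!length(a) || !length(b)) stopf("both node sets must be nonempty")
  a <- unique(a); b <- unique(b)
  d <- if (is.null(dist_matrix)) shortest_path_distances(net, union(a, b), union(a, b))
       else dist_matrix
  dab <- (sum(apply(d[a, b, drop = FALSE], 1, min)) +
          sum(apply(d[b, a, drop = FALSE], 1, min))) / (length(a) + length(b))
  within <- function(s) {
    if (length(s) == 1) return(0)
    ds <- d[s, s, drop = FALSE]
    diag(ds) <- Inf
    mean(apply(ds, 1, min))
  }
  dab - (within(a) + within(b)) / 2
}

# Degree bins for the permutation null: nodes grouped by floor(log2(degree)),
# bins merged upward (and the last remnant downward) until each holds at
# least min_bin_size nodes.
degree_bins <- function(net, min_bin_size = 25) {
  deg <- igraph::degree(net)
  lvl <- floor(log2(pmax(deg, 1)))
  ord <- sort(unique(lvl))
  bins <- list(); cur <- character(0)
  for (l in ord) {
    cur <- c(cur, names(deg)[lvl == l])
    if (length(cur) >= min_bin_size) {
      bins[[length(bins) + 1]] <- cur
      cur <- character(0)
    }
  }
  if (length(cur)) {
    if (length(bins)) bins[[length(bins)]] <- c(bins[[length(bins)]], cur)
    else bins[[1]] <- cur
  }
  assign_bin <- integer(igraph::vcount(net))
  names(assign_bin) <- names(deg)
  for (i in seq_along(bins)) assign_bin[bins[[i]]] <- i
  list(bins = bins, of = assign_bin)
}

# One degree-matched random counterpart of node set s (without replacement).
sample_matched <- function(s, bins) {
  counts <- table(bins$of[s])
  out <- character(0)
  for (b in names(counts))
    out <- c(out, sample(bins$bins[[as.integer(b)]], counts[[b]]))
  out
}

#' Proximity z-score of drug targets to a disease module
#'
#' Observed proximity is the closest-distance measure
#' `d(T, D) = mean_t min_g dist(t, g)`. The null redraws both sets with
#' matching sizes and degree profiles (degree-binned sampling without
#' replacement) `n_perm` times; `z = (d - mean_null) / sd_null`. Negative z
#' means the drug targets the disease neighbourhood more closely than
#' degree-matched chance.
#'
#' @param net an undirected `igraph` graph (largest connected component).
#' @param targets drug target node names (nonempty, in `net`).
#' @param disease disease-module node names (nonempty, in `net`).
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param seed integer RNG seed.
#' @param min_bin_size minimum degree-bin occupancy (default 25).
#' @param dist_matrix optional precomputed all-pairs distance matrix.
#' @return List with `z`, `observed`, `null_mean`, `null_sd`, `degenerate`
#'   (TRUE when the null is constant and z is set to +/-Inf or 0).
#' @export
proximity_zscore <- function(net, targets, disease, n_perm = 1000, seed = 1,
                             min_bin_size = 25, dist_matrix = NULL) {
  if (!length(targets) || !length(disease)) stopf("empty node set")
  if (n_perm < 100) stopf("n_perm must be >= 100")
  targets <- unique(targets); disease <- unique(disease)
  if (is.null(dist_matrix)) {
    all <- igraph::V(net)$name
    dist_matrix <- shortest_path_distances(net, all, all)
  }
  closest <- function(tt, dd)
    mean(apply(dist_matrix[tt, dd, drop = FALSE], 1, min))
  observed <- closest(targets, disease)
  bins <- degree_bins(net, min_bin_size)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    closest(sample_matched(targets, bins), sample_matched(disease, bins))
  }, numeric(1)))
  mu <- mean(null); sdv <- stats::sd(null)
  if (sdv == 0) {
    z <- if (observed > mu) Inf else if (observed < mu) -Inf else 0
    return(list(z = z, observed = observed, null_mean = mu, null_sd = sdv,
                degenerate = TRUE))
  }
  list(z = (observed - mu) / sdv, observed = observed, null_mean = mu,
       null_sd = sdv, degenerate = FALSE)
}

#' Classify a drug pair into one of six network principles
#'
#' Based on the signs of the two drug-disease z-scores and the drug-drug
#' separation. Boundary conventions: `z = 0` counts as not overlapping the
#' disease module, `s = 0` as separated, so "complementary" (the
#' effective-combination principle) requires strict disease overlap of both
#' drugs (`z_A < 0`, `z_B < 0`) with non-overlapping targets (`s >= 0`).
#'
#' @param s_ab separation of the two drugs' targets.
#' @param z_a,z_b the two drug-disease proximity z-scores.
#' @return One of "complementary", "overlapping", "indirect", "independent",
#'   "single_nonoverlapping", "single_overlapping".
#' @export
classify_principle <- function(s_ab, z_a, z_b) {
  if (any(is.na(c(s_ab, z_a, z_b)))) stopf("inputs must be finite")
  both <- z_a < 0 && z_b < 0
  neither <- z_a >= 0 && z_b >= 0
  sep <- s_ab >= 0
  if (both && sep) "complementary"
  else if (both && !sep) "overlapping"
  else if (neither && !sep) "indirect"
  else if (neither && sep) "independent"
  else if (sep) "single_nonoverlapping"
  else "single_overlapping"
}

#' Screen all drug pairs against a disease module
#'
#' Maps drug targets and disease genes into the interactome's largest
#' connected component (drugs with fewer than two mapped targets are
#' discarded, logged), computes each drug's proximity z-score to the disease
#' module and each pair's separation, classifies every pair into a network
#' principle, and marks pairs under "complementary exposure" as effective.
#' For effective pairs, the target-target network joins every cross-drug
#' pair of distinct target genes.
#'
#' @param net an undirected `igraph` interactome.
#' @param drug_targets named list: drug id -> character vector of target
#'   genes.
#' @param disease character vector of disease-module genes (e.g. the top
#'   DEGs of a contrast).
#' @param n_perm permutations per z-score (default 1000).
#' @param seed integer RNG seed.
#' @param min_bin_size degree-bin occupancy for the null (default 25).
#' @return Object of class `proximity_result`: data.frame `pairs` (drug_a,
#'   drug_b, s_ab, z_a, z_b, principle, effective), `z_table`, `tt_edges`
#'   (target-target network of effective pairs), `dual_matrix` (lower half
#'   separations, upper half principle labels), `disease_size`.
#' @export
screen_combinations <- function(net, drug_targets, disease, n_perm = 1000,
                                seed = 1, min_bin_size = 25) {
  lcc <- largest_component(net)
  nodes <- igraph::V(lcc)$name
  disease_in <- intersect(unique(disease), nodes)
  dropped_dis <- length(unique(disease)) - length(disease_in)
  if (dropped_dis) msg("dropped %d disease genes outside the LCC", dropped_dis)
  if (!length(disease_in)) stopf("disease module empty after LCC mapping")
  mapped <- lapply(drug_targets, function(t) intersect(unique(t), nodes))
  keep <- vapply(mapped, function(t) length(t) >= 2, logical(1))
  if (any(!keep)) msg("discarded %d drugs with fewer than two LCC targets",
                      sum(!keep))
  mapped <- mapped[keep]
  if (length(mapped) < 2) stopf("need >= 2 drugs after the >= 2-targets filter")
  dist_matrix <- shortest_path_distances(lcc, nodes, nodes)
  ids <- names(mapped)
  z <- vapply(seq_along(ids), function(i)
    proximity_zscore(lcc, mapped[[i]], disease_in, n_perm = n_perm,
                     seed = derive_seed(seed, i), min_bin_size = min_bin_size,
                     dist_matrix = dist_matrix)$z, numeric(1))
  names(z) <- ids
  combs <- utils::combn(ids, 2)
  pairs <- data.frame(drug_a = combs[1, ], drug_b = combs[2, ],
                      stringsAsFactors = FALSE)
  pairs$s_ab <- vapply(seq_len(nrow(pairs)), function(r)
    separation(lcc, mapped[[pairs$drug_a[r]]], mapped[[pairs$drug_b[r]]],
               dist_matrix = dist_matrix), numeric(1))
  pairs$z_a <- z[pairs$drug_a]; pairs$z_b <- z[pairs$drug_b]
  pairs$principle <- vapply(seq_len(nrow(pairs)), function(r)
    classify_principle(pairs$s_ab[r], pairs$z_a[r], pairs$z_b[r]), character(1))
  pairs$effective <- pairs$principle == "complementary"
  tt <- list()
  for (r in which(pairs$effective)) {
    ta <- mapped[[pairs$drug_a[r]]]; tb <- mapped[[pairs$drug_b[r]]]
    grid <- expand.grid(gene_a = ta, gene_b = tb, stringsAsFactors = FALSE)
    grid <- grid[grid$gene_a != grid$gene_b, , drop = FALSE]
    if (nrow(grid)) {
      grid$drug_a <- pairs$drug_a[r]; grid$drug_b <- pairs$drug_b[r]
      tt[[length(tt) + 1]] <- grid
    }
  }
  tt_edges <- if (length(tt)) do.call(rbind, tt)
              else data.frame(gene_a = character(0), gene_b = character(0),
                              drug_a = character(0), drug_b = character(0))
  dual <- matrix("", length(ids), length(ids), dimnames = list(ids, ids))
  for (r in seq_len(nrow(pairs))) {
    dual[pairs$drug_b[r], pairs$drug_a[r]] <- sprintf("%.4f", pairs$s_ab[r])
    dual[pairs$drug_a[r], pairs$drug_b[r]] <- pairs$principle[r]
  }
  structure(list(pairs = pairs, z_table = data.frame(drug_id = ids, z = unname(z)),
                 tt_edges = tt_edges, dual_matrix = dual,
                 disease_size = length(disease_in)),
            class = "proximity_result")
}

#' @export
print.proximity_result <- function(x, ...) {
  cat(sprintf("proximity_result: %d pairs, %d effective (complementary), disease module %d genes\n",
              nrow(x$pairs), sum(x$pairs$effective), x$disease_size))
  invisible(x)
}

#' Drug target sets from a catalog
#'
#' Extracts each approved drug's "target"-category genes as the named list
#' consumed by [screen_combinations()].
#'
#' @param catalog a [drug_catalog()].
#' @param approved_only keep only approved drugs (default TRUE).
#' @param drug_ids optional subset of drug ids.
#' @return Named list: drug id -> character vector of target genes.
#' @export
drug_target_sets <- function(catalog, approved_only = TRUE, drug_ids = NULL) {
  inter <- catalog$interactions
  inter <- inter[inter$category == "target", , drop = FALSE]
  if (approved_only) {
    ok <- vapply(split_terms(catalog$drugs$groups), function(g)
      "approved" %in% g, logical(1))
    inter <- inter[inter$drug_id %in% catalog$drugs$drug_id[ok], , drop = FALSE]
  }
  if (!is.null(drug_ids)) inter <- inter[inter$drug_id %in% drug_ids, , drop = FALSE]
  split(inter$gene_id, inter$drug_id)
}
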