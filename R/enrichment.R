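#' Over-representation analysis with fold enrichment
#'
#' Upper-tail hypergeometric test of a query gene list against every set in
#' a collection, within a stated universe. Query genes outside the universe
#' are dropped with a warning; each set is intersected with the universe and
#' skipped if empty. Fold enrichment is `FE = (k/n) / (K/N)` and
#' `p = P(X >= k)`; BH adjustment is across the tested sets.
#'
#' @param query character vector of query gene ids.
#' @param sets a [read_gmt()] collection (or named list with `genes`
#'   elements).
#' @param universe character vector of background gene ids (conventionally
#'   all genes on the expression matrix).
#' @return Object of class `enrichment_result`: data.frame with columns
#'   set, description, k, K, n, N, FE, p, p_adj, overlap (semicolon-joined).
#' @export
ora <- function(query, sets, universe) {
  universe <- unique(as.character(universe))
  query <- unique(as.character(query))
  if (!length(universe)) stopf("empty universe")
  if (!length(query)) stopf("empty query")
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(sprintf("%d query genes outside the universe dropped", length(outside)))
    query <- intersect(query, universe)
    if (!length(query)) stopf("no query genes left inside the universe")
  }
  N <- length(universe); n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]]$genes, universe)
    K <- length(members)
    if (K == 0) return(NULL)
    ov <- intersect(query, members)
    k <- length(ov)
    data.frame(set = nm,
               description = sets[[nm]]$description %||% "",
               k = k, K = K, n = n, N = N,
               FE = (k / n) / (K / N),
               p = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               overlap = paste(sort(ov), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stopf("no sets overlap the universe")
  res <- do.call(rbind, rows)
  res$p_adj <- benjamini_hochberg(res$p)
  res <- res[order(res$p, res$set), c("set", "description", "k", "K", "n", "N",
                                      "FE", "p", "p_adj", "overlap")]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pathway-pathway graph of significant sets
#'
#' Nodes are sets significant at `alpha` (adjusted p), sized by fold
#' enrichment; two sets are joined when they share at least one overlapping
#' query gene, with the shared-gene count as edge weight.
#'
#' @param res an [ora()] result.
#' @param alpha adjusted-p threshold (default 0.05).
#' @return An undirected `igraph` graph with vertex attribute `FE` and edge
#'   attribute `weight`; empty graph if nothing is significant.
#' @export
pathway_graph <- function(res, alpha = 0.05) {
  sig <- res[res$p_adj < alpha, , drop = FALSE]
  g <- igraph::make_empty_graph(0, directed = FALSE)
  if (!nrow(sig)) return(g)
  g <- igraph::add_vertices(g, nrow(sig), name = sig$set, FE = sig$FE)
  ovl <- split_terms(sig$overlap)
  if (nrow(sig) >= 2) {
    for (i in seq_len(nrow(sig) - 1)) for (j in (i + 1):nrow(sig)) {
      shared <- length(intersect(ovl[[i]], ovl[[j]]))
      if (shared >= 1)
        g <- igraph::add_edges(g, c(i, j), weight = shared)
    }
  }
  g
}

#' Fold-enrichment matrix across contrasts
#'
#' Stacks the FE column of several [ora()] results (one per contrast) into a
#' sets x contrasts matrix for heatmap-style comparison.
#'
#' @param results named list of [ora()] results.
#' @return Numeric matrix, `NA` where a set was not tested in a contrast.
#' @export
fe_matrix <- function(results) {
  all_sets <- sort(unique(unlist(lapply(results, `[[`, "set"))))
  m <- matrix(NA_real_, length(all_sets), length(results),
              dimnames = list(all_sets, names(results)))
  for (nm in names(results)) {
    r <- results[[nm]]
    m[r$set, nm] <- r$FE
  }
  m
}
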