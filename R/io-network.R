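#' Read an undirected interaction network from a two-column edge list
#'
#' Self-loops are dropped and duplicate edges collapsed, each with a logged
#' count. The result is an undirected simple [igraph::graph] whose vertex
#' names are the (opaque, case-sensitive) node identifiers.
#'
#' @param path TSV with two node columns; lines starting with `#` ignored.
#' @param header whether the first row is a header (default `FALSE`, the
#'   edge-list convention).
#' @return An undirected simple `igraph` graph.
#' @export
read_network <- function(path, header = FALSE) {
  tab <- read_tsv_raw(path, header = header)
  if (nrow(tab) == 0) stopf("empty network file: %s", path)
  if (ncol(tab) < 2) stopf("edge list needs two node columns")
  from <- as.character(tab[[1]]); to <- as.character(tab[[2]])
  loops <- from == to
  if (any(loops)) msg("dropped %d self-loops", sum(loops))
  from <- from[!loops]; to <- to[!loops]
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  n_before <- igraph::ecount(g)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  dup <- n_before - igraph::ecount(g)
  if (dup > 0) msg("collapsed %d duplicate edges", dup)
  g
}

#' Write a network as a two-column edge list TSV
#'
#' @param g an undirected `igraph` graph.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(g, path) {
  el <- igraph::as_edgelist(g, names = TRUE)
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
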