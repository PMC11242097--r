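# Shared fixtures and independent oracles, built in code at test time.

toy_dataset <- function(m = NULL, groups = c("A", "A", "B", "B"), batch = NULL) {
  if (is.null(m)) {
    set.seed(42)
    m <- matrix(rnorm(10 * length(groups), 7, 1), 10, length(groups))
  }
  rownames(m) <- sprintf("g%02d", seq_len(nrow(m)))
  colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  meta <- data.frame(sample_id = colnames(m), group = groups,
                     stringsAsFactors = FALSE)
  if (!is.null(batch)) meta$batch <- batch
  expression_dataset(m, meta)
}

# wrap an adjacency matrix as a coexpression_network
adj_network <- function(adj) {
  structure(list(gene_ids = rownames(adj), score = adj, adjacency = adj,
                 q = 0, threshold = 0),
            class = "coexpression_network")
}

# planted-partition adjacency over named genes
planted_partition <- function(genes, blocks, p_in = 0.6, p_out = 0.02, seed = 1) {
  set.seed(seed)
  n <- length(genes)
  adj <- matrix(0, n, n, dimnames = list(genes, genes))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    p <- if (blocks[i] == blocks[j]) p_in else p_out
    adj[i, j] <- adj[j, i] <- as.numeric(stats::runif(1) < p)
  }
  adj_network(adj)
}

# adjusted Rand index (independent of the package)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  si <- sum(choose(rowSums(tab), 2)); sj <- sum(choose(colSums(tab), 2))
  sij <- sum(choose(tab, 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# queue-based breadth-first-search distances (oracle for shortest paths)
bfs_distances <- function(g, from) {
  nodes <- igraph::V(g)$name
  adj <- lapply(igraph::adjacent_vertices(g, nodes), function(v) v$name)
  names(adj) <- nodes
  d <- rep(Inf, length(nodes)); names(d) <- nodes
  d[from] <- 0
  queue <- from
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (is.infinite(d[w])) {
      d[w] <- d[v] + 1
      queue <- c(queue, w)
    }
  }
  d
}

# exhaustive MRNETB objective over all nonempty predictor subsets
exhaustive_best_J <- function(R, u) {
  p <- length(u)
  best <- -Inf
  for (k in seq_len(p)) for (S in utils::combn(p, k, simplify = FALSE)) {
    red <- if (k > 1) sum(R[S, S][upper.tri(R[S, S])]) / k else 0
    best <- max(best, sum(u[S]) - red)
  }
  best
}

# brute-force hypergeometric upper tail from the pmf (oracle for ORA)
hyper_tail <- function(k, K, N, n) {
  kk <- k:min(n, K)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# four-drug toy catalog from the repurposing rule table
toy_catalog <- function() {
  drugs <- data.frame(
    drug_id = c("D1", "D2", "D3", "D4"),
    name = paste0("drug", 1:4),
    molecule_type = "small_molecule",
    groups = "approved",
    indication_tags = "",
    stringsAsFactors = FALSE)
  inter <- data.frame(
    drug_id = c("D1", "D2", "D3", "D4"),
    gene_id = c("G_up", "G_up", "G_down", "G_down"),
    category = "target",
    actions = c("inhibitor", "agonist", "", "inhibitor"),
    stringsAsFactors = FALSE)
  drug_catalog(drugs, inter)
}

# random catalog + DEG list for the brute-force repurposing oracle
random_catalog <- function(seed, n_drugs = 20, n_genes = 20) {
  set.seed(seed)
  genes <- sprintf("G%02d", seq_len(n_genes))
  vocab <- c("inhibitor", "antagonist", "agonist", "activator",
             "partial agonist", "binder", "substrate", "")
  drugs <- data.frame(
    drug_id = sprintf("D%02d", seq_len(n_drugs)),
    name = sprintf("drug%02d", seq_len(n_drugs)),
    molecule_type = sample(c("small_molecule", "biotech"), n_drugs, TRUE),
    groups = sample(c("approved", "investigational", "approved;nutraceutical"),
                    n_drugs, TRUE),
    indication_tags = "", stringsAsFactors = FALSE)
  n_int <- n_drugs * 3
  inter <- data.frame(
    drug_id = sample(drugs$drug_id, n_int, TRUE),
    gene_id = sample(genes, n_int, TRUE),
    category = sample(c("target", "carrier", "transporter", "enzyme"),
                      n_int, TRUE, prob = c(0.7, 0.1, 0.1, 0.1)),
    actions = vapply(seq_len(n_int), function(i)
      paste(sample(vocab, sample(0:2, 1)), collapse = ";"), character(1)),
    stringsAsFactors = FALSE)
  inter <- unique(inter)
  degs <- data.frame(gene_id = sample(genes, 8),
                     direction = sample(c("up", "down"), 8, TRUE),
                     stringsAsFactors = FALSE)
  list(catalog = drug_catalog(drugs, inter), degs = degs)
}

# independent brute-force filter over the full cross product
brute_force_proposals <- function(catalog, degs) {
  enh <- c("activator", "agonist", "partial agonist", "stimulator",
           "inducer", "potentiator")
  sup <- c("inhibitor", "antagonist", "blocker", "suppressor",
           "negative allosteric modulator", "antisense")
  out <- character(0)
  for (r in seq_len(nrow(catalog$interactions))) {
    row <- catalog$interactions[r, ]
    if (row$category != "target") next
    grp <- strsplit(catalog$drugs$groups[catalog$drugs$drug_id == row$drug_id],
                    ";")[[1]]
    if (!"approved" %in% grp) next
    hit <- match(row$gene_id, degs$gene_id)
    if (is.na(hit)) next
    acts <- strsplit(row$actions, ";")[[1]]
    acts <- trimws(acts[nzchar(trimws(acts))])
    bad <- if (degs$direction[hit] == "up") enh else sup
    if (length(acts) && any(tolower(acts) %in% bad)) next
    out <- c(out, paste(row$drug_id, row$gene_id))
  }
  sort(unique(out))
}
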