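two_clique_net <- function(genes_per = 10) {
  n <- 2 * genes_per
  g <- sprintf("h%02d", seq_len(n))
  adj <- matrix(0, n, n, dimnames = list(g, g))
  adj[1:genes_per, 1:genes_per] <- 1
  adj[(genes_per + 1):n, (genes_per + 1):n] <- 1
  diag(adj) <- 0
  adj_network(adj)
}

test_that("joint graph has the block-coupling structure", {
  net <- two_clique_net(5)
  jg <- build_joint_graph(net, net, beta = 2)
  n <- length(net$gene_ids)
  expect_equal(dim(jg$w), c(2 * n, 2 * n))
  expect_equal(jg$w, t(jg$w))
  # edge count: |E_A| + |E_B| + N coupling edges
  n_edges <- sum(jg$w != 0) / 2
  ea <- sum(net$adjacency) / 2
  expect_equal(n_edges, 2 * ea + n)
  expect_equal(unname(diag(jg$w[1:n, (n + 1):(2 * n)])), rep(2, n))
  expect_error(build_joint_graph(net, net, beta = 0), "beta")
})

test_that("eigengap finds disconnected components and coupled cliques", {
  # c disconnected components -> c zero eigenvalues, k = c
  net <- two_clique_net(6)
  jg <- build_joint_graph(net, net, beta = 5)
  sel <- select_k_eigengap(jg, 2, 8)
  expect_equal(sel$k, 2)
  expect_equal(sum(abs(sel$eigenvalues) < 1e-10), 2)
  # two cliques joined by a weak bridge still split at k = 2
  net2 <- two_clique_net(10)
  net2$adjacency[10, 11] <- net2$adjacency[11, 10] <- 1
  net2$score <- net2$adjacency
  sel2 <- select_k_eigengap(build_joint_graph(net2, net2, beta = 5), 2, 10)
  expect_equal(sel2$k, 2)
  expect_true(sel2$k >= 2 && sel2$k <= 10)
})

test_that("identical block-diagonal networks align into their cliques", {
  net <- two_clique_net(10)
  jg <- build_joint_graph(net, net, beta = 5)
  mods <- spectral_align(jg, k = 2, seed = 1)
  expect_length(mods, 2)
  sizes <- sort(vapply(mods, function(m) length(m$genes), numeric(1)))
  expect_equal(sizes, c(10, 10))
  for (m in mods) expect_identical(m$members_a, m$members_b)
  # determinism under the seed
  mods2 <- spectral_align(jg, k = 2, seed = 1)
  expect_identical(lapply(mods, `[[`, "genes"), lapply(mods2, `[[`, "genes"))
})

test_that("planted partitions are recovered across network pairs", {
  genes <- sprintf("g%03d", 1:90)
  blocks <- rep(1:3, each = 30)
  aris <- c(); ks <- c()
  for (s in 1:10) {
    na <- planted_partition(genes, blocks, seed = 2 * s)
    nb <- planted_partition(genes, blocks, seed = 2 * s + 1)
    pr <- prune_isolated(na, nb)
    jg <- build_joint_graph(pr$net_a, pr$net_b, beta = 5)
    ks <- c(ks, select_k_eigengap(jg, 2, 10)$k)
    mods <- spectral_align(jg, k = 3, seed = s)
    memb <- rep(NA_integer_, length(pr$net_a$gene_ids))
    names(memb) <- pr$net_a$gene_ids
    for (m in mods) memb[m$genes] <- m$id
    aris <- c(aris, adjusted_rand(memb, blocks[match(names(memb), genes)]))
  }
  expect_gte(mean(aris), 0.9)
  expect_gte(sum(ks == 3), 8)
})

test_that("module filtering enforces size bounds and connectivity", {
  net <- two_clique_net(10)
  # candidate covering one clique plus a 2-node satellite from the other
  cand <- list(list(id = 1, genes = c(sprintf("h%02d", 1:10), "h11", "h12"),
                    members_a = sprintf("h%02d", 1:12),
                    members_b = sprintf("h%02d", 1:10)))
  kept <- filter_modules(cand, net, net, small_component_cutoff = 3)
  expect_length(kept, 1)
  expect_setequal(kept[[1]]$genes, sprintf("h%02d", 1:10))
  # too-small candidates are dropped
  small <- list(list(id = 1, genes = sprintf("h%02d", 1:5),
                     members_a = sprintf("h%02d", 1:5),
                     members_b = sprintf("h%02d", 1:5)))
  expect_length(filter_modules(small, net, net), 0)
  # modules lacking members from one network are dropped
  onesided <- list(list(id = 1, genes = sprintf("h%02d", 1:10),
                        members_a = sprintf("h%02d", 1:10),
                        members_b = character(0)))
  expect_length(filter_modules(onesided, net, net), 0)
})

test_that("co-expression fold change has the documented sign convention", {
  net <- two_clique_net(5)
  jg <- build_joint_graph(net, net, beta = 5)
  mods <- filter_modules(spectral_align(jg, 2, seed = 1), net, net,
                         size_min = 2, small_component_cutoff = 2)
  mi_a <- matrix(0.5, 10, 10, dimnames = list(net$gene_ids, net$gene_ids))
  # equal MI -> zero fold change
  m0 <- coexpression_fold_change(mods[[1]], mi_a, mi_a)
  expect_equal(m0$edges$log2fc_coexpr, rep(0, nrow(m0$edges)))
  # doubled MI -> +1; halved -> -1 (loss is negative)
  m1 <- coexpression_fold_change(mods[[1]], mi_a, 2 * mi_a)
  expect_equal(m1$edges$log2fc_coexpr, rep(1, nrow(m1$edges)), tolerance = 1e-5)
  m2 <- coexpression_fold_change(mods[[1]], 2 * mi_a, mi_a)
  expect_equal(m2$edges$log2fc_coexpr, rep(-1, nrow(m2$edges)), tolerance = 1e-5)
  expect_error(coexpression_fold_change(mods[[1]], mi_a, mi_a, epsilon = 0),
               "epsilon")
})

test_that("self-alignment with strong coupling pairs every gene's copies", {
  genes <- sprintf("g%03d", 1:60)
  blocks <- rep(1:2, each = 30)
  net <- planted_partition(genes, blocks, seed = 77)
  pr <- prune_isolated(net, net)
  jg <- build_joint_graph(pr$net_a, pr$net_b, beta = 20)
  mods <- spectral_align(jg, k = 2, seed = 3)
  for (m in mods) expect_identical(m$members_a, m$members_b)
})
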