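test_that("unit-weight Dijkstra equals breadth-first search on random graphs", {
  set.seed(61)
  for (trial in 1:50) {
    g <- igraph::sample_gnp(sample(8:20, 1), 0.3)
    igraph::V(g)$name <- paste0("v", seq_len(igraph::vcount(g)))
    lcc <- largest_component(g)
    nodes <- igraph::V(lcc)$name
    d <- shortest_path_distances(lcc, nodes, nodes)
    src <- sample(nodes, 1)
    expect_equal(d[src, ], bfs_distances(lcc, src)[colnames(d)])
  }
  pg <- igraph::make_graph(~ a - b, b - c)
  expect_equal(shortest_path_distances(pg, "a", "c")[1, 1], 2)
  expect_equal(shortest_path_distances(pg, "b", "b")[1, 1], 0)
  expect_error(shortest_path_distances(pg, "a", "zz"), "zz")
})

test_that("separation matches hand-evaluated cases and is symmetric", {
  g <- igraph::make_graph(~ x - y)
  expect_equal(separation(g, c("x", "y"), c("x", "y")), -1)
  pg <- igraph::make_graph(~ a - b, b - c, c - d)
  expect_equal(separation(pg, "a", "d"), 3)
  expect_equal(separation(pg, "b", "b"), 0)
  # symmetry on a random graph
  set.seed(62)
  gr <- largest_component(igraph::sample_gnp(15, 0.3))
  igraph::V(gr)$name <- paste0("v", seq_len(igraph::vcount(gr)))
  nodes <- igraph::V(gr)$name
  a <- nodes[1:3]; b <- nodes[4:6]
  expect_equal(separation(gr, a, b), separation(gr, b, a))
  expect_error(separation(gr, character(0), b), "nonempty")
})

test_that("permutation z-score matches the exhaustive null for a single target", {
  g <- simulate_ppin(10, 1, seed = 4)
  nodes <- igraph::V(g)$name
  dm <- shortest_path_distances(g, nodes, nodes)
  disease <- nodes[c(2, 5)]
  closest <- function(tt, dd) mean(apply(dm[tt, dd, drop = FALSE], 1, min))
  # exhaustive null over every (target placement, disease placement)
  vals <- c()
  for (t in nodes) for (dd in utils::combn(nodes, 2, simplify = FALSE))
    vals <- c(vals, closest(t, dd))
  target <- nodes[7]
  z_exact <- (closest(target, disease) - mean(vals)) / stats::sd(vals)
  # min_bin_size above the node count collapses all degrees into one bin,
  # making the permutation null sample the same space
  z_perm <- proximity_zscore(g, target, disease, n_perm = 5000, seed = 11,
                             min_bin_size = 100)$z
  expect_lt(abs(z_perm - z_exact), 0.1)
})

test_that("z-scores are negative for embedded targets and reproducible", {
  g <- simulate_ppin(40, 2, seed = 7)
  nodes <- igraph::V(g)$name
  disease <- nodes[1:8]
  inside <- disease[1:3]  # targets inside the module: observed distance 0
  r1 <- proximity_zscore(g, inside, disease, n_perm = 1000, seed = 3)
  expect_equal(r1$observed, 0)
  expect_lt(r1$z, 0)
  r2 <- proximity_zscore(g, inside, disease, n_perm = 1000, seed = 3)
  expect_identical(r1$z, r2$z)
  expect_error(proximity_zscore(g, inside, disease, n_perm = 50), "n_perm")
})

test_that("principle classification partitions the sign grid", {
  expect_equal(classify_principle(0.4, -1.2, -0.8), "complementary")
  expect_equal(classify_principle(-0.3, -1, -1), "overlapping")
  expect_equal(classify_principle(-0.3, 1, 1), "indirect")
  expect_equal(classify_principle(0.3, 1, 1), "independent")
  expect_equal(classify_principle(0.3, -1, 1), "single_nonoverlapping")
  expect_equal(classify_principle(-0.3, 1, -1), "single_overlapping")
  # boundaries: z = 0 counts as non-overlapping, s = 0 as separated
  expect_equal(classify_principle(0, -1, -1), "complementary")
  expect_equal(classify_principle(0.3, 0, 0), "independent")
  grid <- expand.grid(s = c(-0.5, 0.5), za = c(-1, 1), zb = c(-1, 1))
  labs <- apply(grid, 1, function(r) classify_principle(r[1], r[2], r[3]))
  expect_setequal(unique(labs),
                  c("complementary", "overlapping", "indirect", "independent",
                    "single_nonoverlapping", "single_overlapping"))
  expect_error(classify_principle(NA, 1, 1), "finite")
})

test_that("identical-target drug pairs are never effective", {
  # identical sets inside the disease module: separation <= 0 by construction
  g <- simulate_ppin(30, 2, seed = 9)
  nodes <- igraph::V(g)$name
  disease <- nodes[1:10]
  targets <- list(DA = disease[1:3], DB = disease[1:3])
  scr <- suppressMessages(
    screen_combinations(g, targets, disease, n_perm = 200, seed = 5))
  expect_lte(scr$pairs$s_ab, 0)
  expect_false(any(scr$pairs$effective))
})

test_that("a hand-built fixture produces a complementary pair", {
  # disease triangle in the middle, two drugs adjacent on opposite sides,
  # remote chain so random placements sit farther from the module
  g <- igraph::make_graph(~ m1 - m2, m2 - m3, m1 - m3,
                          a1 - m1, a2 - m1, a1 - a2,
                          b1 - m3, b2 - m3, b1 - b2,
                          c1 - c2, c2 - c3, c3 - c4, c4 - c5, c5 - a2)
  disease <- c("m1", "m2", "m3")
  targets <- list(DA = c("a1", "a2"), DB = c("b1", "b2"))
  scr <- suppressMessages(
    screen_combinations(g, targets, disease, n_perm = 2000, seed = 2))
  expect_equal(nrow(scr$pairs), 1)
  expect_lt(scr$pairs$z_a, 0)
  expect_lt(scr$pairs$z_b, 0)
  expect_gte(scr$pairs$s_ab, 0)
  expect_equal(scr$pairs$principle, "complementary")
  # target-target network joins cross-drug targets only
  expect_true(all(scr$tt_edges$gene_a %in% c("a1", "a2")))
  expect_true(all(scr$tt_edges$gene_b %in% c("b1", "b2")))
})

test_that("screening scores every unordered drug pair deterministically", {
  g <- simulate_ppin(40, 2, seed = 12)
  catalog <- simulate_drug_catalog(g, n_drugs = 6, targets_per_drug_range = c(2, 4),
                                   seed = 13)
  disease <- igraph::V(g)$name[1:12]
  scr <- suppressMessages(screen_combinations(g, drug_target_sets(catalog),
                                              disease, n_perm = 200, seed = 8))
  n_drugs <- nrow(scr$z_table)
  expect_equal(nrow(scr$pairs), choose(n_drugs, 2))
  scr2 <- suppressMessages(screen_combinations(g, drug_target_sets(catalog),
                                               disease, n_perm = 200, seed = 8))
  expect_identical(scr$pairs, scr2$pairs)
})

test_that("z-scores are stable in the permutation count on a small fixture", {
  g <- igraph::make_graph(~ m1 - m2, m2 - m3, m1 - m3,
                          a1 - m1, a2 - m1, a1 - a2,
                          b1 - m3, b2 - m3, b1 - b2,
                          c1 - c2, c2 - c3, c3 - c4, c4 - c5, c5 - a2)
  z1 <- proximity_zscore(g, c("a1", "a2"), c("m1", "m2", "m3"),
                         n_perm = 1000, seed = 4, min_bin_size = 25)$z
  z2 <- proximity_zscore(g, c("a1", "a2"), c("m1", "m2", "m3"),
                         n_perm = 2000, seed = 4, min_bin_size = 25)$z
  expect_lt(abs(z1 - z2), 0.2)
})
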