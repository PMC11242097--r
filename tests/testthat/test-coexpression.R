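test_that("KNN MI estimator is symmetric and tracks the Gaussian closed form", {
  set.seed(41)
  n <- 800; rho <- 0.9
  x <- rnorm(n); y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  est <- knn_mutual_information(x, y)
  expect_lt(abs(est - (-0.5 * log(1 - rho^2))), 0.1)
  expect_identical(est, knn_mutual_information(y, x))
  # independent vectors stay near zero
  nulls <- vapply(1:5, function(s) {
    set.seed(s); knn_mutual_information(rnorm(500), rnorm(500))
  }, numeric(1))
  expect_lt(abs(mean(nulls)), 0.05)
  expect_warning(cz <- knn_mutual_information(rep(1, 20), rnorm(20)), "constant")
  expect_equal(cz, 0)
  expect_error(knn_mutual_information(rnorm(3), rnorm(3), k_nn = 3), "k_nn")
})

test_that("tied values are broken deterministically", {
  x <- rep(1:5, each = 4)  # heavy ties
  y <- rev(x)
  a <- knn_mutual_information(x, y)
  b <- knn_mutual_information(x, y)
  expect_identical(a, b)
  expect_true(is.finite(a))
})

test_that("MI matrix is symmetric with zero diagonal and separates planted modules", {
  cfg <- simulation_config(30, c(A = 30),
    module_spec = list(list(genes = 1:10, groups = "A", loading = 1)),
    noise_sd = 0.3)
  sim <- simulate_expression(cfg, seed = 42)
  mi <- mi_matrix(sim$dataset)
  expect_equal(mi$mi, t(mi$mi))
  expect_equal(diag(mi$mi), rep(0, 30), ignore_attr = TRUE)
  expect_true(all(mi$mi >= 0))
  in_mod <- mi$mi[1:10, 1:10][upper.tri(diag(10))]
  bg <- mi$mi[11:30, 11:30][upper.tri(diag(20))]
  expect_gt(mean(in_mod), mean(bg))
  # two genes -> a single evaluated pair
  two <- mi_matrix(sim$dataset, genes = sim$dataset$gene_ids[1:2])
  expect_equal(sum(two$mi[upper.tri(two$mi)] != 0), 1)
})

test_that("MRNETB objective attains the exhaustive-subset optimum", {
  set.seed(43)
  for (trial in 1:20) {
    p <- 6
    M <- matrix(runif(p * p), p); M <- (M + t(M)) / 2; diag(M) <- 0
    for (t in seq_len(p)) {
      pred <- setdiff(seq_len(p), t)
      sel <- mclnet:::mrnetb_select(M[pred, pred], M[pred, t])
      expect_equal(sel$J, exhaustive_best_J(M[pred, pred], M[pred, t]),
                   tolerance = 1e-9)
    }
  }
})

test_that("MRNETB weights respect structure and relevance bounds", {
  # two independent 2-gene blocks: cross-block weights vanish
  M <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  M[1, 2] <- M[2, 1] <- 1; M[3, 4] <- M[4, 3] <- 1
  w <- mrnetb(M)
  expect_equal(w, t(w))
  expect_equal(diag(w), rep(0, 4), ignore_attr = TRUE)
  expect_equal(w[1, 3], 0); expect_equal(w[2, 4], 0)
  expect_gt(w[1, 2], 0); expect_gt(w[3, 4], 0)
  # weights never exceed the relevance MI
  set.seed(44)
  M2 <- matrix(runif(64), 8); M2 <- (M2 + t(M2)) / 2; diag(M2) <- 0
  dimnames(M2) <- list(letters[1:8], letters[1:8])
  w2 <- mrnetb(M2)
  expect_true(all(w2 <= M2 + 1e-12))
  expect_true(all(w2 >= 0))
})

test_that("hard thresholding keeps exactly the top quantile of positive weights", {
  set.seed(45)
  vals <- sample(seq(0.01, 1, length.out = 100))
  w <- matrix(0, 15, 15, dimnames = list(sprintf("g%02d", 1:15), sprintf("g%02d", 1:15)))
  w[upper.tri(w)][1:100] <- vals
  w <- w + t(w)
  net <- hard_threshold(w, q = 0.95)
  expect_equal(sum(net$adjacency[upper.tri(net$adjacency)]), 5)
  # oracle: sort-and-cut
  kept <- sort(vals, decreasing = TRUE)[1:5]
  expect_setequal(net$score[upper.tri(net$score)][net$score[upper.tri(net$score)] > 0], kept)
  # q = 0 keeps every positive edge
  all_kept <- hard_threshold(w, q = 0)
  expect_equal(sum(all_kept$adjacency[upper.tri(all_kept$adjacency)]), 100)
  expect_error(hard_threshold(w, q = 1), "\\[0, 1\\)")
  expect_warning(hard_threshold(matrix(0, 3, 3,
    dimnames = list(letters[1:3], letters[1:3]))), "empty")
})

test_that("jointly isolated genes are pruned from both networks", {
  adj1 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  adj2 <- adj1
  adj1[1, 2] <- adj1[2, 1] <- 1           # c isolated in net1
  adj2[1, 2] <- adj2[2, 1] <- 1
  adj2[2, 3] <- adj2[3, 2] <- 1           # c connected in net2; d isolated in both
  suppressMessages(pr <- prune_isolated(adj_network(adj1), adj_network(adj2)))
  expect_setequal(pr$net_a$gene_ids, c("a", "b", "c"))
  expect_setequal(pr$net_b$gene_ids, c("a", "b", "c"))
  # no isolated genes -> identity
  pr2 <- prune_isolated(adj_network(adj2[1:3, 1:3]), adj_network(adj2[1:3, 1:3]))
  expect_equal(pr2$net_a$gene_ids, c("a", "b", "c"))
})

test_that("retained edges concentrate inside planted modules", {
  hits <- vapply(1:10, function(s) {
    cfg <- simulation_config(40, c(A = 30),
      module_spec = list(list(genes = 1:20, groups = "A", loading = 1)),
      noise_sd = 0.3)
    sim <- simulate_expression(cfg, seed = s)
    mi <- mi_matrix(sim$dataset)
    net <- hard_threshold(mrnetb(mi), q = 0.95)
    e <- coexpression_edges(net)
    if (!nrow(e)) return(NA_real_)
    mean(e$gene1 %in% sim$dataset$gene_ids[1:20] &
         e$gene2 %in% sim$dataset$gene_ids[1:20])
  }, numeric(1))
  expect_gte(mean(hits, na.rm = TRUE), 0.8)
})
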