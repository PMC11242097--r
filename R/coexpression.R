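#' Kraskov k-nearest-neighbour mutual information estimate
#'
#' Algorithm-1 estimator: with max-norm neighbourhoods in the joint space,
#' `MI = psi(k) + psi(N) - <psi(n_x + 1) + psi(n_y + 1)>` (nats), where
#' `n_x`, `n_y` count marginal neighbours strictly inside the distance to the
#' k-th joint neighbour. The estimator is undefined under heavy ties, so tied
#' values are broken with deterministic sub-noise jitter (uniform on
#' (0, 1e-10), seeded) before ranking; the raw estimate may be slightly
#' negative under the null.
#'
#' @param x,y equal-length numeric vectors, length > `k_nn`.
#' @param k_nn neighbour count (default 3).
#' @param jitter_seeds length-2 seeds for the tie-breaking jitter of `x` and
#'   `y` (only used when the vector has ties).
#' @return Mutual information estimate in nats.
#' @export
knn_mutual_information <- function(x, y, k_nn = 3, jitter_seeds = c(1, 2)) {
  n <- length(x)
  if (length(y) != n) stopf("x and y must have equal length")
  if (k_nn < 1 || n <= k_nn) stopf("need length > k_nn >= 1")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("constant vector: MI set to 0")
    return(0)
  }
  x <- jitter_ties(x, jitter_seeds[1])
  y <- jitter_ties(y, jitter_seeds[2])
  dx <- abs(outer(x, x, "-"))
  dy <- abs(outer(y, y, "-"))
  dz <- pmax(dx, dy)
  diag(dz) <- Inf
  eps <- apply(dz, 1, function(r) sort(r, partial = k_nn)[k_nn])
  nx <- rowSums(dx < eps) - 1L  # self always counted (distance 0)
  ny <- rowSums(dy < eps) - 1L
  digamma(k_nn) + digamma(n) - mean(digamma(nx + 1L) + digamma(ny + 1L))
}

jitter_ties <- function(v, seed) {
  if (!anyDuplicated(v)) return(v)
  with_seed(seed, v + stats::runif(length(v), 0, 1e-10))
}

#' Pairwise mutual-information matrix for one condition
#'
#' Evaluates the Kraskov estimator for every unordered gene pair of the
#' samples in `ds` (callers subset to one condition first). No Fisher-z
#' normalization is applied. Negative estimates are clamped to 0; the
#' diagonal is 0. Jitter seeds derive from gene indices so the matrix is
#' exactly symmetric and deterministic.
#'
#' @param ds an [expression_dataset()] holding the condition's samples.
#' @param genes gene ids to include (default all).
#' @param k_nn neighbour count (default 3).
#' @return Object of class `mi_matrix`: list with `mi` (symmetric named
#'   matrix, nats), `gene_ids`, `k_nn`.
#' @export
mi_matrix <- function(ds, genes = ds$gene_ids, k_nn = 3) {
  if (length(ds$sample_ids) < 3) stopf("need >= 3 samples in the condition")
  m <- ds$values[genes, , drop = FALSE]
  p <- length(genes)
  mi <- matrix(0, p, p, dimnames = list(genes, genes))
  if (p >= 2) {
    rows <- lapply(seq_len(p), function(i) jitter_ties(m[i, ], i))
    for (i in seq_len(p - 1)) for (j in (i + 1):p) {
      est <- knn_mutual_information(rows[[i]], rows[[j]], k_nn,
                                    jitter_seeds = c(i, j))
      mi[i, j] <- mi[j, i] <- max(est, 0)
    }
  }
  structure(list(mi = mi, gene_ids = genes, k_nn = k_nn), class = "mi_matrix")
}

#' MRNETB network inference
#'
#' Maximum-relevance / minimum-redundancy inference by backward elimination
#' with sequential replacement. For each target gene Y the predictor subset S
#' maximizes `J(S) = sum_i I(Xi;Y) - mean_{i<j in S} pairwise redundancy`
#' (the redundancy term is `(1/|S|) * sum_{i<j} I(Xi;Xj)`): backward
#' elimination walks the greedy removal path from the full predictor set and
#' keeps the best subset encountered, then sequential replacement applies
#' single-variable moves (swap one in for one out, drop one, add one) until
#' none improves J. Each selected
#' predictor scores its relevance minus its mean redundancy to the rest of
#' the final subset; unselected predictors score 0; the undirected weight is
#' the larger of the two directional scores, clamped at 0.
#'
#' @param mi a [mi_matrix()] (or plain symmetric nonnegative matrix).
#' @return Symmetric nonnegative weight matrix with zero diagonal.
#' @export
mrnetb <- function(mi) {
  M <- if (inherits(mi, "mi_matrix")) mi$mi else as.matrix(mi)
  p <- nrow(M)
  diag(M) <- 0
  if (p < 3) {
    msg("fewer than 3 genes: MRNETB degenerates to the MI values")
    return(M)
  }
  score <- matrix(0, p, p, dimnames = dimnames(M))
  for (t in seq_len(p)) {
    pred <- setdiff(seq_len(p), t)
    sel <- mrnetb_select(M[pred, pred, drop = FALSE], M[pred, t])
    s_idx <- which(sel$in_set)
    for (i in s_idx) {
      others <- setdiff(s_idx, i)
      r <- if (length(others)) mean(M[pred[i], pred[others]]) else 0
      score[pred[i], t] <- M[pred[i], t] - r
    }
  }
  w <- pmax(score, t(score))
  w[w < 0] <- 0
  diag(w) <- 0
  w
}

# Backward elimination + sequential replacement for one target.
# R: predictor-predictor redundancy matrix; u: relevance vector.
# The elimination phase walks the full greedy removal path from the complete
# predictor set down to a single predictor, keeping the best subset seen
# (stopping at the first non-improving removal can strand the search on a
# plateau at the full set). The replacement phase then applies the best of
# the single-variable moves (swap one in for one out, drop one, add one)
# until no move improves J.
mrnetb_select <- function(R, u, tol = 1e-12) {
  p <- length(u)
  cur <- seq_len(p)
  row_red <- rowSums(R)   # redundancy of each predictor to the current set
  Q <- sum(row_red) / 2   # sum of pairwise redundancies within the set
  Rel <- sum(u)
  s <- p
  best_S <- cur
  best_J <- Rel - if (s > 1) Q / s else 0
  while (s > 1) {
    j_rm <- (Rel - u[cur]) - (Q - row_red[cur]) / (s - 1)
    b <- which.max(j_rm)
    i <- cur[b]
    Rel <- Rel - u[i]; Q <- Q - row_red[i]
    row_red <- row_red - R[, i]
    cur <- cur[cur != i]; s <- s - 1
    if (j_rm[b] > best_J + tol) { best_J <- j_rm[b]; best_S <- cur }
  }
  # restart incremental state from the best subset on the path
  S <- best_S
  s <- length(S)
  row_red <- rowSums(R[, S, drop = FALSE])
  Q <- sum(row_red[S]) / 2
  Rel <- sum(u[S])
  repeat {
    cur_J <- Rel - if (s > 1) Q / s else 0
    best_move_J <- cur_J; move <- NULL
    out <- setdiff(seq_len(p), S)
    if (s > 1) {
      j_rm <- (Rel - u[S]) - (Q - row_red[S]) / (s - 1)
      b <- which.max(j_rm)
      if (j_rm[b] > best_move_J + tol) {
        best_move_J <- j_rm[b]; move <- list(drop = S[b])
      }
    }
    if (length(out)) {
      j_add <- (Rel + u[out]) - (Q + row_red[out]) / (s + 1)
      b <- which.max(j_add)
      if (j_add[b] > best_move_J + tol) {
        best_move_J <- j_add[b]; move <- list(add = out[b])
      }
      for (i in S) {
        red_new <- Q - row_red[i] + row_red[out] - R[out, i]
        j_sw <- (Rel - u[i] + u[out]) - red_new / s
        b <- which.max(j_sw)
        if (j_sw[b] > best_move_J + tol) {
          best_move_J <- j_sw[b]; move <- list(drop = i, add = out[b])
        }
      }
    }
    if (is.null(move)) break
    if (!is.null(move$drop)) {
      i <- move$drop
      Rel <- Rel - u[i]; Q <- Q - row_red[i]
      row_red <- row_red - R[, i]
      S <- S[S != i]; s <- s - 1
    }
    if (!is.null(move$add)) {
      o <- move$add
      Rel <- Rel + u[o]; Q <- Q + row_red[o]
      row_red <- row_red + R[, o]
      S <- c(S, o); s <- s + 1
    }
  }
  in_set <- logical(p)
  in_set[S] <- TRUE
  list(in_set = in_set, J = Rel - if (s > 1) Q / s else 0)
}

#' Quantile hard-thresholding of a weighted network
#'
#' Weights at or below the `q`-th quantile of the strictly positive
#' off-diagonal weights are set to zero; the binary adjacency is the nonzero
#' pattern. `q = 0` retains every positive-weight edge.
#'
#' @param weights symmetric nonnegative weight matrix (e.g. from [mrnetb()]).
#' @param q quantile in \[0, 1).
#' @return Object of class `coexpression_network`: list with `gene_ids`,
#'   `score` (thresholded weights), `adjacency` (0/1 matrix), `q`,
#'   `threshold`.
#' @export
hard_threshold <- function(weights, q = 0.95) {
  if (q < 0 || q >= 1) stopf("q must be in [0, 1)")
  w <- as.matrix(weights)
  diag(w) <- 0
  pos <- w[upper.tri(w)]
  pos <- pos[pos > 0]
  if (!length(pos)) {
    warning("all weights zero: empty network")
    thr <- 0
  } else thr <- if (q == 0) 0 else unname(stats::quantile(pos, q))
  out <- w
  out[out <= thr & upper.tri(out) | out <= thr & lower.tri(out)] <- 0
  adj <- (out > 0) * 1
  structure(list(gene_ids = rownames(w), score = out, adjacency = adj,
                 q = q, threshold = thr),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("coexpression_network: %d genes, %d edges (q = %g, thr = %.4g)\n",
              length(x$gene_ids), sum(x$adjacency[upper.tri(x$adjacency)]),
              x$q, x$threshold))
  invisible(x)
}

#' Remove genes unconnected in both of two networks
#'
#' Genes with degree zero in both networks are removed from both; a gene
#' connected in either network is kept in both.
#'
#' @param net_a,net_b [hard_threshold()] networks on the same gene universe.
#' @return List with pruned `net_a` and `net_b`.
#' @export
prune_isolated <- function(net_a, net_b) {
  if (!identical(net_a$gene_ids, net_b$gene_ids))
    stopf("networks must share the same gene universe")
  deg_a <- rowSums(net_a$adjacency)
  deg_b <- rowSums(net_b$adjacency)
  keep <- deg_a > 0 | deg_b > 0
  if (!all(keep)) msg("pruned %d genes unconnected in both networks", sum(!keep))
  subset_net <- function(net) {
    structure(list(gene_ids = net$gene_ids[keep],
                   score = net$score[keep, keep, drop = FALSE],
                   adjacency = net$adjacency[keep, keep, drop = FALSE],
                   q = net$q, threshold = net$threshold),
              class = "coexpression_network")
  }
  list(net_a = subset_net(net_a), net_b = subset_net(net_b))
}

#' Edge list of a co-expression network
#'
#' @param net a [hard_threshold()] network.
#' @return data.frame with columns gene1, gene2, score.
#' @export
coexpression_edges <- function(net) {
  idx <- which(net$adjacency == 1 & upper.tri(net$adjacency), arr.ind = TRUE)
  data.frame(gene1 = net$gene_ids[idx[, 1]], gene2 = net$gene_ids[idx[, 2]],
             score = net$score[idx], stringsAsFactors = FALSE)
}
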