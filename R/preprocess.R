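#' Quantile normalization
#'
#' Forces every sample (column) onto the common distribution given by the
#' across-sample mean of order statistics; within-column ranks are preserved
#' and tied values receive the mean of their tied reference values.
#' Idempotent: normalizing twice equals normalizing once.
#'
#' @param ds an [expression_dataset()].
#' @return A normalized [expression_dataset()].
#' @export
quantile_normalize <- function(ds) {
  m <- ds$values
  if (ncol(m) < 2) {
    warning("single sample: quantile normalization is the identity")
    return(ds)
  }
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    tmp <- numeric(nrow(m))
    tmp[order(m[, j])] <- ref
    # tied input values share the mean of their tied reference values
    out[, j] <- stats::ave(tmp, match(m[, j], m[, j]), FUN = mean)
  }
  expression_dataset(out, ds$sample_meta)
}

#' Per-gene batch mean-centering
#'
#' Shifts each batch's per-gene mean to the gene's grand mean — a simple
#' additive batch correction. An externally corrected matrix can be supplied
#' instead via [expression_dataset()].
#'
#' @param ds an [expression_dataset()].
#' @param batch_labels optional per-sample batch labels; defaults to the
#'   `batch` column of the sample sheet.
#' @return A corrected [expression_dataset()].
#' @export
batch_center <- function(ds, batch_labels = ds$sample_meta$batch) {
  if (is.null(batch_labels) || any(is.na(batch_labels)))
    stopf("every sample needs a batch label")
  batch_labels <- as.character(batch_labels)
  m <- ds$values
  grand <- rowMeans(m)
  for (b in unique(batch_labels)) {
    cols <- which(batch_labels == b)
    if (length(cols) == 1L) msg("batch '%s' has a single sample", b)
    m[, cols] <- m[, cols, drop = FALSE] - rowMeans(m[, cols, drop = FALSE]) + grand
  }
  expression_dataset(m, ds$sample_meta)
}

#' Most variable genes
#'
#' @param ds an [expression_dataset()].
#' @param k number of genes to return (1..n_genes).
#' @return Character vector of the `k` gene ids with largest across-sample
#'   variance; ties broken by input order.
#' @export
top_variable_genes <- function(ds, k) {
  if (k <= 0) stopf("k must be positive")
  if (k > length(ds$gene_ids)) stopf("k exceeds the number of genes")
  v <- apply(ds$values, 1, stats::var)
  ord <- order(-v, seq_along(v))  # stable: ties by input order
  ds$gene_ids[ord[seq_len(k)]]
}

#' Pairwise sample distances from leading log2 differences
#'
#' The distance between two samples is the root-mean-square of the `k_top`
#' largest absolute log2 expression differences between them — the leading
#' fold-change distance used for multidimensional scaling of array samples.
#'
#' @param ds an [expression_dataset()] (log2 scale).
#' @param k_top number of leading genes per pair (default 500, capped at the
#'   gene count).
#' @return An object of class `sample_distance_matrix`: list with `d`
#'   (symmetric matrix, zero diagonal), `sample_ids`, `k_top`.
#' @export
mds_distances <- function(ds, k_top = 500) {
  k_top <- min(k_top, length(ds$gene_ids))
  if (k_top < 1) stopf("k_top must be positive")
  n <- length(ds$sample_ids)
  d <- matrix(0, n, n, dimnames = list(ds$sample_ids, ds$sample_ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    diffs <- sort(abs(ds$values[, i] - ds$values[, j]), decreasing = TRUE)
    d[i, j] <- d[j, i] <- sqrt(mean(diffs[seq_len(k_top)]^2))
  }
  structure(list(d = d, sample_ids = ds$sample_ids, k_top = k_top),
            class = "sample_distance_matrix")
}

#' Classical (metric) multidimensional scaling
#'
#' Double-centered Gram-matrix eigendecomposition via [stats::cmdscale()];
#' dimensions with non-positive eigenvalues are dropped with a warning.
#'
#' @param dm a [mds_distances()] result (or a symmetric matrix).
#' @param n_dims requested embedding dimension.
#' @return Numeric matrix of sample coordinates (samples x dims).
#' @export
classical_mds <- function(dm, n_dims = 2) {
  if (n_dims < 1) stopf("n_dims must be >= 1")
  d <- if (inherits(dm, "sample_distance_matrix")) dm$d else as.matrix(dm)
  fit <- stats::cmdscale(stats::as.dist(d), k = min(n_dims, nrow(d) - 1),
                         eig = TRUE)
  pos <- sum(fit$eig > 1e-12)
  if (pos < n_dims)
    warning(sprintf("only %d positive-eigenvalue dimensions available", pos))
  coords <- fit$points[, seq_len(min(n_dims, max(pos, 1))), drop = FALSE]
  rownames(coords) <- rownames(d)
  coords
}

#' SVM-based sample regrouping
#'
#' Mirrors the staged-lymphoma relabelling step: linear support-vector
#' machines are trained on bootstrap resamples (stratified, with
#' replacement) of the training groups using the `k_top` most-variable
#' training genes, then used to predict held-out samples. A held-out sample
#' is reassigned to the majority predicted label when its frequency reaches
#' `threshold`, otherwise marked "excluded".
#'
#' @param ds an [expression_dataset()].
#' @param held_out_group group label whose samples are predicted.
#' @param n_bootstrap number of bootstrap models (> 0).
#' @param k_top training-feature count (most variable genes of the training
#'   data).
#' @param seed integer RNG seed.
#' @param threshold majority frequency required to assign a label.
#' @return An object of class `regrouping_report`: data.frame `assignments`
#'   (sample_id, final label) plus `frequencies` (samples x labels matrix of
#'   predicted-label frequencies, rows summing to 1).
#' @export
svm_regroup <- function(ds, held_out_group, n_bootstrap = 100, k_top = 500,
                        seed = 1, threshold = 0.75) {
  if (n_bootstrap <= 0) stopf("n_bootstrap must be positive")
  groups <- ds$sample_meta$group
  held_idx <- which(groups == held_out_group)
  if (!length(held_idx)) stopf("held_out_group '%s' is empty", held_out_group)
  train_idx <- which(groups != held_out_group)
  train_groups <- groups[train_idx]
  if (length(unique(train_groups)) < 2) stopf("need >= 2 training groups")
  feats <- top_variable_genes(subset_samples(ds, train_idx),
                              min(k_top, length(ds$gene_ids)))
  x_all <- t(ds$values[feats, , drop = FALSE])
  labels <- sort(unique(train_groups))
  counts <- matrix(0L, length(held_idx), length(labels),
                   dimnames = list(ds$sample_ids[held_idx], labels))
  with_seed(seed, {
    for (b in seq_len(n_bootstrap)) {
      repeat {
        boot <- unlist(lapply(split(train_idx, train_groups), function(ix)
          sample(ix, length(ix), replace = TRUE)))
        if (length(unique(groups[boot])) == length(labels)) break
        msg("bootstrap resample lost a group; redrawing")
      }
      fit <- e1071::svm(x_all[boot, , drop = FALSE],
                        factor(groups[boot], levels = labels),
                        kernel = "linear", scale = FALSE)
      pred <- stats::predict(fit, x_all[held_idx, , drop = FALSE])
      for (i in seq_along(held_idx))
        counts[i, as.character(pred[i])] <- counts[i, as.character(pred[i])] + 1L
    }
  })
  freq <- counts / n_bootstrap
  final <- apply(freq, 1, function(f) {
    top <- which.max(f)
    if (f[top] >= threshold) colnames(freq)[top] else "excluded"
  })
  structure(list(
    assignments = data.frame(sample_id = rownames(freq), label = unname(final),
                             stringsAsFactors = FALSE),
    frequencies = freq, held_out_group = held_out_group,
    n_bootstrap = n_bootstrap, threshold = threshold),
    class = "regrouping_report")
}

#' @export
print.regrouping_report <- function(x, ...) {
  cat(sprintf("regrouping_report: %d held-out '%s' samples, %d bootstrap models\n",
              nrow(x$assignments), x$held_out_group, x$n_bootstrap))
  print(x$assignments)
  invisible(x)
}
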