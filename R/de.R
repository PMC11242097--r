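#' Benjamini-Hochberg adjustment
#'
#' Validated step-up false-discovery-rate adjustment (running-minimum
#' enforced, capped at 1), delegating to [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
benjamini_hochberg <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0 | p > 1))
    stopf("p-values must be numeric in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Empirical-Bayes moderated two-group t-test
#'
#' Per gene, the pooled two-group variance s_g^2 (d_g = n1 + n2 - 2 df) is
#' shrunk towards a scaled-F prior whose hyperparameters (d0, s0^2) are
#' estimated by moment-matching the log sample variances (digamma/trigamma
#' equations). The moderated statistic is
#' t = logFC / (s_tilde * sqrt(1/n1 + 1/n2)) on d0 + d_g df, with
#' s_tilde^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g). logFC is group2 - group1.
#'
#' @param ds an [expression_dataset()] (log2 scale).
#' @param group1,group2 group labels with >= 2 samples each.
#' @param d0_override optional prior df override (use `Inf` for full
#'   shrinkage, `0` for the ordinary pooled t).
#' @return An object of class `de_result`: data.frame `table` ordered by raw
#'   p (gene_id, logFC, t, p, p_adj, direction) plus `contrast`, `d0`, `s0_2`.
#' @export
moderated_t_test <- function(ds, group1, group2, d0_override = NULL) {
  i1 <- which(ds$sample_meta$group == group1)
  i2 <- which(ds$sample_meta$group == group2)
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2 || n2 < 2) stopf("both groups need >= 2 samples")
  x1 <- ds$values[, i1, drop = FALSE]; x2 <- ds$values[, i2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  logfc <- m2 - m1
  ss1 <- rowSums((x1 - m1)^2); ss2 <- rowSums((x2 - m2)^2)
  dg <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / dg
  if (all(s2 <= 0)) stopf("all genes have zero variance; prior undefined")
  if (is.null(d0_override)) {
    hyp <- fit_f_prior(s2, dg)
  } else {
    hyp <- list(d0 = d0_override,
                s0_2 = if (is.finite(d0_override) && d0_override == 0)
                  NA_real_ else stats::median(s2[s2 > 0]))
  }
  d0 <- hyp$d0; s0_2 <- hyp$s0_2
  s_tilde2 <- if (is.infinite(d0)) rep(s0_2, length(s2))
              else if (d0 == 0) s2
              else (d0 * s0_2 + dg * s2) / (d0 + dg)
  se <- sqrt(s_tilde2 * (1 / n1 + 1 / n2))
  t_stat <- logfc / se
  df_total <- if (is.infinite(d0)) Inf else d0 + dg
  p <- 2 * stats::pt(-abs(t_stat), df = df_total)
  tab <- data.frame(gene_id = ds$gene_ids, logFC = logfc, t = t_stat, p = p,
                    p_adj = benjamini_hochberg(p),
                    direction = ifelse(logfc >= 0, "up", "down"),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$p, -abs(tab$logFC), tab$gene_id), ]
  rownames(tab) <- NULL
  structure(list(table = tab, contrast = paste0(group1, "_vs_", group2),
                 group1 = group1, group2 = group2, d0 = d0, s0_2 = s0_2,
                 df_residual = dg),
            class = "de_result")
}

# Moment-match log sample variances against the scaled-F prior:
# E[log s_g^2] and Var[log s_g^2] follow digamma/trigamma identities; d0
# solves trigamma(d0/2) = max(var(z) - trigamma(dg/2), 0) by Newton on the
# inverse trigamma, then s0^2 from the mean equation.
fit_f_prior <- function(s2, dg) {
  pos <- s2 > 0
  z <- log(s2[pos])
  ev <- stats::var(z)
  rhs <- ev - trigamma(dg / 2)
  if (!is.finite(rhs) || rhs <= 1e-8)
    return(list(d0 = Inf, s0_2 = exp(mean(z) - digamma(dg / 2) + log(dg / 2))))
  d0 <- 2 * inv_trigamma(rhs)
  s0_2 <- exp(mean(z) - digamma(dg / 2) + digamma(d0 / 2) +
                log(dg / d0))
  list(d0 = d0, s0_2 = s0_2)
}

# Newton inversion of trigamma (monotone decreasing on (0, Inf)).
inv_trigamma <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif) < 1e-10 * x) break
  }
  x
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("de_result %s: %d genes, %d at adjusted p < 0.05 (d0 = %.3g)\n",
              x$contrast, nrow(x$table), sum(x$table$p_adj < 0.05), x$d0))
  invisible(x)
}

#' Top differentially expressed genes
#'
#' Genes with adjusted (or raw) p below `alpha`, ranked by raw p ascending
#' (ties by |logFC| descending, then gene id), truncated to `n`. If fewer
#' than `n` genes pass, all passing genes are returned — e.g. a contrast with
#' only 27 significant genes yields a 27-gene list at `n = 100`.
#'
#' @param de a [moderated_t_test()] result.
#' @param n maximum number of genes (>= 1).
#' @param alpha significance threshold (default 0.05 on adjusted p).
#' @param use_adjusted use adjusted p (default) or raw p for the cutoff.
#' @return data.frame with columns gene_id, logFC, p, p_adj, direction.
#' @export
top_degs <- function(de, n = 100, alpha = 0.05, use_adjusted = TRUE) {
  if (n < 1) stopf("n must be >= 1")
  tab <- de$table
  keep <- if (use_adjusted) tab$p_adj < alpha else tab$p < alpha
  tab <- tab[keep, , drop = FALSE]
  if (!nrow(tab)) {
    warning(sprintf("no significant genes in %s at alpha = %g", de$contrast, alpha))
    return(tab[, c("gene_id", "logFC", "p", "p_adj", "direction")])
  }
  tab <- tab[order(tab$p, -abs(tab$logFC), tab$gene_id), , drop = FALSE]
  tab <- tab[seq_len(min(n, nrow(tab))), c("gene_id", "logFC", "p", "p_adj",
                                           "direction")]
  rownames(tab) <- NULL
  tab
}

#' Write a differential-expression table as TSV
#'
#' @param de a [moderated_t_test()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_de <- function(de, path) {
  utils::write.table(de$table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
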