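#' Expression dataset container
#'
#' Bundles a genes x samples matrix of log2-scale intensities with per-sample
#' metadata (group and optional batch labels). All pipeline stages consume and
#' produce this type.
#'
#' @param values numeric matrix, genes in rows, samples in columns. Row and
#'   column names supply gene and sample identifiers unless given explicitly.
#' @param sample_meta data.frame with columns `sample_id`, `group` and
#'   optionally `batch`, one row per sample, in any order.
#' @param gene_ids,sample_ids optional identifier vectors overriding dimnames.
#'
#' @return An object of class `expression_dataset` with elements `values`
#'   (named matrix), `gene_ids`, `sample_ids` and `sample_meta` (rows aligned
#'   with the matrix columns).
#' @export
expression_dataset <- function(values, sample_meta, gene_ids = rownames(values),
                               sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(sample_ids))
    stopf("gene and sample identifiers are required")
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(gene_ids)) stopf("duplicate gene ids: %s",
    paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids)) stopf("duplicate sample ids: %s",
    paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (nrow(values) != length(gene_ids) || ncol(values) != length(sample_ids))
    stopf("matrix dimensions do not match identifier lengths")
  if (!all(is.finite(values)))
    stopf("expression values must be finite (missing values rejected)")
  sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(sample_meta)))
    stopf("sample_meta needs columns sample_id and group")
  missing <- setdiff(sample_ids, sample_meta$sample_id)
  if (length(missing))
    stopf("samples absent from sample sheet: %s", paste(missing, collapse = ", "))
  sample_meta <- sample_meta[match(sample_ids, sample_meta$sample_id), , drop = FALSE]
  rownames(sample_meta) <- NULL
  if (any(is.na(sample_meta$group) | sample_meta$group == ""))
    stopf("every sample needs a group label")
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(values = values, gene_ids = gene_ids, sample_ids = sample_ids,
                 sample_meta = sample_meta),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d genes x %d samples\n",
              length(x$gene_ids), length(x$sample_ids)))
  cat("groups:", paste(sprintf("%s(%d)", names(table(x$sample_meta$group)),
                               table(x$sample_meta$group)), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

# Subset samples of a dataset, keeping metadata aligned.
subset_samples <- function(ds, keep) {
  idx <- if (is.character(keep)) match(keep, ds$sample_ids) else keep
  expression_dataset(ds$values[, idx, drop = FALSE],
                     ds$sample_meta[idx, , drop = FALSE])
}

# Samples belonging to one group.
group_samples <- function(ds, group) {
  ds$sample_ids[ds$sample_meta$group == group]
}

read_tsv_raw <- function(path, header = TRUE) {
  utils::read.delim(path, header = header, sep = "\t", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    quote = "", na.strings = c("NA", ""))
}

#' Read an expression matrix and sample sheet
#'
#' The matrix is a TSV with a header of sample ids and gene ids in the first
#' column; the sample sheet is a TSV with columns `sample_id`, `group` and
#' optionally `batch`. Lines starting with `#` are ignored.
#'
#' @param matrix_path path to the expression TSV.
#' @param sample_sheet_path path to the sample sheet TSV.
#' @param drop_missing if `TRUE`, genes with any missing value are dropped
#'   (with a message); the default rejects missing values.
#' @return An [expression_dataset()].
#' @export
read_expression <- function(matrix_path, sample_sheet_path, drop_missing = FALSE) {
  tab <- read_tsv_raw(matrix_path)
  if (ncol(tab) < 2) stopf("expression matrix needs gene ids plus >=1 sample")
  gene_ids <- as.character(tab[[1]])
  vals <- tab[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad))
        stopf("non-numeric value '%s' at gene %s, sample %s",
              v[bad[1]], gene_ids[bad[1]], names(vals)[j])
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- gene_ids
  if (anyNA(m)) {
    if (drop_missing) {
      keep <- stats::complete.cases(m)
      msg("dropped %d genes with missing values", sum(!keep))
      m <- m[keep, , drop = FALSE]
      gene_ids <- gene_ids[keep]
    } else stopf("missing expression values (set drop_missing = TRUE to drop genes)")
  }
  sheet <- read_tsv_raw(sample_sheet_path)
  expression_dataset(m, sheet)
}

#' Write an expression dataset
#'
#' Writes the matrix TSV and (optionally) the sample sheet alongside it.
#'
#' @param ds an [expression_dataset()].
#' @param matrix_path output TSV path.
#' @param sample_sheet_path optional output path for the sample sheet.
#' @return `matrix_path`, invisibly.
#' @export
write_expression <- function(ds, matrix_path, sample_sheet_path = NULL) {
  df <- data.frame(gene_id = ds$gene_ids, ds$values, check.names = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sample_sheet_path))
    utils::write.table(ds$sample_meta, sample_sheet_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(matrix_path)
}
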