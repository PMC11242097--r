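#' Read a gene-set collection in GMT format
#'
#' One set per line: name TAB description TAB member gene ids. Duplicate
#' members within a set are collapsed (logged).
#'
#' @param path GMT file path.
#' @return A named list of class `gene_set_collection`; each element holds
#'   `description` and `genes` (unique character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stopf("empty GMT file: %s", path)
  sets <- list()
  n_dup <- 0L
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stopf("GMT line %d has %d fields (need >= 3)", i, length(parts))
    name <- parts[1]
    if (name %in% names(sets)) stopf("duplicate set name '%s' at line %d", name, i)
    members <- parts[-(1:2)]
    members <- members[nzchar(members)]
    if (!length(members)) stopf("GMT line %d has no members", i)
    n_dup <- n_dup + (length(members) - length(unique(members)))
    sets[[name]] <- list(description = parts[2], genes = unique(members))
  }
  if (n_dup > 0) msg("collapsed %d duplicate set members", n_dup)
  structure(sets, class = "gene_set_collection")
}

#' Write a gene-set collection in GMT format
#'
#' @param sets a `gene_set_collection` (or compatible named list).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    s <- sets[[nm]]
    paste(c(nm, s$description, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, median size %g\n", length(x),
              stats::median(vapply(x, function(s) length(s$genes), numeric(1)))))
  invisible(x)
}
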