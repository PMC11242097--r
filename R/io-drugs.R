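INTERACTION_CATEGORIES <- c("target", "carrier", "transporter", "enzyme")

# Action vocabularies for the direction-compatibility filter. The two sets
# are configurable in action_compatible(); these defaults always contain the
# canonical terms (activator/agonist/partial agonist; inhibitor/antagonist).
ENHANCING_ACTIONS <- c("activator", "agonist", "partial agonist",
                       "stimulator", "inducer", "potentiator")
SUPPRESSING_ACTIONS <- c("inhibitor", "antagonist", "blocker", "suppressor",
                         "negative allosteric modulator", "antisense")

#' Drug catalog container
#'
#' A validated catalog of drugs (id, name, molecule type, approval groups,
#' indication tags) and drug-gene interactions (category from the
#' target/carrier/transporter/enzyme vocabulary, plus free action terms such
#' as "inhibitor" or "agonist"; empty actions mean unspecified).
#'
#' @param drugs data.frame with columns `drug_id`, `name`, `molecule_type`
#'   (`small_molecule` or `biotech`), `groups` (semicolon-separated),
#'   `indication_tags` (semicolon-separated, may be empty).
#' @param interactions data.frame with columns `drug_id`, `gene_id`,
#'   `category`, `actions` (semicolon-separated, may be empty).
#' @return An object of class `drug_catalog`.
#' @export
drug_catalog <- function(drugs, interactions) {
  drugs <- as.data.frame(drugs, stringsAsFactors = FALSE)
  interactions <- as.data.frame(interactions, stringsAsFactors = FALSE)
  need_d <- c("drug_id", "name", "molecule_type", "groups", "indication_tags")
  need_i <- c("drug_id", "gene_id", "category", "actions")
  if (!all(need_d %in% names(drugs)))
    stopf("drugs table needs columns: %s", paste(need_d, collapse = ", "))
  if (!all(need_i %in% names(interactions)))
    stopf("interactions table needs columns: %s", paste(need_i, collapse = ", "))
  if (anyDuplicated(drugs$drug_id)) stopf("duplicate drug ids")
  bad_type <- setdiff(unique(drugs$molecule_type), c("small_molecule", "biotech"))
  if (length(bad_type)) stopf("unknown molecule_type: %s", paste(bad_type, collapse = ", "))
  unknown <- setdiff(interactions$drug_id, drugs$drug_id)
  if (length(unknown))
    stopf("interactions reference unknown drug ids: %s", paste(unknown, collapse = ", "))
  bad_cat <- setdiff(unique(interactions$category), INTERACTION_CATEGORIES)
  if (length(bad_cat))
    stopf("interaction category outside {%s}: %s",
          paste(INTERACTION_CATEGORIES, collapse = ", "), paste(bad_cat, collapse = ", "))
  interactions$actions[is.na(interactions$actions)] <- ""
  drugs$indication_tags[is.na(drugs$indication_tags)] <- ""
  known <- c(ENHANCING_ACTIONS, SUPPRESSING_ACTIONS,
             "binder", "substrate", "ligand", "modulator", "cofactor")
  seen <- unique(unlist(split_terms(interactions$actions)))
  novel <- setdiff(seen, known)
  if (length(novel)) msg("retained unknown action terms: %s", paste(novel, collapse = ", "))
  rownames(drugs) <- NULL; rownames(interactions) <- NULL
  structure(list(drugs = drugs, interactions = interactions), class = "drug_catalog")
}

split_terms <- function(x) {
  out <- strsplit(as.character(x), ";", fixed = TRUE)
  lapply(out, function(v) trimws(v[nzchar(trimws(v))]))
}

#' Read a drug catalog from two TSV files
#'
#' @param drugs_path TSV with columns `drug_id`, `name`, `molecule_type`,
#'   `groups`, `indication_tags`.
#' @param interactions_path TSV with columns `drug_id`, `gene_id`,
#'   `category`, `actions` (semicolon-separated list, possibly empty).
#' @return A [drug_catalog()].
#' @export
read_drug_catalog <- function(drugs_path, interactions_path) {
  drug_catalog(read_tsv_raw(drugs_path), read_tsv_raw(interactions_path))
}

#' Write a drug catalog to two TSV files
#'
#' @param catalog a [drug_catalog()].
#' @param drugs_path,interactions_path output TSV paths.
#' @return `drugs_path`, invisibly.
#' @export
write_drug_catalog <- function(catalog, drugs_path, interactions_path) {
  utils::write.table(catalog$drugs, drugs_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(catalog$interactions, interactions_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(drugs_path)
}

#' @export
print.drug_catalog <- function(x, ...) {
  cat(sprintf("drug_catalog: %d drugs, %d interactions (%d of type target)\n",
              nrow(x$drugs), nrow(x$interactions),
              sum(x$interactions$category == "target")))
  invisible(x)
}
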