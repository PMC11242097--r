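#' Direction-compatibility of a drug action
#'
#' A drug-gene pair is excluded when any (or, optionally, every) of its
#' action terms pushes the gene the wrong way: enhancing actions
#' (activator, agonist, partial agonist, ...) are incompatible with
#' up-regulated genes; suppressing actions (inhibitor, antagonist, ...) with
#' down-regulated genes. Pairs with no stated action are kept.
#'
#' @param direction `"up"` or `"down"` (the gene's fold-change direction).
#' @param actions character vector of action terms (may be empty).
#' @param enhancing,suppressing configurable vocabularies; the defaults
#'   always contain the canonical terms.
#' @param mode `"any"` (default: exclude if any action is incompatible) or
#'   `"all"` (exclude only if all actions are incompatible).
#' @return `"keep"` or `"exclude"`.
#' @export
action_compatible <- function(direction, actions,
                              enhancing = ENHANCING_ACTIONS,
                              suppressing = SUPPRESSING_ACTIONS,
                              mode = c("any", "all")) {
  mode <- match.arg(mode)
  if (!direction %in% c("up", "down")) stopf("direction must be 'up' or 'down'")
  actions <- actions[nzchar(actions)]
  if (!length(actions)) return("keep")
  bad_vocab <- if (direction == "up") enhancing else suppressing
  incompatible <- tolower(actions) %in% tolower(bad_vocab)
  hit <- if (mode == "any") any(incompatible) else all(incompatible)
  if (hit) "exclude" else "keep"
}

#' Propose drugs for one contrast's top DEGs
#'
#' Retains (drug, gene) pairs where the interaction category is "target",
#' the drug is approved (unless `approved_only = FALSE`), the gene is in the
#' contrast's top-DEG list, and the action passes [action_compatible()].
#'
#' @param catalog a [drug_catalog()].
#' @param degs data.frame with columns `gene_id` and `direction` (from
#'   [top_degs()]).
#' @param approved_only keep only drugs whose groups include "approved".
#' @param mode passed to [action_compatible()].
#' @return Object of class `repurposing_result`: data.frame `pairs`
#'   (drug_id, name, molecule_type, gene_id, direction, actions), plus
#'   `bipartite` edge list (drug_id, gene_id).
#' @export
propose_drugs <- function(catalog, degs, approved_only = TRUE, mode = "any") {
  if (!nrow(catalog$drugs)) stopf("empty drug catalog")
  if (!nrow(degs)) stopf("empty DEG list")
  inter <- catalog$interactions
  inter <- inter[inter$category == "target", , drop = FALSE]
  drugs <- catalog$drugs
  if (approved_only) {
    ok <- vapply(split_terms(drugs$groups), function(g) "approved" %in% g,
                 logical(1))
    inter <- inter[inter$drug_id %in% drugs$drug_id[ok], , drop = FALSE]
  }
  inter <- inter[inter$gene_id %in% degs$gene_id, , drop = FALSE]
  if (nrow(inter)) {
    dir <- degs$direction[match(inter$gene_id, degs$gene_id)]
    acts <- split_terms(inter$actions)
    verdict <- vapply(seq_len(nrow(inter)), function(i)
      action_compatible(dir[i], acts[[i]], mode = mode), character(1))
    inter <- inter[verdict == "keep", , drop = FALSE]
    dir <- dir[verdict == "keep"]
  } else dir <- character(0)
  di <- match(inter$drug_id, drugs$drug_id)
  pairs <- data.frame(drug_id = inter$drug_id, name = drugs$name[di],
                      molecule_type = drugs$molecule_type[di],
                      gene_id = inter$gene_id, direction = dir,
                      actions = inter$actions, stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$drug_id, pairs$gene_id), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 bipartite = pairs[, c("drug_id", "gene_id")],
                 n_drugs = length(unique(pairs$drug_id))),
            class = "repurposing_result")
}

#' @export
print.repurposing_result <- function(x, ...) {
  cat(sprintf("repurposing_result: %d drug-gene pairs, %d distinct drugs\n",
              nrow(x$pairs), x$n_drugs))
  invisible(x)
}

#' Gene-to-contrast membership table
#'
#' For a bipartite drug-gene network spanning several contrasts, records in
#' which contrasts each proposed gene was significant (the donut-chart
#' semantics of per-gene contrast membership).
#'
#' @param deg_tables named list of [top_degs()] tables, one per contrast.
#' @return data.frame with columns gene_id and contrasts
#'   (semicolon-joined contrast names).
#' @export
gene_contrast_table <- function(deg_tables) {
  genes <- sort(unique(unlist(lapply(deg_tables, `[[`, "gene_id"))))
  member <- vapply(genes, function(g)
    paste(names(deg_tables)[vapply(deg_tables, function(t) g %in% t$gene_id,
                                   logical(1))], collapse = ";"),
    character(1))
  data.frame(gene_id = genes, contrasts = unname(member),
             stringsAsFactors = FALSE)
}
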