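#' Three-stage triage of significant repurposing candidates
#'
#' Stage 1 removes drugs carrying a contraindication whose condition term
#' matches the disease trait vocabulary (case-insensitive). Stage 2 removes
#' drugs whose target already has a known association score of at least
#' `assoc_cutoff` with any trait term (such targets are already under
#' investigation for the disease). Stage 3 flags, but does not remove,
#' targets whose tissue-enrichment category matches a disease-relevant
#' tissue — a prioritization hint, not a hard filter. A missing table skips
#' its stage with a warning.
#'
#' @param results Data frame of significant scoring results with at least
#'   `drug_id` and `target` columns (e.g. rows of [score_drug()] output).
#' @param association Data frame `target`, `trait`, `score` in `[0, 1]`,
#'   or `NULL`.
#' @param contraindications Data frame `drug_id`, `condition`, or `NULL`.
#' @param tissue_expression Data frame `gene`, `tissue`, `category`, or
#'   `NULL`.
#' @param trait_terms Character vector of disease trait terms.
#' @param relevant_tissues Character vector of disease-relevant tissue names
#'   for the stage-3 flag.
#' @param assoc_cutoff Inclusive association-score exclusion threshold.
#' @return The input rows with added columns `excluded_by`
#'   (`""`, `"contraindication"` or `"known_association"`) and `tissue_flag`;
#'   candidates are the rows with `excluded_by == ""`, sorted by `total`
#'   descending when a `total` column exists.
#' @export
triage <- function(results, association = NULL, contraindications = NULL,
                   tissue_expression = NULL, trait_terms,
                   relevant_tissues = character(0), assoc_cutoff = 0.2) {
  stopifnot(all(c("drug_id", "target") %in% names(results)))
  res <- results
  res$excluded_by <- ""
  res$tissue_flag <- FALSE
  terms <- tolower(trait_terms)

  if (is.null(contraindications)) {
    warning("no contraindication table supplied; stage 1 skipped")
  } else {
    ci <- contraindications[tolower(contraindications$condition) %in% terms, ,
                            drop = FALSE]
    hit <- res$drug_id %in% ci$drug_id
    res$excluded_by[hit] <- "contraindication"
  }

  if (is.null(association)) {
    warning("no target-trait association table supplied; stage 2 skipped")
  } else {
    assoc <- association[tolower(association$trait) %in% terms &
                           association$score >= assoc_cutoff, , drop = FALSE]
    hit <- res$target %in% assoc$target & res$excluded_by == ""
    res$excluded_by[hit] <- "known_association"
  }

  if (is.null(tissue_expression)) {
    warning("no tissue-expression table supplied; stage 3 skipped")
  } else {
    te <- tissue_expression[tolower(tissue_expression$tissue) %in%
                              tolower(relevant_tissues), , drop = FALSE]
    enriched <- te$gene[te$category %in% c("tissue enriched",
                                           "tissue_enriched", "enriched")]
    res$tissue_flag <- res$target %in% enriched
  }

  if ("total" %in% names(res)) {
    res <- res[order(res$excluded_by != "", -res$total), , drop = FALSE]
  }
  rownames(res) <- NULL
  res
}
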