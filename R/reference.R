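# Packaged reference table of previously reported candidates.

#' Previously reported high-confidence candidate reproduction genes
#'
#' A curated reference table of 21 candidate reproduction genes reported by
#' a full-scale run of the hybrid method on the human interactome (STRING
#' v9.1, 115 seed genes with experimental reproduction annotation), in the
#' shape the pipeline emits: per gene the path-count betweenness, the
#' permutation FDR, and the maximum interaction / alignment scores to the
#' seed set with the partner gene attaining each maximum. Useful for
#' checking the filter semantics (every row satisfies FDR < 0.05, alignment
#' score >= 90 and interaction score >= 900) and as a template for the
#' candidate-table shape.
#'
#' @return A tibble with columns `ensembl_id`, `gene_symbol`,
#'   `betweenness`, `permutation_fdr`, `interaction_score`,
#'   `interaction_partner`, `alignment_score`, `alignment_partner`, sorted
#'   by decreasing interaction score.
#' @export
reference_candidates <- function() {
  path <- system.file("extdata", "reference_candidates.tsv",
                      package = "pathprio", mustWork = TRUE)
  as_tibble(read.delim(path, stringsAsFactors = FALSE))
}
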