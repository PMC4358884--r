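# Interaction-confidence classifier: max combined score against seed and
# non-seed reference sets.

#' Maximum interaction confidence of genes against a reference set
#'
#' For each query gene, the maximum combined confidence score over its
#' network edges to members of `reference`, with the partner attaining it
#' (lexicographic tie-break). A gene with no edge to the reference gets
#' score 0: absence of an interaction record is absence of evidence, not the
#' 150 score floor.
#'
#' @param network A `ppi_network`.
#' @param genes Query gene identifiers (must be network nodes).
#' @param reference Reference set identifiers (non-empty).
#' @return A tibble (`gene`, `score`, `partner`), one row per query gene.
#' @export
interaction_v_max <- function(network, genes, reference) {
  stopifnot(inherits(network, "ppi_network"), length(reference) > 0L)
  genes <- unique(genes)
  miss <- setdiff(genes, igraph::V(network$graph)$name)
  if (length(miss) > 0L) {
    abort(paste0("gene(s) not in network: ",
                 paste(head(miss, 5L), collapse = ", ")))
  }
  e <- network$edges
  long <- bind_rows(
    e %>% select(gene = "protein_a", partner = "protein_b", "combined"),
    e %>% select(gene = "protein_b", partner = "protein_a", "combined")
  )
  best <- long %>%
    filter(.data$gene %in% genes, .data$partner %in% reference,
           .data$gene != .data$partner) %>%
    group_by(.data$gene) %>%
    arrange(desc(.data$combined), .data$partner, .by_group = TRUE) %>%
    slice(1L) %>%
    ungroup() %>%
    select("gene", score = "combined", "partner")
  tibble(gene = genes) %>%
    left_join(best, by = "gene") %>%
    mutate(score = ifelse(is.na(.data$score), 0, as.numeric(.data$score)))
}

#' Interaction-based candidate classification
#'
#' A query gene is called a candidate when its maximum combined interaction
#' score to the positive set `s_r` strictly exceeds its maximum to the
#' unlabeled set `s_nr` (ties are not candidates). By default `s_nr` is
#' every network protein outside `s_r`.
#'
#' @param network A `ppi_network`.
#' @param genes Query gene identifiers.
#' @param s_r Positive (seed) set.
#' @param s_nr Unlabeled set; default all other network nodes. Must be
#'   disjoint from `s_r`.
#' @return A verdict tibble (`gene`, `v_r`, `argmax_r`, `v_nr`, `argmax_nr`,
#'   `is_candidate`).
#' @export
interaction_classify <- function(network, genes, s_r, s_nr = NULL) {
  if (is.null(s_nr)) s_nr <- setdiff(network_nodes(network), s_r)
  if (length(intersect(s_r, s_nr)) > 0L) {
    abort("s_r and s_nr must be disjoint")
  }
  vr <- interaction_v_max(network, genes, s_r)
  vnr <- interaction_v_max(network, genes, s_nr)
  tibble(
    gene = vr$gene,
    v_r = vr$score, argmax_r = vr$partner,
    v_nr = vnr$score, argmax_nr = vnr$partner,
    is_candidate = vr$score > vnr$score
  )
}
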