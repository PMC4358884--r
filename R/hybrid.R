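# The hybrid prioritization pipeline: graph stage -> alignment filter ->
# interaction filter.

#' Configuration for the hybrid pipeline
#'
#' @param fdr_threshold Permutation-FDR cut for the graph stage; genes are
#'   kept when strictly below it (default 0.05).
#' @param alignment_threshold Minimum alignment score to the seed set;
#'   candidates strictly below are excluded, so a score exactly at the
#'   threshold passes (default 90).
#' @param interaction_threshold Minimum combined interaction score to the
#'   seed set, same exclusion rule (default 900).
#' @param n_permutations Permutations for the FDR (default 500).
#' @param rng_seed Integer seed for the permutation draw.
#' @param path_mode Shortest-path mode, see [seed_shortest_paths()].
#' @return A `hybrid_config` list.
#' @export
hybrid_config <- function(fdr_threshold = 0.05, alignment_threshold = 90,
                          interaction_threshold = 900,
                          n_permutations = 500L, rng_seed = 1L,
                          path_mode = c("single", "all")) {
  stopifnot(fdr_threshold >= 0, alignment_threshold >= 0,
            interaction_threshold >= 0, n_permutations >= 1L)
  structure(
    list(fdr_threshold = fdr_threshold,
         alignment_threshold = alignment_threshold,
         interaction_threshold = interaction_threshold,
         n_permutations = as.integer(n_permutations),
         rng_seed = as.integer(rng_seed),
         path_mode = match.arg(path_mode)),
    class = "hybrid_config"
  )
}

#' Keep rows whose alignment score reaches a threshold
#'
#' Implements the hybrid pipeline's second stage on any candidate table:
#' rows with a score strictly below the threshold are excluded, so a score
#' exactly at the threshold is retained.
#'
#' @param candidates A tibble with an alignment-score column.
#' @param threshold Minimum retained score (default 90).
#' @param column Score column name (default `"alignment_score"`).
#' @return The filtered tibble.
#' @export
alignment_filter <- function(candidates, threshold = 90,
                             column = "alignment_score") {
  stopifnot(column %in% names(candidates))
  candidates[!(candidates[[column]] < threshold), , drop = FALSE]
}

#' Keep rows whose interaction score reaches a threshold
#'
#' The hybrid pipeline's third stage: rows with a combined interaction score
#' strictly below the threshold are excluded.
#'
#' @param candidates A tibble with an interaction-score column.
#' @param threshold Minimum retained score (default 900).
#' @param column Score column name (default `"interaction_score"`).
#' @return The filtered tibble.
#' @export
interaction_filter <- function(candidates, threshold = 900,
                               column = "interaction_score") {
  stopifnot(column %in% names(candidates))
  candidates[!(candidates[[column]] < threshold), , drop = FALSE]
}

#' Run the hybrid prioritization pipeline
#'
#' Stage I (graph): seed-pair shortest paths on the weighted network,
#' path-count betweenness, selection of shortest-path genes, permutation
#' FDR, and the strict `fdr < fdr_threshold` cut. Stage II (similarity):
#' for each surviving gene, the maximum alignment score to the seed set;
#' genes scoring below `alignment_threshold` are excluded. Stage III
#' (interaction): the maximum combined interaction score to the seed set;
#' genes below `interaction_threshold` are excluded. The final candidates
#' are reported sorted by decreasing interaction score.
#'
#' @param network A `ppi_network`.
#' @param seeds Character vector of seed identifiers.
#' @param scores Alignment score table (`id_a`, `id_b`, `score`), e.g. from
#'   [alignment_scores()] or [read_score_table()]. The alignment threshold
#'   applies to whatever score scale this table carries.
#' @param config A [hybrid_config()].
#' @return A `hybrid_result` with `$candidates` (tibble: `gene`,
#'   `betweenness`, `fdr`, `alignment_score`, `alignment_partner`,
#'   `interaction_score`, `interaction_partner`), `$stages` (the
#'   shortest-path-gene, FDR-filtered and alignment-filtered tables),
#'   `$paths` (the seed-pair path tibble) and `$config`.
#' @export
run_hybrid <- function(network, seeds, scores, config = hybrid_config()) {
  stopifnot(inherits(network, "ppi_network"),
            inherits(config, "hybrid_config"))
  seeds <- sort(unique(seeds))

  paths <- seed_shortest_paths(network, seeds, mode = config$path_mode)
  bt <- path_betweenness(paths, network)
  spg <- shortest_path_genes(bt, seeds)
  inform(sprintf("stage I: %d shortest-path gene(s)", nrow(spg)))

  fdr_tbl <- permutation_fdr(network, seeds, spg,
                             n_permutations = config$n_permutations,
                             rng_seed = config$rng_seed, betweenness = bt)
  stage1 <- filter_by_fdr(fdr_tbl, config$fdr_threshold)
  inform(sprintf("stage I: %d of %d gene(s) with FDR < %g",
                 nrow(stage1), nrow(spg), config$fdr_threshold))

  align <- v_max(scores, stage1$gene, seeds) %>%
    select("gene", alignment_score = "score", alignment_partner = "partner")
  stage1_aligned <- stage1 %>% left_join(align, by = "gene")
  stage2 <- alignment_filter(stage1_aligned, config$alignment_threshold)
  inform(sprintf("stage II: %d of %d gene(s) with alignment score >= %g",
                 nrow(stage2), nrow(stage1), config$alignment_threshold))

  inter <- if (nrow(stage2) > 0L) {
    interaction_v_max(network, stage2$gene, seeds) %>%
      select("gene", interaction_score = "score",
             interaction_partner = "partner")
  } else {
    tibble(gene = character(), interaction_score = numeric(),
           interaction_partner = character())
  }
  stage2_scored <- stage2 %>% left_join(inter, by = "gene")
  stage3 <- interaction_filter(stage2_scored, config$interaction_threshold)
  inform(sprintf("stage III: %d of %d gene(s) with interaction score >= %g",
                 nrow(stage3), nrow(stage2), config$interaction_threshold))

  candidates <- stage3 %>%
    select("gene", "betweenness", "fdr", "alignment_score",
           "alignment_partner", "interaction_score",
           "interaction_partner") %>%
    arrange(desc(.data$interaction_score), .data$gene)

  structure(
    list(candidates = candidates,
         stages = list(shortest_path = fdr_tbl,
                       fdr_filtered = stage1_aligned,
                       alignment_filtered = stage2_scored),
         paths = paths, seeds = seeds, config = config),
    class = "hybrid_result"
  )
}

#' @export
print.hybrid_result <- function(x, ...) {
  cat("<hybrid_result>\n")
  cat(sprintf("  seeds: %d | shortest-path genes: %d | FDR < %g: %d | ",
              length(x$seeds), nrow(x$stages$shortest_path),
              x$config$fdr_threshold, nrow(x$stages$fdr_filtered)))
  cat(sprintf("alignment >= %g: %d | interaction >= %g: %d\n",
              x$config$alignment_threshold,
              nrow(x$stages$alignment_filtered),
              x$config$interaction_threshold, nrow(x$candidates)))
  print(x$candidates, n = 10)
  invisible(x)
}
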