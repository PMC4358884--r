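# Leave-one-out evaluation of the four prioritization methods.

graph_stage_candidates <- function(network, seeds, config) {
  paths <- seed_shortest_paths(network, seeds, mode = config$path_mode)
  bt <- path_betweenness(paths, network)
  spg <- shortest_path_genes(bt, seeds)
  if (nrow(spg) == 0L) return(character())
  fdr_tbl <- permutation_fdr(network, seeds, spg,
                             n_permutations = config$n_permutations,
                             rng_seed = config$rng_seed, betweenness = bt)
  filter_by_fdr(fdr_tbl, config$fdr_threshold)$gene
}

#' Leave-one-out (jackknife) evaluation of a prioritization method
#'
#' Each seed gene is held out in turn and the method is run on the remaining
#' seeds; the held-out gene counts as identified when it appears in the
#' method's candidate set. For the graph method that set is the
#' FDR-filtered shortest-path genes; for RWR the top-`k` non-seed genes by
#' stationary probability, with `k` defaulting to the size of the graph
#' method's candidate set on the same fold; for the similarity and
#' interaction classifiers, the strict `v_R > v_NR` verdict with the
#' remaining seeds as positive set.
#'
#' @param network A `ppi_network`.
#' @param seeds Character vector of seed identifiers (at least 3).
#' @param method One of `"graph"`, `"rwr"`, `"similarity"`,
#'   `"interaction"`.
#' @param scores Alignment score table; required for `"similarity"`.
#' @param config A [hybrid_config()] driving the graph stage (permutations,
#'   FDR threshold, path mode). Fold `f` uses `rng_seed + f` for its
#'   permutation draw.
#' @param k Fixed RWR candidate-list size; `NULL` (default) recomputes `k`
#'   per fold from the graph method.
#' @param restart,tol RWR parameters, see [run_rwr()].
#' @return A `jackknife_result` tibble (`seed`, `identified`) with
#'   attributes `method` and `identified_count`.
#' @export
jackknife_evaluate <- function(network, seeds,
                               method = c("graph", "rwr", "similarity",
                                          "interaction"),
                               scores = NULL, config = hybrid_config(),
                               k = NULL, restart = 0.7, tol = 1e-6) {
  method <- match.arg(method)
  stopifnot(inherits(network, "ppi_network"))
  seeds <- sort(unique(seeds))
  if (length(seeds) < 3L) abort("jackknife needs at least 3 seed genes")
  if (method == "similarity" && is.null(scores)) {
    abort("the similarity method needs an alignment score table")
  }
  universe <- network_nodes(network)

  identified <- vapply(seq_along(seeds), function(f) {
    g <- seeds[f]
    rest <- setdiff(seeds, g)
    fold_config <- config
    fold_config$rng_seed <- config$rng_seed + f
    switch(method,
      graph = g %in% graph_stage_candidates(network, rest, fold_config),
      rwr = {
        kk <- if (is.null(k)) {
          length(graph_stage_candidates(network, rest, fold_config))
        } else k
        if (kk == 0L) FALSE else {
          state <- run_rwr(network, rest, restart = restart, tol = tol)
          g %in% rank_candidates(state, rest, kk)$gene
        }
      },
      similarity = {
        s_nr <- setdiff(unique(c(scores$id_a, scores$id_b)), c(rest, g))
        similarity_classify(scores, g, rest, s_nr)$is_candidate
      },
      interaction = {
        s_nr <- setdiff(universe, c(rest, g))
        interaction_classify(network, g, rest, s_nr)$is_candidate
      }
    )
  }, logical(1))

  out <- tibble(seed = seeds, identified = identified)
  structure(out, class = c("jackknife_result", class(out)),
            method = method, identified_count = sum(identified))
}
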