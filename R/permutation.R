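# Permutation false-discovery rate for path-count betweenness.

# Inner-node counts over single (lexicographic tie-break) shortest paths
# between all pairs of `node_set`, tallied for `genes` only. Lighter than
# seed_shortest_paths(): no path tibble is built.
inner_counts <- function(graph, node_set, genes) {
  node_set <- sort(node_set)
  counts <- setNames(integer(length(genes)), genes)
  for (i in seq_len(length(node_set) - 1L)) {
    by_target <- co_minimal_paths(graph, node_set[i],
                                  node_set[(i + 1L):length(node_set)])
    for (paths in by_target) {
      p <- lex_min_path(paths)
      inner <- p[-c(1L, length(p))]
      hit <- inner[inner %in% genes]
      if (length(hit) > 0L) counts[hit] <- counts[hit] + 1L
    }
  }
  counts
}

#' Permutation FDR for shortest-path genes
#'
#' Assesses whether a gene's path-count betweenness is specific to the seed
#' set or would arise for random gene sets of the same size. Each permutation
#' draws `length(seeds)` distinct nodes uniformly from the network (re-drawn
#' if identical to the seed set), recomputes the seed-pair shortest paths and
#' the candidates' betweenness, and counts the permutations in which a
#' candidate's permuted betweenness is strictly larger than its actual one.
#' The permutation FDR is that exceedance count divided by the number of
#' permutations; genes that score high against random sets as well are not
#' specific to the seeds and are removed downstream.
#'
#' @param network A `ppi_network`.
#' @param seeds Character vector of seed identifiers.
#' @param candidates Candidate genes: the tibble from
#'   [shortest_path_genes()] or a character vector.
#' @param n_permutations Number of random sets (default 500).
#' @param rng_seed Integer seed making the draw reproducible.
#' @param betweenness Optional precomputed betweenness tibble from
#'   [path_betweenness()]; recomputed when `NULL`.
#' @param sampling `"uniform"` (default) draws nodes uniformly from the
#'   network; `"degree_matched"` draws each permuted node from the degree
#'   quintile of the corresponding seed.
#'
#' @return A tibble (`gene`, `betweenness`, `exceed_count`, `fdr`) sorted by
#'   increasing FDR then decreasing betweenness.
#' @export
permutation_fdr <- function(network, seeds, candidates,
                            n_permutations = 500L, rng_seed = 1L,
                            betweenness = NULL,
                            sampling = c("uniform", "degree_matched")) {
  sampling <- match.arg(sampling)
  stopifnot(inherits(network, "ppi_network"), n_permutations >= 1L)
  if (is.data.frame(candidates)) candidates <- candidates$gene
  candidates <- sort(unique(candidates))
  seeds <- sort(unique(seeds))
  g <- network$graph
  nodes <- igraph::V(g)$name
  if (length(nodes) < length(seeds)) {
    abort("network has fewer nodes than the seed set size")
  }
  if (is.null(betweenness)) {
    betweenness <- path_betweenness(seed_shortest_paths(network, seeds),
                                    network)
  }
  actual <- setNames(betweenness$betweenness, betweenness$gene)[candidates]

  if (sampling == "degree_matched") {
    deg <- igraph::degree(g)
    bin <- setNames(
      cut(rank(deg, ties.method = "first"), breaks = 5L, labels = FALSE),
      names(deg))
    by_bin <- split(nodes, bin[nodes])
    seed_bin <- as.character(bin[seeds])
  }

  exceed <- setNames(integer(length(candidates)), candidates)
  withr::with_seed(rng_seed, {
    for (b in seq_len(n_permutations)) {
      repeat {
        perm <- if (sampling == "uniform") {
          sample(nodes, length(seeds))
        } else {
          draw <- vapply(seed_bin, function(k) sample(by_bin[[k]], 1L),
                         character(1))
          unique(draw)
        }
        if (length(perm) == length(seeds) && !setequal(perm, seeds)) break
      }
      cnt <- inner_counts(g, perm, candidates)
      exceed <- exceed + (cnt > actual)
    }
  })

  tibble(
    gene = candidates,
    betweenness = as.integer(actual),
    exceed_count = as.integer(exceed),
    fdr = as.numeric(exceed) / n_permutations
  ) %>%
    arrange(.data$fdr, desc(.data$betweenness), .data$gene)
}

#' Keep genes whose permutation FDR is below a threshold
#'
#' The cut is strict: a gene is kept only when `fdr < threshold`.
#'
#' @param results Tibble from [permutation_fdr()].
#' @param threshold FDR cut (default 0.05).
#' @return The filtered tibble.
#' @export
filter_by_fdr <- function(results, threshold = 0.05) {
  results %>% filter(.data$fdr < threshold)
}

#' Write a shortest-path gene table as TSV
#'
#' Emits `gene`, `betweenness`, `exceed_count`, `fdr` sorted by FDR then
#' betweenness descending.
#'
#' @param results Tibble from [permutation_fdr()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fdr_table <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
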