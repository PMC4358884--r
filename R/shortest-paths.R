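# Seed-pair shortest paths and inner-node path-count betweenness.

# Lexicographically smallest of several node-name sequences (all co-minimal
# shortest paths of one pair). Sequences are compared element by element;
# a strict prefix precedes its extensions.
lex_min_path <- function(paths) {
  if (length(paths) == 1L) return(paths[[1L]])
  best <- paths[[1L]]
  for (p in paths[-1L]) {
    k <- min(length(p), length(best))
    cmp <- 0L
    for (i in seq_len(k)) {
      if (p[i] < best[i]) { cmp <- -1L; break }
      if (p[i] > best[i]) { cmp <- 1L; break }
    }
    if (cmp == -1L || (cmp == 0L && length(p) < length(best))) best <- p
  }
  best
}

# All minimum-weight paths from one source seed to each of several targets,
# as a list (one element per reachable target) of lists of name vectors.
co_minimal_paths <- function(graph, from, targets) {
  # igraph warns about unreachable targets; disconnection is handled (and
  # reported) by the callers
  res <- suppressWarnings(
    igraph::all_shortest_paths(graph, from = from, to = targets,
                               weights = igraph::E(graph)$weight))
  paths <- lapply(res$vpaths, function(v) igraph::V(graph)$name[as.integer(v)])
  ends <- vapply(paths, function(p) p[length(p)], character(1))
  split(paths, factor(ends, levels = unique(ends)))
}

#' Shortest paths between every pair of seed genes
#'
#' Runs Dijkstra's algorithm between every unordered pair of seed genes on
#' the weighted network (edge weight `1000 - combined`, so high-confidence
#' interactions are preferred). By default one path is reported per pair;
#' ties among equal-weight paths are broken by the lexicographically
#' smallest node sequence (read from the lexicographically smaller
#' endpoint), which makes the output deterministic. `mode = "all"` reports
#' every co-minimal path instead. Disconnected pairs are omitted with a
#' note.
#'
#' @param network A `ppi_network`.
#' @param seeds Character vector of seed identifiers (at least 2, all in the
#'   network).
#' @param mode `"single"` (default) or `"all"` co-minimal paths per pair.
#'
#' @return A tibble with one row per path: `from`, `to` (endpoints in
#'   lexicographic order), `total_weight`, `path` (list column of node
#'   sequences), `inner` (list column of inner nodes) and `n_inner`.
#' @export
seed_shortest_paths <- function(network, seeds, mode = c("single", "all")) {
  mode <- match.arg(mode)
  stopifnot(inherits(network, "ppi_network"))
  seeds <- sort(unique(seeds))
  if (length(seeds) < 2L) abort("need at least 2 seed genes")
  miss <- setdiff(seeds, igraph::V(network$graph)$name)
  if (length(miss) > 0L) {
    abort(paste0("seed gene(s) not in network: ",
                 paste(head(miss, 5L), collapse = ", ")))
  }
  g <- network$graph

  rows <- vector("list", length(seeds) - 1L)
  n_disconnected <- 0L
  for (i in seq_len(length(seeds) - 1L)) {
    from <- seeds[i]
    targets <- seeds[(i + 1L):length(seeds)]
    by_target <- co_minimal_paths(g, from, targets)
    n_disconnected <- n_disconnected +
      (length(targets) - length(by_target))
    if (length(by_target) == 0L) next
    pair_rows <- lapply(by_target, function(paths) {
      chosen <- if (mode == "single") list(lex_min_path(paths)) else
        paths[order(vapply(paths, paste, character(1), collapse = "\r"))]
      lapply(chosen, function(p) {
        to <- p[length(p)]
        w <- path_weight(g, p)
        list(from = from, to = to, total_weight = w, path = p,
             inner = p[-c(1L, length(p))])
      })
    })
    rows[[i]] <- unlist(pair_rows, recursive = FALSE, use.names = FALSE)
  }
  rows <- unlist(rows, recursive = FALSE, use.names = FALSE)
  if (n_disconnected > 0L) {
    inform(sprintf("%d disconnected seed pair(s) omitted", n_disconnected))
  }
  if (length(rows) == 0L) {
    return(tibble(from = character(), to = character(),
                  total_weight = integer(), path = list(), inner = list(),
                  n_inner = integer()))
  }
  tibble(
    from = vapply(rows, `[[`, character(1), "from"),
    to = vapply(rows, `[[`, character(1), "to"),
    total_weight = vapply(rows, `[[`, numeric(1), "total_weight"),
    path = lapply(rows, `[[`, "path"),
    inner = lapply(rows, `[[`, "inner"),
    n_inner = vapply(rows, function(r) length(r$inner), integer(1))
  ) %>%
    arrange(.data$from, .data$to)
}

path_weight <- function(graph, nodes) {
  if (length(nodes) < 2L) return(0)
  eids <- igraph::get_edge_ids(graph,
                               rbind(nodes[-length(nodes)], nodes[-1L]))
  sum(igraph::E(graph)$weight[eids])
}

#' Path-count betweenness of every network node
#'
#' Counts, for each node, the seed-pair shortest paths that contain it as an
#' inner node. This path-count betweenness (not the classical normalized
#' betweenness centrality) measures a protein's direct and indirect
#' association with the seed set: nodes bridging many seed pairs score high.
#'
#' @param paths Path tibble from [seed_shortest_paths()].
#' @param network A `ppi_network`; nodes on no path are reported with count
#'   0.
#' @return A tibble (`gene`, `betweenness`) over all network nodes, sorted
#'   by decreasing betweenness then gene.
#' @export
path_betweenness <- function(paths, network) {
  stopifnot(inherits(network, "ppi_network"))
  nodes <- network_nodes(network)
  inner <- unlist(paths$inner, use.names = FALSE)
  counts <- table(factor(inner, levels = nodes))
  tibble(gene = nodes, betweenness = as.integer(counts)) %>%
    arrange(desc(.data$betweenness), .data$gene)
}

#' Select shortest-path genes
#'
#' Non-seed genes with betweenness larger than zero, i.e. genes lying on at
#' least one seed-pair shortest path. Seed genes may accumulate inner-node
#' counts on other pairs' paths but are excluded here: the goal is novel
#' genes.
#'
#' @param betweenness Betweenness tibble from [path_betweenness()].
#' @param seeds Character vector of seed identifiers.
#' @return The filtered betweenness tibble.
#' @export
shortest_path_genes <- function(betweenness, seeds) {
  betweenness %>%
    filter(.data$betweenness > 0L, !.data$gene %in% seeds)
}
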