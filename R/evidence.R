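# Experimental-evidence statistics for the interactions on candidate-bearing
# seed-pair shortest paths.

#' Summarise experimental support among a set of interactions
#'
#' @param n_experimental Number of experimentally supported interactions.
#' @param n_total Total number of interactions.
#' @return A one-row tibble (`n_total`, `n_experimental`, `fraction`,
#'   `percentage`); `fraction` is `NA` when `n_total` is 0.
#' @export
path_evidence_summary <- function(n_experimental, n_total) {
  stopifnot(n_experimental >= 0, n_total >= 0, n_experimental <= n_total)
  frac <- if (n_total == 0L) NA_real_ else n_experimental / n_total
  tibble(n_total = as.integer(n_total),
         n_experimental = as.integer(n_experimental),
         fraction = frac, percentage = 100 * frac)
}

#' Experimental-evidence statistics of candidate-bearing paths
#'
#' Selects the seed-pair shortest paths that contain at least one candidate
#' gene as an inner node, takes the union of the interactions (edges) along
#' them, and reports how many carry experimental evidence. A high
#' experimental fraction relative to the network-wide baseline indicates
#' that the paths feeding the candidates rest on reliable interactions.
#'
#' @param network A `ppi_network`.
#' @param paths Path tibble from [seed_shortest_paths()].
#' @param candidates Candidate genes: character vector or a tibble with a
#'   `gene` column (non-empty).
#' @return A `path_evidence` object: `$edges` (tibble `protein_a`,
#'   `protein_b`, `combined`, `experimental_flag`), `$summary` (see
#'   [path_evidence_summary()], plus `n_paths`). When no path qualifies the
#'   summary has `n_total = 0` and a missing fraction.
#' @export
path_evidence_stats <- function(network, paths, candidates) {
  stopifnot(inherits(network, "ppi_network"))
  if (is.data.frame(candidates)) candidates <- candidates$gene
  if (length(candidates) == 0L) abort("candidates must be non-empty")

  qualifies <- vapply(paths$inner, function(v) any(v %in% candidates),
                      logical(1))
  qual_paths <- paths$path[qualifies]
  if (length(qual_paths) == 0L) {
    edges <- network$edges[0, c("protein_a", "protein_b", "combined",
                                "experimental_flag")]
    summary <- path_evidence_summary(0L, 0L)
    summary$n_paths <- 0L
    return(structure(list(edges = edges, summary = summary),
                     class = "path_evidence"))
  }

  edge_pairs <- lapply(qual_paths, function(p) {
    tibble(protein_a = pmin(p[-length(p)], p[-1L]),
           protein_b = pmax(p[-length(p)], p[-1L]))
  }) %>%
    bind_rows() %>%
    distinct()
  edges <- edge_pairs %>%
    left_join(network$edges %>%
                select("protein_a", "protein_b", "combined",
                       "experimental_flag"),
              by = c("protein_a", "protein_b")) %>%
    arrange(.data$protein_a, .data$protein_b)

  summary <- path_evidence_summary(sum(edges$experimental_flag), nrow(edges))
  summary$n_paths <- sum(qualifies)
  structure(list(edges = edges, summary = summary),
            class = "path_evidence")
}

#' @export
print.path_evidence <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<path_evidence> %d path(s), %d interaction(s), %d experimental",
              s$n_paths, s$n_total, s$n_experimental))
  if (!is.na(s$fraction)) cat(sprintf(" (%.2f%%)", s$percentage))
  cat("\n")
  invisible(x)
}
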