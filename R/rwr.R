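# Random walk with restart comparator.

#' Column-stochastic transition matrix of a network
#'
#' Column-normalizes the adjacency matrix. By default adjacency is binary
#' (edge presence); `weighted = TRUE` uses the combined confidence scores
#' instead. Zero-degree nodes get a self-loop column so that every column
#' sums to 1 and probability mass is conserved.
#'
#' @param network A `ppi_network`.
#' @param weighted Use combined scores as edge weights (default `FALSE`).
#' @return A sparse column-stochastic `dgCMatrix` with node names as
#'   dimnames.
#' @export
transition_matrix <- function(network, weighted = FALSE) {
  stopifnot(inherits(network, "ppi_network"))
  A <- igraph::as_adjacency_matrix(
    network$graph, attr = if (weighted) "combined" else NULL, sparse = TRUE)
  A <- methods::as(A, "dMatrix")
  cs <- Matrix::colSums(A)
  dangling <- which(cs == 0)
  if (length(dangling) > 0L) {
    A[cbind(dangling, dangling)] <- 1
    cs[dangling] <- 1
  }
  out <- A %*% Matrix::Diagonal(x = 1 / cs)
  dimnames(out) <- dimnames(A)
  out
}

#' Random walk with restart from a seed set
#'
#' Iterates `P_{t+1} = (1 - r) A' P_t + r P_0` where `A'` is the
#' column-stochastic transition matrix and `P_0` puts mass `1/m` on each of
#' the `m` seed genes, until the L1 difference between successive states
#' falls below `tol`. The stationary probability of each protein measures
#' its proximity to the seed set under a walker that restarts at the seeds
#' with probability `r` at every step.
#'
#' @param network A `ppi_network`, or a column-stochastic transition matrix
#'   from [transition_matrix()].
#' @param seeds Character vector of seed identifiers.
#' @param restart Restart probability `r` in (0, 1\] (default 0.7).
#' @param tol Convergence tolerance on the L1 difference (default 1e-6).
#' @param max_iter Iteration cap (default 10000); reaching it returns the
#'   current state with a warning and `converged = FALSE`.
#' @param weighted Passed to [transition_matrix()] when `network` is a
#'   `ppi_network`.
#'
#' @return An `rwr_result`: a tibble (`gene`, `probability`) sorted by
#'   decreasing probability, with attributes `iterations`, `converged`,
#'   `restart` and `seeds`.
#' @export
run_rwr <- function(network, seeds, restart = 0.7, tol = 1e-6,
                    max_iter = 10000L, weighted = FALSE) {
  stopifnot(restart > 0, restart <= 1, tol > 0, max_iter >= 1L)
  A <- if (inherits(network, "ppi_network")) {
    transition_matrix(network, weighted = weighted)
  } else network
  nodes <- colnames(A)
  seeds <- unique(seeds)
  if (length(seeds) == 0L) abort("need at least one seed gene")
  if (!all(seeds %in% nodes)) {
    abort(paste0("seed gene(s) not in network: ",
                 paste(head(setdiff(seeds, nodes), 5L), collapse = ", ")))
  }
  p0 <- setNames(numeric(length(nodes)), nodes)
  p0[seeds] <- 1 / length(seeds)
  p <- p0
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    p_new <- as.numeric((1 - restart) * (A %*% p)) + restart * p0
    delta <- sum(abs(p_new - p))
    p <- setNames(p_new, nodes)
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(sprintf("RWR did not converge within %d iterations", max_iter))
  }
  out <- tibble(gene = nodes, probability = as.numeric(p)) %>%
    arrange(desc(.data$probability), .data$gene)
  structure(out, class = c("rwr_result", class(out)),
            iterations = iter, converged = converged, restart = restart,
            seeds = sort(seeds))
}

#' Rank non-seed genes by RWR probability
#'
#' Sorts non-seed nodes by decreasing stationary probability (ties broken
#' lexicographically) and keeps the top `k`. Asking for more genes than
#' exist returns all of them with a warning.
#'
#' @param state An `rwr_result` from [run_rwr()].
#' @param seeds Character vector of seed identifiers to exclude.
#' @param k Number of candidates to keep.
#' @return A tibble (`gene`, `probability`, `rank`).
#' @export
rank_candidates <- function(state, seeds, k) {
  stopifnot(k >= 1L)
  out <- state %>%
    as_tibble() %>%
    filter(!.data$gene %in% seeds) %>%
    arrange(desc(.data$probability), .data$gene) %>%
    mutate(rank = row_number())
  if (k > nrow(out)) {
    warn(sprintf("k = %d exceeds the %d non-seed genes; returning all",
                 k, nrow(out)))
    k <- nrow(out)
  }
  head(out, k)
}
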