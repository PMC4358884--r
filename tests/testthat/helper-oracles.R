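# Independent oracles and fixture builders. These never call the package's
# own path or alignment routines.

# --- network fixtures -------------------------------------------------------

# Build a ppi_network from a compact edge data frame (a, b, combined,
# optional experimental channel score).
make_network <- function(df) {
  if (is.null(df$experimental)) df$experimental <- 0L
  records <- tibble::tibble(
    protein_a = df$a, protein_b = df$b,
    experimental = as.integer(df$experimental),
    combined = as.integer(df$combined)
  )
  suppressMessages(suppressWarnings(build_network(records)))
}

# Random connected weighted network on n nodes (letters as names).
random_network <- function(n_nodes, edge_prob = 0.5, rng_seed = 1) {
  withr::with_seed(rng_seed, {
    nodes <- sprintf("n%02d", seq_len(n_nodes))
    pairs <- t(combn(nodes, 2))
    keep <- runif(nrow(pairs)) < edge_prob
    chain <- cbind(nodes[-n_nodes], nodes[-1]) # keep it connected
    sel <- unique(rbind(pairs[keep, , drop = FALSE], chain))
    make_network(data.frame(
      a = sel[, 1], b = sel[, 2],
      combined = sample(150:999, nrow(sel), replace = TRUE)
    ))
  })
}

# Write a STRING-dialect links file from rows of raw text fields.
write_links_file <- function(rows, path = withr::local_tempfile(
                               fileext = ".txt", .local_envir = parent.frame())) {
  header <- paste("protein1 protein2 neighborhood fusion cooccurence",
                  "coexpression experimental database textmining",
                  "combined_score")
  writeLines(c(header, rows), path)
  path
}

links_row <- function(a, b, combined, experimental = 0) {
  paste(a, b, 0, 0, 0, 0, experimental, 0, 0, combined)
}

# --- shortest-path oracle ---------------------------------------------------

# Exhaustive enumeration of all simple paths between two nodes; returns the
# minimum total weight and all paths attaining it.
enumerate_min_paths <- function(network, from, to) {
  g <- network$graph
  wmap <- setNames(network$edges$weight,
                   paste(network$edges$protein_a, network$edges$protein_b))
  vpaths <- igraph::all_simple_paths(g, from = from, to = to)
  if (length(vpaths) == 0) return(NULL)
  weights <- vapply(vpaths, function(v) {
    nm <- igraph::V(g)$name[as.integer(v)]
    a <- nm[-length(nm)]
    b <- nm[-1]
    sum(wmap[paste(pmin(a, b), pmax(a, b))])
  }, numeric(1))
  minw <- min(weights)
  paths <- lapply(vpaths[weights == minw], function(v)
    igraph::V(g)$name[as.integer(v)])
  list(weight = minw, paths = paths)
}

# Lexicographically smallest node sequence, implemented by padded string
# comparison (independent of the package's element-wise comparison).
oracle_lex_min <- function(paths) {
  keys <- vapply(paths, function(p) paste(p, collapse = "\001"),
                 character(1))
  paths[[order(keys)[1]]]
}

# Betweenness by brute force: for every seed pair, enumerate all simple
# paths, keep the lexicographically smallest minimum-weight one, and count
# inner nodes.
oracle_betweenness <- function(network, seeds) {
  nodes <- sort(igraph::V(network$graph)$name)
  counts <- setNames(integer(length(nodes)), nodes)
  seeds <- sort(seeds)
  for (i in seq_len(length(seeds) - 1)) {
    for (j in (i + 1):length(seeds)) {
      res <- enumerate_min_paths(network, seeds[i], seeds[j])
      if (is.null(res)) next
      p <- oracle_lex_min(res$paths)
      inner <- p[-c(1, length(p))]
      counts[inner] <- counts[inner] + 1L
    }
  }
  counts
}

# --- local alignment oracle -------------------------------------------------

# Smith-Waterman with affine gaps (first gap residue costs gap_open, each
# further one gap_extend), plain triple-loop dynamic programming.
oracle_local_alignment <- function(seq1, seq2, mat, gap_open, gap_extend) {
  s1 <- strsplit(seq1, "")[[1]]
  s2 <- strsplit(seq2, "")[[1]]
  n <- length(s1)
  m <- length(s2)
  if (n == 0 || m == 0) return(0)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1) # gap in seq1 (consumes seq2)
  F <- matrix(-Inf, n + 1, m + 1) # gap in seq2 (consumes seq1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - gap_open, E[i, j - 1] - gap_extend)
      F[i, j] <- max(H[i - 1, j] - gap_open, F[i - 1, j] - gap_extend)
      H[i, j] <- max(0,
                     H[i - 1, j - 1] + mat[s1[i - 1], s2[j - 1]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

random_aa <- function(len, rng_seed = NULL) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
  paste(sample(aa, len, replace = TRUE), collapse = "")
}
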