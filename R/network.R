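# Confidence-weighted PPI network: edge tibble + igraph graph.

#' The seven per-channel score names of a detailed protein-links file
#'
#' Column order of the evidence channels, as they appear between the two
#' protein identifiers and the combined score.
#'
#' @return A character vector of length 7.
#' @export
string_channels <- function() {
  c("neighborhood", "fusion", "cooccurence", "coexpression",
    "experimental", "database", "textmining")
}

strip_taxon <- function(ids) sub("^[0-9]+\\.", "", ids)

#' Read a detailed protein-links file
#'
#' Parses the whitespace-separated protein-links dialect: a header line, then
#' one row per interaction with two protein identifiers, seven per-channel
#' scores and a combined confidence score. The combined score must lie in
#' \[150, 999\]. Taxon prefixes (`"9606."`) are stripped from identifiers on
#' ingest so that seed lists with bare identifiers match.
#'
#' @param path Path to a links file; `.gz` files are read transparently.
#' @param taxon Optional taxon prefix (e.g. `"9606"`). When given, only rows
#'   whose two identifiers both carry that prefix are kept.
#' @param strict When `TRUE`, malformed rows (wrong column count, non-integer
#'   score) and rows with a combined score outside \[150, 999\] are errors
#'   naming the offending line; when `FALSE` (default, suited to real files)
#'   such rows are skipped and their counts reported.
#'
#' @return A tibble with columns `protein_a`, `protein_b`, the seven channel
#'   scores (see [string_channels()]) and `combined`.
#' @seealso [build_network()], [write_network_links()]
#' @export
read_string_links <- function(path, taxon = NULL, strict = FALSE) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con), add = TRUE)
  lines <- readLines(con, warn = FALSE)
  if (length(lines) < 2L || all(!nzchar(trimws(lines[-1])))) {
    abort(paste0("no interaction rows in '", path, "'"))
  }
  body <- lines[-1L]
  lineno <- seq_along(body) + 1L
  keep <- nzchar(trimws(body))
  body <- body[keep]
  lineno <- lineno[keep]

  fields <- strsplit(trimws(body), "[[:space:]]+")
  nf <- lengths(fields)
  ncol_expected <- 10L

  bad_shape <- nf != ncol_expected
  if (any(bad_shape) && strict) {
    abort(sprintf("malformed row at line %d: expected %d fields, found %d",
                  lineno[which(bad_shape)[1]], ncol_expected,
                  nf[which(bad_shape)[1]]))
  }
  mat <- matrix("", nrow = length(fields), ncol = ncol_expected)
  mat[!bad_shape, ] <- do.call(rbind, fields[!bad_shape])

  scores <- suppressWarnings(
    matrix(as.integer(mat[, 3:10]), nrow = nrow(mat))
  )
  bad_score <- !bad_shape & apply(is.na(scores), 1L, any)
  if (any(bad_score) && strict) {
    abort(sprintf("malformed row at line %d: non-integer score",
                  lineno[which(bad_score)[1]]))
  }
  malformed <- bad_shape | bad_score

  combined <- scores[, 8L]
  out_of_range <- !malformed & (combined < 150L | combined > 999L)
  if (any(out_of_range) && strict) {
    abort(sprintf(
      "combined score %d outside [150, 999] at line %d",
      combined[which(out_of_range)[1]], lineno[which(out_of_range)[1]]))
  }

  drop <- malformed | out_of_range
  if (any(malformed)) {
    inform(sprintf("skipped %d malformed row(s)", sum(malformed)))
  }
  if (any(out_of_range)) {
    inform(sprintf("skipped %d row(s) with combined score outside [150, 999]",
                   sum(out_of_range)))
  }

  ids_a <- mat[, 1L]
  ids_b <- mat[, 2L]
  keep_row <- !drop
  if (!is.null(taxon)) {
    pref <- paste0(taxon, ".")
    keep_row <- keep_row &
      startsWith(ids_a, pref) & startsWith(ids_b, pref)
  }

  out <- tibble(
    protein_a = strip_taxon(ids_a[keep_row]),
    protein_b = strip_taxon(ids_b[keep_row])
  )
  ch <- string_channels()
  for (j in seq_along(ch)) out[[ch[j]]] <- scores[keep_row, j]
  out$combined <- combined[keep_row]
  out
}

#' Build a weighted interaction network from interaction records
#'
#' Collapses the two orientations of each interaction to one undirected edge
#' and assigns every edge the shortest-path weight `1000 - combined`, so that
#' high-confidence interactions are short. Self-interactions are dropped with
#' a warning; duplicate records for the same protein pair are resolved by the
#' maximum combined score (reported when the duplicates disagree).
#'
#' @param records A tibble of interaction records as returned by
#'   [read_string_links()] (only `protein_a`, `protein_b`, `experimental` and
#'   `combined` are required).
#' @param experimental_threshold An edge is flagged as experimentally
#'   supported when its experimental channel score is at least this value
#'   (default 1, i.e. any nonzero experimental evidence).
#'
#' @return A `ppi_network` object: an edge tibble (`protein_a`, `protein_b`,
#'   `combined`, `weight`, `experimental`, `experimental_flag`) plus the
#'   equivalent igraph graph. Edge endpoints are stored in lexicographic
#'   order.
#' @export
build_network <- function(records, experimental_threshold = 1L) {
  stopifnot(is.data.frame(records), nrow(records) > 0L)
  if (!"experimental" %in% names(records)) records$experimental <- 0L
  if (!all(c("protein_a", "protein_b", "combined") %in% names(records))) {
    abort("records must have columns protein_a, protein_b, combined")
  }
  if (any(records$combined < 150L | records$combined > 999L)) {
    abort("combined scores must lie in [150, 999]")
  }

  self <- records$protein_a == records$protein_b
  if (any(self)) {
    warn(sprintf("dropping %d self-interaction record(s)", sum(self)))
    records <- records[!self, , drop = FALSE]
  }
  if (nrow(records) == 0L) abort("no usable interaction records")

  edges <- records %>%
    mutate(
      a = pmin(.data$protein_a, .data$protein_b),
      b = pmax(.data$protein_a, .data$protein_b)
    ) %>%
    group_by(.data$a, .data$b)
  n_conflict <- edges %>%
    summarise(conflict = n_distinct(.data$combined) > 1L, .groups = "drop") %>%
    pull(.data$conflict) %>%
    sum()
  if (n_conflict > 0L) {
    inform(sprintf(
      "%d duplicated pair(s) with conflicting combined scores; keeping the maximum",
      n_conflict))
  }
  edges <- edges %>%
    arrange(desc(.data$combined), .by_group = TRUE) %>%
    slice(1L) %>%
    ungroup() %>%
    transmute_edges(experimental_threshold)

  g <- igraph::graph_from_data_frame(
    edges %>% select("protein_a", "protein_b", "weight", "combined",
                     "experimental_flag"),
    directed = FALSE
  )
  structure(
    list(edges = edges, graph = g,
         experimental_threshold = experimental_threshold),
    class = "ppi_network"
  )
}

transmute_edges <- function(x, experimental_threshold) {
  tibble(
    protein_a = x$a,
    protein_b = x$b,
    combined = as.integer(x$combined),
    weight = 1000L - as.integer(x$combined),
    experimental = as.integer(x$experimental),
    experimental_flag = as.integer(x$experimental) >= experimental_threshold
  ) %>%
    arrange(.data$protein_a, .data$protein_b)
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf(
    "<ppi_network> %d proteins, %d interactions (%d experimentally supported)\n",
    igraph::vcount(x$graph), nrow(x$edges), sum(x$edges$experimental_flag)))
  cat(sprintf("  edge weight = 1000 - combined score; weights in [%d, %d]\n",
              min(x$edges$weight), max(x$edges$weight)))
  invisible(x)
}

#' @method as_tibble ppi_network
#' @export
as_tibble.ppi_network <- function(x, ...) x$edges

#' Proteins of a network
#' @param network A `ppi_network`.
#' @return Sorted character vector of node identifiers.
#' @export
network_nodes <- function(network) {
  stopifnot(inherits(network, "ppi_network"))
  sort(igraph::V(network$graph)$name)
}

#' Edge table of a network
#' @param network A `ppi_network`.
#' @return The edge tibble.
#' @export
network_edges <- function(network) {
  stopifnot(inherits(network, "ppi_network"))
  network$edges
}

#' Write a network back to the detailed protein-links dialect
#'
#' Emits a header and one row per undirected edge, with all channel scores
#' zero except the experimental channel. Re-parsing the file with
#' [read_string_links()] and rebuilding with [build_network()] reproduces the
#' network (same nodes, edges, combined scores and experimental flags).
#'
#' @param network A `ppi_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_links <- function(network, path) {
  stopifnot(inherits(network, "ppi_network"))
  e <- network$edges
  df <- data.frame(
    protein1 = e$protein_a, protein2 = e$protein_b,
    neighborhood = 0L, fusion = 0L, cooccurence = 0L, coexpression = 0L,
    experimental = e$experimental, database = 0L, textmining = 0L,
    combined_score = e$combined
  )
  write.table(df, path, sep = " ", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a network as an edge-list TSV
#'
#' @param network A `ppi_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "ppi_network"))
  e <- network$edges %>%
    select("protein_a", "protein_b", "combined", "weight",
           "experimental_flag")
  write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a seed-gene list and map it onto a network
#'
#' Reads one identifier per line (blank lines and `#` comments ignored,
#' taxon prefixes stripped) and keeps those present among the network's
#' nodes. Absent identifiers are reported and dropped. At least two mappable
#' seeds are required, otherwise no seed pair exists for the shortest-path
#' search.
#'
#' @param path Path to the seed list.
#' @param network A `ppi_network`.
#' @return Sorted character vector of seed identifiers present in the
#'   network.
#' @export
read_seed_genes <- function(path, network) {
  stopifnot(inherits(network, "ppi_network"))
  lines <- trimws(readLines(path, warn = FALSE))
  ids <- strip_taxon(lines[nzchar(lines) & !startsWith(lines, "#")])
  ids <- unique(ids)
  nodes <- network_nodes(network)
  missing <- setdiff(ids, nodes)
  if (length(missing) > 0L) {
    warn(sprintf("%d seed identifier(s) not in the network, dropped: %s",
                 length(missing),
                 paste(head(missing, 5L), collapse = ", ")))
  }
  seeds <- sort(intersect(ids, nodes))
  if (length(seeds) < 2L) {
    abort("fewer than 2 seed genes map onto the network; no seed pairs exist")
  }
  seeds
}
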