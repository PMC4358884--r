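# Synthetic benchmark: random confidence-weighted networks with planted
# bridge genes on seed-pair shortest paths, and matching protein sequences.

#' Specification of a synthetic prioritization benchmark
#'
#' Describes a random interaction network with a planted structure: seed
#' genes split into groups, one bridge gene per group wired to each of its
#' group's seeds with maximum-confidence edges (combined 999, weight 1), so
#' that each bridge lies on the unique minimum-weight route of every pair of
#' its group's seeds. Bridges get no background edges, so any path through a
#' bridge must enter and leave via its spoke seeds; background edges are
#' capped at combined 900 (weight at least 100), giving the bridge routes a
#' weight margin of at least 98 over any alternative. Background combined
#' scores are skewed toward the 150 floor, mimicking the mass of a real
#' confidence-score distribution.
#'
#' @param n_nodes Total nodes (default 200).
#' @param n_seeds Seed genes (default 12).
#' @param n_bridges Planted bridge genes, each assigned a disjoint group of
#'   seeds (default 3; groups need at least 2 seeds each).
#' @param n_similar_bridges Bridges whose sequences are mutated copies of a
#'   seed template, so their best alignment lands in the seed set (default
#'   all bridges).
#' @param edge_prob Background edge probability between non-bridge node
#'   pairs (default 0.04).
#' @param background_combined Range of background combined scores (default
#'   c(150, 900)).
#' @param bridge_combined Combined score of bridge spokes (default 999).
#' @param experimental_fraction Fraction of edges carrying an experimental
#'   channel score equal to their combined score (default 0.3).
#' @param seq_length Protein sequence length in residues (default 150).
#' @param mutation_rate Per-site substitution rate of bridge sequences
#'   relative to their seed template, in \[0, 1\] (default 0.05).
#' @param seed_topology `"bridged"` (default) plants bridges;
#'   `"clique"` instead joins every seed pair directly at combined 999, a
#'   negative control on which the graph stage finds no candidates.
#' @param rng_seed Integer seed (default 1).
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n_nodes = 200L, n_seeds = 12L, n_bridges = 3L,
                            n_similar_bridges = n_bridges,
                            edge_prob = 0.04,
                            background_combined = c(150L, 900L),
                            bridge_combined = 999L,
                            experimental_fraction = 0.3,
                            seq_length = 150L, mutation_rate = 0.05,
                            seed_topology = c("bridged", "clique"),
                            rng_seed = 1L) {
  seed_topology <- match.arg(seed_topology)
  if (n_seeds + n_bridges > n_nodes) {
    abort("n_seeds + n_bridges exceeds n_nodes")
  }
  if (seed_topology == "bridged" && n_bridges > 0L &&
      n_seeds < 2L * n_bridges) {
    abort("each bridge needs a seed group of at least 2: n_seeds < 2 * n_bridges")
  }
  if (n_similar_bridges > n_bridges) {
    abort("n_similar_bridges exceeds n_bridges")
  }
  if (mutation_rate < 0 || mutation_rate > 1) {
    abort("mutation_rate must lie in [0, 1]")
  }
  if (background_combined[1] < 150L || background_combined[2] > 999L ||
      background_combined[1] > background_combined[2]) {
    abort("background_combined must be an increasing range within [150, 999]")
  }
  structure(
    list(n_nodes = as.integer(n_nodes), n_seeds = as.integer(n_seeds),
         n_bridges = as.integer(n_bridges),
         n_similar_bridges = as.integer(n_similar_bridges),
         edge_prob = edge_prob,
         background_combined = as.integer(background_combined),
         bridge_combined = as.integer(bridge_combined),
         experimental_fraction = experimental_fraction,
         seq_length = as.integer(seq_length),
         mutation_rate = mutation_rate, seed_topology = seed_topology,
         rng_seed = as.integer(rng_seed)),
    class = "simulation_spec"
  )
}

rbackground_combined <- function(n, range) {
  lo <- range[1]
  hi <- range[2]
  as.integer(round(lo + (hi - lo) * rbeta(n, 1.2, 4)))
}

#' Generate a synthetic interaction network with planted bridges
#'
#' Builds the network described by a [simulation_spec()]: named nodes
#' (`SEED..`, `BRDG..`, `PROT..`), an Erdos-Renyi background among
#' non-bridge nodes (plus a random chain keeping them connected), and the
#' planted bridge spokes. Deterministic for a fixed `rng_seed`.
#'
#' @param spec A [simulation_spec()].
#' @return A `ppi_simulation` list: `$network` (a `ppi_network`), `$seeds`,
#'   `$bridges` (character vectors), `$truth` (tibble `gene`, `role`,
#'   `group`, `similar`) and `$spec`.
#' @export
simulate_ppi_network <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  n_other <- spec$n_nodes - spec$n_seeds - spec$n_bridges
  seeds <- sprintf("SEED%02d", seq_len(spec$n_seeds))
  bridges <- if (spec$n_bridges > 0L) {
    sprintf("BRDG%02d", seq_len(spec$n_bridges))
  } else character()
  others <- if (n_other > 0L) sprintf("PROT%03d", seq_len(n_other)) else
    character()
  background_nodes <- c(seeds, others)

  group <- if (spec$n_bridges > 0L) {
    rep_len(seq_len(spec$n_bridges), spec$n_seeds)
  } else rep(NA_integer_, spec$n_seeds)

  records <- withr::with_seed(spec$rng_seed, {
    # Erdos-Renyi background among non-bridge nodes
    pairs <- t(utils::combn(background_nodes, 2L))
    keep <- stats::runif(nrow(pairs)) < spec$edge_prob
    bg <- tibble(protein_a = pairs[keep, 1L], protein_b = pairs[keep, 2L])
    # random chain guaranteeing one background component
    chain_order <- sample(background_nodes)
    chain <- tibble(protein_a = chain_order[-length(chain_order)],
                    protein_b = chain_order[-1L])
    bg <- bind_rows(bg, chain) %>%
      mutate(a = pmin(.data$protein_a, .data$protein_b),
             b = pmax(.data$protein_a, .data$protein_b)) %>%
      distinct(.data$a, .data$b) %>%
      select(protein_a = "a", protein_b = "b")
    bg$combined <- rbackground_combined(nrow(bg), spec$background_combined)

    planted <- if (spec$seed_topology == "clique") {
      sp <- t(utils::combn(seeds, 2L))
      tibble(protein_a = sp[, 1L], protein_b = sp[, 2L],
             combined = spec$bridge_combined)
    } else if (spec$n_bridges > 0L) {
      tibble(protein_a = bridges[group], protein_b = seeds,
             combined = spec$bridge_combined)
    } else {
      tibble(protein_a = character(), protein_b = character(),
             combined = integer())
    }
    # planted edges dominate any background duplicate of the same pair
    rec <- bind_rows(planted, bg)
    rec$experimental <- ifelse(
      stats::runif(nrow(rec)) < spec$experimental_fraction, rec$combined, 0L)
    rec
  })

  network <- suppressMessages(build_network(records))
  truth <- tibble(
    gene = c(seeds, bridges, others),
    role = c(rep("seed", length(seeds)), rep("bridge", length(bridges)),
             rep("decoy", length(others))),
    group = c(group, seq_len(spec$n_bridges), rep(NA_integer_, n_other)),
    similar = c(rep(NA, length(seeds)),
                seq_len(spec$n_bridges) <= spec$n_similar_bridges,
                rep(NA, n_other))
  )
  structure(list(network = network, seeds = seeds, bridges = bridges,
                 truth = truth, spec = spec),
            class = "ppi_simulation")
}

#' @export
print.ppi_simulation <- function(x, ...) {
  cat(sprintf(
    "<ppi_simulation> %d nodes (%d seeds, %d bridges), rng_seed %d\n",
    x$spec$n_nodes, length(x$seeds), length(x$bridges), x$spec$rng_seed))
  print(x$network)
  invisible(x)
}

random_protein <- function(n, length) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
  vapply(seq_len(n), function(i) {
    paste(sample(aa, length, replace = TRUE), collapse = "")
  }, character(1))
}

mutate_protein <- function(seq, rate) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
  chars <- strsplit(seq, "")[[1]]
  hit <- stats::runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(ch) {
      sample(setdiff(aa, ch), 1L)
    }, character(1))
  }
  paste(chars, collapse = "")
}

#' Generate protein sequences matching a simulated network
#'
#' Seed genes get independent random sequences. Bridges flagged as
#' "similar" get a point-mutated copy of the template of the first seed in
#' their group, so their best alignment partner lies in the seed set; all
#' other genes get unrelated random sequences, which score far below a
#' template self-alignment. Deterministic for the spec's `rng_seed`.
#'
#' @param sim A `ppi_simulation` from [simulate_ppi_network()].
#' @return A tibble (`gene`, `role`, `sequence`).
#' @export
simulate_sequences <- function(sim) {
  stopifnot(inherits(sim, "ppi_simulation"))
  spec <- sim$spec
  truth <- sim$truth
  withr::with_seed(spec$rng_seed + 1L, {
    seq_tbl <- truth %>% select("gene", "role")
    seqs <- random_protein(nrow(seq_tbl), spec$seq_length)
    names(seqs) <- seq_tbl$gene
    similar_bridges <- truth[truth$role == "bridge" & truth$similar, ,
                             drop = FALSE]
    for (i in seq_len(nrow(similar_bridges))) {
      grp <- similar_bridges$group[i]
      template_seed <- truth$gene[truth$role == "seed" &
                                    !is.na(truth$group) &
                                    truth$group == grp][1L]
      seqs[similar_bridges$gene[i]] <- mutate_protein(seqs[template_seed],
                                                      spec$mutation_rate)
    }
    seq_tbl$sequence <- unname(seqs)
    seq_tbl
  })
}

#' Write a simulated benchmark to disk
#'
#' Emits the network in the detailed protein-links dialect, the seed list
#' (one identifier per line), the sequences as FASTA, and the ground-truth
#' roles as TSV.
#'
#' @param sim A `ppi_simulation`.
#' @param dir Output directory (created if missing).
#' @param sequences Optional sequence tibble from [simulate_sequences()];
#'   generated on the fly when `NULL`.
#' @return The directory path, invisibly.
#' @export
write_simulation <- function(sim, dir, sequences = NULL) {
  stopifnot(inherits(sim, "ppi_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_network_links(sim$network, file.path(dir, "protein_links.txt"))
  writeLines(sim$seeds, file.path(dir, "seed_genes.txt"))
  if (is.null(sequences)) sequences <- simulate_sequences(sim)
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(setNames(sequences$sequence, sequences$gene)),
    file.path(dir, "sequences.fasta"))
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
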