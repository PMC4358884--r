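# A deterministic simulated benchmark shared across hybrid tests.
hybrid_fixture <- function(n_similar = 2L, rng_seed = 19L) {
  sim <- simulate_ppi_network(simulation_spec(
    n_nodes = 100, n_seeds = 12, n_bridges = 4,
    n_similar_bridges = n_similar, rng_seed = rng_seed))
  seqs <- simulate_sequences(sim)
  scores <- alignment_scores(
    seqs, query = setdiff(seqs$gene, sim$seeds), reference = sim$seeds)
  list(sim = sim, scores = scores)
}

test_that("alignment and interaction filters keep exact-threshold rows", {
  tbl <- tibble::tibble(
    gene = c("a", "b", "c"),
    alignment_score = c(89, 90, 91),
    interaction_score = c(899, 900, 907)
  )
  expect_equal(alignment_filter(tbl)$gene, c("b", "c"))
  expect_equal(interaction_filter(tbl)$gene, c("b", "c"))
  expect_equal(interaction_filter(tbl, 901)$gene, "c")
})

test_that("planted bridges with similar sequences survive all three stages", {
  fx <- hybrid_fixture(n_similar = 2L)
  res <- suppressMessages(run_hybrid(
    fx$sim$network, fx$sim$seeds, fx$scores,
    hybrid_config(n_permutations = 200, rng_seed = 3)))
  similar <- fx$sim$truth$gene[!is.na(fx$sim$truth$similar) &
                                 fx$sim$truth$similar]
  expect_setequal(res$candidates$gene, similar)
  # dissimilar bridges fall at the alignment stage, not before
  dissimilar <- setdiff(fx$sim$bridges, similar)
  expect_true(all(dissimilar %in% res$stages$fdr_filtered$gene))
  expect_false(any(dissimilar %in% res$stages$alignment_filtered$gene))
})

test_that("stage outputs are nested and ordered by interaction score", {
  fx <- hybrid_fixture()
  res <- suppressMessages(run_hybrid(
    fx$sim$network, fx$sim$seeds, fx$scores,
    hybrid_config(n_permutations = 100, rng_seed = 5)))
  s1 <- res$stages$fdr_filtered$gene
  s2 <- res$stages$alignment_filtered$gene
  s3 <- res$candidates$gene
  expect_true(all(s1 %in% res$stages$shortest_path$gene))
  expect_true(all(s2 %in% s1))
  expect_true(all(s3 %in% s2))
  expect_true(!is.unsorted(rev(res$candidates$interaction_score)))
})

test_that("raising any threshold never increases the candidate count", {
  fx <- hybrid_fixture()
  base <- hybrid_config(n_permutations = 100, rng_seed = 5)
  run <- function(cfg) {
    nrow(suppressMessages(run_hybrid(
      fx$sim$network, fx$sim$seeds, fx$scores, cfg))$candidates)
  }
  n0 <- run(base)
  for (tweak in list(
    hybrid_config(fdr_threshold = 0.01, n_permutations = 100, rng_seed = 5),
    hybrid_config(alignment_threshold = 500, n_permutations = 100,
                  rng_seed = 5),
    hybrid_config(interaction_threshold = 9999, n_permutations = 100,
                  rng_seed = 5))) {
    expect_lte(run(tweak), n0)
  }
})

test_that("identical inputs and rng seed reproduce the result exactly", {
  fx <- hybrid_fixture()
  cfg <- hybrid_config(n_permutations = 60, rng_seed = 8)
  r1 <- suppressMessages(run_hybrid(fx$sim$network, fx$sim$seeds,
                                    fx$scores, cfg))
  r2 <- suppressMessages(run_hybrid(fx$sim$network, fx$sim$seeds,
                                    fx$scores, cfg))
  expect_identical(r1$candidates, r2$candidates)
  expect_identical(r1$stages, r2$stages)
})

test_that("tidy and glance expose the candidate tables and stage counts", {
  fx <- hybrid_fixture()
  res <- suppressMessages(run_hybrid(
    fx$sim$network, fx$sim$seeds, fx$scores,
    hybrid_config(n_permutations = 60, rng_seed = 8)))
  g <- glance(res)
  expect_equal(g$n_candidates, nrow(tidy(res)))
  expect_equal(g$n_fdr_filtered, nrow(tidy(res, "fdr_filtered")))
  expect_s3_class(autoplot(res), "ggplot")
})

test_that("path evidence counts edges of candidate-bearing paths", {
  # single path a-x-c, both edges experimentally supported
  nw <- make_network(data.frame(
    a = c("a", "x"), b = c("x", "c"), combined = 999,
    experimental = c(400, 500)
  ))
  paths <- seed_shortest_paths(nw, c("a", "c"))
  ev <- path_evidence_stats(nw, paths, "x")
  expect_equal(glance(ev)$n_total, 2L)
  expect_equal(glance(ev)$fraction, 1)
  # no candidate on any path -> empty stats with missing fraction
  ev0 <- path_evidence_stats(nw, paths, "zzz")
  expect_equal(glance(ev0)$n_total, 0L)
  expect_true(is.na(glance(ev0)$fraction))
})

test_that("path evidence fraction matches a recount of the emitted edges", {
  fx <- hybrid_fixture()
  paths <- suppressMessages(seed_shortest_paths(fx$sim$network,
                                                fx$sim$seeds))
  ev <- path_evidence_stats(fx$sim$network, paths, fx$sim$bridges)
  edges <- tidy(ev)
  expect_equal(glance(ev)$n_experimental, sum(edges$experimental_flag))
  expect_equal(glance(ev)$fraction,
               sum(edges$experimental_flag) / nrow(edges))
  expect_true(glance(ev)$fraction >= 0 && glance(ev)$fraction <= 1)
  # every reported edge really exists in the network
  expect_equal(nrow(dplyr::anti_join(
    edges, network_edges(fx$sim$network),
    by = c("protein_a", "protein_b"))), 0L)
})

test_that("the worked percentage summaries are computed, not stored", {
  s <- path_evidence_summary(639, 877)
  expect_equal(round(s$percentage, 2), 72.86)
  s2 <- path_evidence_summary(86854, 1640707)
  expect_equal(round(s2$percentage, 2), 5.29)
})
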