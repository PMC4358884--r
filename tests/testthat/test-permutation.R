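# A bridged fixture: seeds a, c connected through b; decoys off to the side.
bridged_fixture <- function() {
  make_network(data.frame(
    a = c("a", "b", "a", "c", "x", "y"),
    b = c("b", "c", "x", "y", "z", "z"),
    combined = c(999, 999, 400, 400, 400, 400)
  ))
}

test_that("a gene beating every permutation gets FDR 0", {
  nw <- bridged_fixture()
  seeds <- c("a", "c")
  bt <- path_betweenness(seed_shortest_paths(nw, seeds), nw)
  res <- permutation_fdr(nw, seeds, shortest_path_genes(bt, seeds),
                         n_permutations = 50, rng_seed = 1, betweenness = bt)
  expect_true(all(res$fdr >= 0 & res$fdr <= 1))
  expect_equal(res$fdr, res$exceed_count / 50)
})

test_that("the FDR granularity is 1/n_permutations", {
  # exceed_count 3 out of 500 permutations -> 0.006
  expect_equal(3 / 500, 0.006)
  nw <- bridged_fixture()
  seeds <- c("a", "c")
  bt <- path_betweenness(seed_shortest_paths(nw, seeds), nw)
  res <- permutation_fdr(nw, seeds, shortest_path_genes(bt, seeds),
                         n_permutations = 500, rng_seed = 7,
                         betweenness = bt)
  expect_true(all(res$fdr * 500 == round(res$fdr * 500)))
})

test_that("identical rng seeds give identical permutation results", {
  nw <- random_network(12, edge_prob = 0.3, rng_seed = 5)
  seeds <- sort(network_nodes(nw)[1:4])
  bt <- path_betweenness(suppressMessages(seed_shortest_paths(nw, seeds)), nw)
  cand <- shortest_path_genes(bt, seeds)
  r1 <- permutation_fdr(nw, seeds, cand, n_permutations = 40, rng_seed = 11,
                        betweenness = bt)
  r2 <- permutation_fdr(nw, seeds, cand, n_permutations = 40, rng_seed = 11,
                        betweenness = bt)
  r3 <- permutation_fdr(nw, seeds, cand, n_permutations = 40, rng_seed = 12,
                        betweenness = bt)
  expect_identical(r1, r2)
  expect_false(identical(r1, r3)) # a different draw is allowed to differ
})

test_that("permutation results replay an independent re-implementation", {
  # 6-node graph, 2 seeds, 50 permutations: replay the same uniform draws
  # with a brute-force betweenness oracle.
  nw <- random_network(6, edge_prob = 0.5, rng_seed = 3)
  seeds <- c("n01", "n04")
  bt <- path_betweenness(suppressMessages(seed_shortest_paths(nw, seeds)), nw)
  cand <- shortest_path_genes(bt, seeds)$gene
  res <- permutation_fdr(nw, seeds, cand, n_permutations = 50, rng_seed = 9,
                         betweenness = bt)

  nodes <- igraph::V(nw$graph)$name
  actual <- oracle_betweenness(nw, seeds)[res$gene]
  exceed <- setNames(integer(length(res$gene)), res$gene)
  withr::with_seed(9, {
    for (b in 1:50) {
      repeat {
        perm <- sample(nodes, length(seeds))
        if (!setequal(perm, seeds)) break
      }
      cnt <- oracle_betweenness(nw, perm)[res$gene]
      exceed <- exceed + (cnt > actual)
    }
  })
  expect_equal(res$exceed_count, unname(exceed))
  expect_equal(res$fdr, unname(exceed) / 50)
})

test_that("FDR is non-increasing in actual betweenness under fixed draws", {
  nw <- bridged_fixture()
  seeds <- c("a", "c")
  bt <- path_betweenness(seed_shortest_paths(nw, seeds), nw)
  cand <- shortest_path_genes(bt, seeds)
  # raising a gene's actual betweenness (same draws) cannot raise its FDR
  fdr_at <- function(actual_count) {
    doctored <- bt
    doctored$betweenness[doctored$gene == "b"] <- actual_count
    res <- permutation_fdr(nw, seeds, cand, n_permutations = 60,
                           rng_seed = 2, betweenness = doctored)
    res$fdr[res$gene == "b"]
  }
  fdrs <- vapply(0:3, fdr_at, numeric(1))
  expect_true(all(diff(fdrs) <= 0))
})

test_that("the strict FDR cut keeps 0.049 and drops 0.05", {
  res <- tibble::tibble(
    gene = c("g1", "g2", "g3"),
    betweenness = c(5L, 4L, 3L),
    exceed_count = c(0L, 0L, 0L),
    fdr = c(0.049, 0.05, 0.2)
  )
  expect_equal(filter_by_fdr(res, 0.05)$gene, "g1")
  expect_equal(nrow(filter_by_fdr(res[0, ], 0.05)), 0L)
})

test_that("planted bridge genes reach FDR below 0.05", {
  sim <- simulate_ppi_network(simulation_spec(
    n_nodes = 120, n_seeds = 8, n_bridges = 2, rng_seed = 31))
  bt <- path_betweenness(
    suppressMessages(seed_shortest_paths(sim$network, sim$seeds)),
    sim$network)
  cand <- shortest_path_genes(bt, sim$seeds)
  expect_true(all(sim$bridges %in% cand$gene))
  res <- permutation_fdr(sim$network, sim$seeds, cand,
                         n_permutations = 500, rng_seed = 13,
                         betweenness = bt)
  expect_true(all(res$fdr[res$gene %in% sim$bridges] < 0.05))
})

test_that("a seed set larger than the network is rejected", {
  nw <- make_network(data.frame(a = "a", b = "b", combined = 500))
  expect_error(
    permutation_fdr(nw, c("a", "b", "c"), "x", n_permutations = 5),
    "fewer nodes")
})
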