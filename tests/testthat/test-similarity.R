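test_that("identical sequences score their self-similarity sum", {
  mat <- substitution_matrix("BLOSUM62")
  seq <- "MKVLHE"
  self <- sum(vapply(strsplit(seq, "")[[1]], function(ch) mat[ch, ch],
                     numeric(1)))
  expect_equal(local_alignment_score(seq, seq), self)
})

test_that("the textbook local alignment example scores 28", {
  # HEAGAWGHEE vs PAWHEAE, BLOSUM50, linear gap cost 8 per residue
  expect_equal(
    local_alignment_score("HEAGAWGHEE", "PAWHEAE",
                          substitution_matrix = "BLOSUM50",
                          gap_open = 8, gap_extend = 8),
    28)
})

test_that("sequences with no positive-scoring residue pair score 0", {
  # under BLOSUM62, G vs L/I/P is strictly negative
  expect_equal(local_alignment_score("GGGG", "LIPL"), 0)
})

test_that("empty sequences score 0 with a warning", {
  expect_warning(s <- local_alignment_score("", "MKV"), "empty sequence")
  expect_equal(s, 0)
})

test_that("invalid residues error in strict mode and read as X otherwise", {
  expect_error(local_alignment_score("MK1", "MKV"), "invalid residue")
  # X scores 0 against anything, so the lenient score drops by the V match
  lenient <- local_alignment_score("MK1", "MKV", strict = FALSE)
  expect_equal(lenient, local_alignment_score("MK", "MK"))
})

test_that("the aligner agrees with an exhaustive DP oracle on random pairs", {
  mat <- substitution_matrix("BLOSUM62")
  withr::with_seed(42, {
    for (case in 1:40) {
      s1 <- random_aa(sample(1:12, 1))
      s2 <- random_aa(sample(1:12, 1))
      go <- sample(c(5, 8, 11), 1)
      ge <- sample(c(1, 2, go), 1)
      expect_equal(
        local_alignment_score(s1, s2, gap_open = go, gap_extend = ge),
        oracle_local_alignment(s1, s2, mat, go, ge),
        info = sprintf("case %d: %s / %s (open %g extend %g)",
                       case, s1, s2, go, ge))
    }
  })
})

test_that("alignment scores are symmetric", {
  withr::with_seed(7, {
    for (case in 1:10) {
      s1 <- random_aa(sample(3:12, 1))
      s2 <- random_aa(sample(3:12, 1))
      expect_equal(local_alignment_score(s1, s2),
                   local_alignment_score(s2, s1))
    }
  })
})

test_that("v_max returns the maximum scored pair with its partner", {
  scores <- tibble::tibble(
    id_a = c("p", "p", "p"), id_b = c("s1", "s2", "s3"),
    score = c(50, 90, 90)
  )
  out <- v_max(scores, "p", c("s1", "s2"))
  expect_equal(out$score, 90)
  expect_equal(out$partner, "s2")
  # lexicographic tie-break between s2 and s3
  out_tie <- v_max(scores, "p", c("s2", "s3"))
  expect_equal(out_tie$partner, "s2")
})

test_that("v_max ignores self-pairs and handles unscored genes", {
  scores <- tibble::tibble(
    id_a = c("p", "p"), id_b = c("p", "s1"), score = c(1000, 40)
  )
  out <- v_max(scores, "p", c("p", "s1"))
  expect_equal(out$score, 40) # self pair excluded even though scored higher
  none <- v_max(scores, "q", "s1")
  expect_equal(none$score, 0)
  expect_true(is.na(none$partner))
})

test_that("v_max is monotone in the reference set", {
  withr::with_seed(11, {
    genes <- paste0("g", 1:6)
    pairs <- t(combn(genes, 2))
    scores <- tibble::tibble(id_a = pairs[, 1], id_b = pairs[, 2],
                             score = runif(nrow(pairs), 0, 100))
    for (i in 1:10) {
      ref_small <- sample(genes[-1], 2)
      ref_big <- union(ref_small, sample(genes[-1], 2))
      expect_gte(v_max(scores, "g1", ref_big)$score,
                 v_max(scores, "g1", ref_small)$score)
    }
  })
})

test_that("similarity classification is strict on ties", {
  scores <- tibble::tibble(
    id_a = c("p", "p", "q", "q"),
    id_b = c("r1", "n1", "r1", "n1"),
    score = c(90, 50, 50, 50)
  )
  v <- similarity_classify(scores, c("p", "q"), s_r = "r1", s_nr = "n1")
  expect_true(v$is_candidate[v$gene == "p"]) # 90 > 50
  expect_false(v$is_candidate[v$gene == "q"]) # 50 = 50, tie fails
  expect_error(similarity_classify(scores, "p", s_r = "r1", s_nr = "r1"),
               "disjoint")
})

test_that("a mutated copy of a seed is classified as a candidate", {
  sim <- simulate_ppi_network(simulation_spec(
    n_nodes = 40, n_seeds = 4, n_bridges = 2, rng_seed = 19))
  seqs <- simulate_sequences(sim)
  ids <- c(sim$bridges, sim$seeds, paste0("PROT0", 10:15))
  scores <- alignment_scores(seqs[seqs$gene %in% ids, ])
  v <- similarity_classify(scores, sim$bridges, s_r = sim$seeds)
  expect_true(all(v$is_candidate))
  # and the verdict maxima agree with the DP oracle applied directly
  mat <- substitution_matrix("BLOSUM62")
  sv <- setNames(seqs$sequence, seqs$gene)
  b1 <- sim$bridges[1]
  oracle_best <- max(vapply(sim$seeds, function(s) {
    oracle_local_alignment(sv[[b1]], sv[[s]], mat, 11, 1)
  }, numeric(1)))
  expect_equal(v$v_r[v$gene == b1], oracle_best)
})

test_that("score tables read from TSV keep ids and scores", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id_a\tid_b\tscore", "9606.A\tB\t12.5", "B\tC\t3"), path)
  tbl <- read_score_table(path)
  expect_equal(tbl$id_a, c("A", "B"))
  expect_equal(tbl$score, c(12.5, 3))
  writeLines(c("id_a\tid_b\tscore", "A\tB\t-1"), path)
  expect_error(read_score_table(path), "non-negative")
})
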