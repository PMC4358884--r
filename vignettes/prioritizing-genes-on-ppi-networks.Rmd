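---
title: "Prioritizing candidate genes on confidence-weighted interaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing candidate genes on confidence-weighted interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathprio)
library(dplyr)
```

## The problem

Given a set of genes known to participate in a biological process — here
the motivating case is human reproduction, anchored by 115 genes with
experimental process annotation — which other genes are likely to
participate too? Testing genes one by one in the laboratory is slow and
expensive, so a computational shortlist matters. pathprio builds that
shortlist from three complementary kinds of evidence: the topology of a
protein–protein interaction (PPI) network, protein sequence similarity,
and per-interaction confidence scores.

## The model

### The weighted graph

The input is a detailed protein-links table in the STRING dialect: one row
per interaction, seven evidence-channel scores and a combined confidence
score $S(p_1, p_2) \in [150, 999]$. We build an undirected graph
$G = (V, E)$ over all proteins and give every edge the weight

$$w(e) = 1000 - S(p_1, p_2),$$

so a maximally trusted interaction ($S = 999$) has weight 1 and a barely
reported one ($S = 150$) has weight 850. Minimum-weight paths therefore
prefer chains of high-confidence interactions.

### Path-count betweenness and the permutation FDR

For every pair of seed genes we search a minimum-weight path with
Dijkstra's algorithm, and for every protein we count the seed-pair paths
on which it appears as an *inner* node. We call this count the gene's
betweenness; note it is a path count over seed pairs only, not the
classical normalized betweenness centrality. Non-seed genes with a
positive count — *shortest-path genes* — are direct or indirect brokers of
seed–seed connectivity.

Hub proteins broker everything, not just the process of interest. To
remove them we run a randomization test: 500 node sets of the same size as
the seed set are drawn uniformly from $V$ (re-drawn if a set equals the
seed set), the betweenness of each shortest-path gene is recomputed under
each random set, and the permutation FDR is the fraction of random sets
under which the gene's betweenness *strictly exceeds* its actual value.
Genes with FDR $< 0.05$ (strictly) survive. Both inequalities are strict
throughout; with 500 permutations the FDR granularity is $1/500 = 0.002$.

### The two local filters and the hybrid pipeline

Two simpler classifiers judge a query gene $p$ by its strongest single
link to the seed set $S_R$ versus the unlabeled rest $S_{NR}$:

* **similarity**: $v^b_R(p) = \max\{S_b(p, p') : p' \in S_R\}$ with
  $S_b$ a pairwise local alignment score, against the analogous
  $v^b_{NR}(p)$; a candidate iff $v^b_R(p) > v^b_{NR}(p)$ (strict);
* **interaction**: the same construction with the combined confidence
  score, $v^i_R(p) > v^i_{NR}(p)$.

The hybrid pipeline chains the three signals in order of decreasing
reach: (I) the graph stage (shortest-path genes, FDR filter), then (II)
exclusion of candidates with $v^b_R < 90$, then (III) exclusion of
candidates with $v^i_R < 900$. Because the wording is "exclude if strictly
less", values exactly at a threshold pass. The published full-scale run of
this pipeline (packaged as `reference_candidates()`) narrows 406
shortest-path genes to 129, 27 and finally 21 candidates; its minima
(alignment 103, interaction 907) sit just above the cuts, consistent with
either boundary reading, so we follow the literal exclude-if-less rule.

The alignment scores are pluggable: the production path is an external
score table (`read_score_table()`), because large-scale all-versus-all
alignment is a job for a dedicated search tool, and published score scales
(raw vs bit score) vary. The built-in Smith–Waterman scorer
(`local_alignment_score()`, BLOSUM62, affine gap open 11 / extend 1 —
standard protein-search defaults) makes the whole pipeline testable
without any external tool. The stage-II threshold of 90 applies to
whatever scale the supplied table uses; users supplying bit scores should
recalibrate it.

### Random walk with restart

The comparator propagates seed mass through the network:
$P_{t+1} = (1 - r)\,A' P_t + r P_0$, with $A'$ the column-normalized
adjacency matrix, $P_0$ uniform over the seeds, restart probability
$r = 0.7$ and an L1 convergence tolerance of $10^{-6}$ (both standard in
the network-propagation literature). Adjacency is binary by default — the
cited propagation tools operate on unweighted interaction graphs, and the
weighted variant is available via `weighted = TRUE`. Dangling nodes
receive a self-loop column so the matrix stays column-stochastic and
probability mass is conserved (asserted to $10^{-9}$ in tests). The L1
norm was chosen for the unspecified "difference between states";
`max_iterations` defaults to 10,000.

## Design choices where the procedure was genuinely open

* **One path per seed pair.** Dijkstra's algorithm returns a single
  minimum-weight path, and a single-path count is deterministic once ties
  are broken lexicographically (smallest node sequence from the smaller
  endpoint). Counting *every* co-minimal path is also defensible; both
  modes exist (`mode = "all"`), single-path is the default.
* **Seeds as inner nodes.** A seed lying on another pair's path is
  counted in the betweenness table but never selected as a candidate —
  the point of the exercise is novel genes.
* **Permutation sets** are size-matched, drawn uniformly from all of $V$,
  and only rejected when identical to the seed set (overlap allowed) —
  the literal reading of "same size … but different". Degree-matched
  sampling is exposed as an option (`sampling = "degree_matched"`) for
  users worried about hub bias.
* **Missing interactions score 0** in the interaction classifier, not the
  150 score floor: absence of a record is absence of evidence.
* **Jackknife `k` for RWR.** To compare RWR fairly against the graph
  method, a held-out seed counts as recovered when it ranks in the top
  $k$; `k` defaults to the size of the graph method's candidate set *on
  the same fold* (the published comparison used the full-run size, which
  a fixed-`k` option reproduces).
* **`S_{NR}`** defaults to every scored/networked gene outside $S_R$,
  with the query gene itself always excluded from both maxima.

## The synthetic benchmark

Real full-scale inputs (a 1.6M-interaction human network and an
all-versus-all alignment table) are external downloads, so the package
ships a generator that reproduces the *structure* the method exploits at
desk scale. `simulation_spec()` defaults describe the benchmark used
throughout the tests and the acceptance script:

* 200 nodes, of which 12 seeds and 3 planted bridges; the remaining 185
  are background decoys;
* background: an Erdős–Rényi graph (edge probability 0.04, plus a random
  chain to keep it connected) with combined scores drawn from a
  Beta(1.2, 4) distribution rescaled to [150, 900] — skewed toward the
  floor, as real confidence-score mass is;
* each bridge is wired to a disjoint group of 4 seeds with combined-999
  spokes (weight 1) and has *no* other edges. Any path through a bridge
  must therefore enter and leave via two of its spoke seeds, and the
  two-hop spoke route (weight 2) undercuts any background alternative
  (weight ≥ 100 per hop) by a margin of at least 98 — each bridge lies on
  the unique minimum-weight route of each of its $\binom{4}{2} = 6$ seed
  pairs by construction;
* sequences: 150-residue random proteins; each "similar" bridge is a
  copy of its group's first seed template with 5% per-site substitutions,
  so its best alignment partner is a seed; decoys are unrelated random
  sequences, whose local alignment scores against any template stay far
  below a template self-score;
* 30% of edges carry an experimental channel score, feeding the
  path-evidence statistics.

What this benchmark does *not* emulate: real degree distributions
(scale-free hubs), correlated evidence channels, protein families with
graded homology, or annotation noise in the seed list. Passing the
planted-recovery tests shows the pipeline's stages compose and detect the
signal they are designed for; it does not certify performance on real
interactomes.

## Numerical and degenerate-input conventions

* Ties: path ties break lexicographically; score-maximum ties report the
  lexicographically smallest partner; classifier ties (`v_R = v_NR`) are
  *not* candidates.
* A gene with no scored pair or no seed edge gets $v = 0$ and no partner.
* Disconnected seed pairs are skipped with a note (large PPI graphs have
  components), not errors; fewer than two mappable seeds is an error.
* Empty path-evidence sets report a missing fraction, never 0.
* All randomized routines (`permutation_fdr()`, the generator) take an
  explicit integer seed and restore the caller's RNG state.

## Problem sizes in the test-suite and acceptance script

Property suites compare the Dijkstra-based betweenness against exhaustive
simple-path enumeration on 250 random graphs of 5–10 nodes, and the RWR
iteration against a direct linear solve on 50-node graphs (tolerance
$10^{-5}$); planted-signal recovery runs the full pipeline with 500
permutations on the default 200-node benchmark; jackknife evaluations in
the acceptance script use 100 permutations per fold. These sizes are the
package's choices: large enough that the oracles exercise branching,
ties and disconnected cases, small enough to run in seconds.

## Known limitations

* Exact single-source Dijkstra per seed (and per permutation) is the
  only mode; no approximate betweenness. Cost grows with
  `n_permutations` times the number of seed pairs, which is why the
  full-scale published run is an external workflow rather than a test.
* The alignment threshold (90) inherits the score scale of the supplied
  table; no attempt is made to normalize raw vs bit scores.
* The FDR is a per-gene empirical exceedance probability, not a
  multiple-testing-adjusted q-value; its resolution is limited to
  $1/n_\text{permutations}$.
* `S_{NR}` built from "everything not in $S_R$" inevitably contains
  unknown true positives; the hybrid pipeline therefore uses only the
  $v_R$ thresholds, not the $v_R > v_{NR}$ verdicts, exactly so that an
  ill-defined $S_{NR}$ cannot veto a good candidate.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_ppi_network(simulation_spec(rng_seed = 1))
seqs <- simulate_sequences(sim)
scores <- alignment_scores(seqs, query = setdiff(seqs$gene, sim$seeds),
                           reference = sim$seeds)
res <- run_hybrid(sim$network, sim$seeds, scores,
                  hybrid_config(n_permutations = 500, rng_seed = 2))
tidy(res)      # final candidate table
glance(res)    # per-stage counts
autoplot(res)  # the candidate funnel
```
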