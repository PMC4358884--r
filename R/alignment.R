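# Sequence-similarity classifier: local alignment scores against seed and
# non-seed reference sets.

#' Fetch a protein substitution matrix by name
#'
#' Looks the matrix up among the scoring matrices shipped with Biostrings
#' (BLOSUM45/50/62/80/100, PAM30/40/70/120/250) and zeroes the `X`
#' (unknown residue) row and column so that unknown residues neither reward
#' nor penalize an alignment.
#'
#' @param substitution_matrix A matrix, or the name of a shipped one.
#' @return A numeric substitution matrix.
#' @export
substitution_matrix <- function(substitution_matrix = "BLOSUM62") {
  if (is.matrix(substitution_matrix)) {
    mat <- substitution_matrix
  } else {
    e <- new.env()
    utils::data(list = substitution_matrix, package = "Biostrings", envir = e)
    mat <- e[[substitution_matrix]]
  }
  if ("X" %in% rownames(mat)) {
    mat["X", ] <- 0L
    mat[, "X"] <- 0L
  }
  mat
}

validate_protein <- function(seq, alphabet, strict) {
  letters_seen <- unique(strsplit(seq, "")[[1]])
  bad <- setdiff(letters_seen, alphabet)
  if (length(bad) == 0L) return(seq)
  if (strict) {
    abort(paste0("invalid residue(s): ", paste(bad, collapse = ", ")))
  }
  chartr(paste(bad, collapse = ""), strrep("X", length(bad)), seq)
}

#' Optimal local alignment score of two protein sequences
#'
#' Smith-Waterman score under a substitution matrix and affine gap
#' penalties: the first residue of a gap costs `gap_open`, every further
#' residue `gap_extend` (setting `gap_extend = gap_open` gives linear gap
#' costs). The score is 0 when no positive-scoring local alignment exists.
#' Defaults (BLOSUM62, open 11, extend 1) mirror common protein-search
#' practice.
#'
#' @param seq1,seq2 Protein sequences (character strings over the 20-letter
#'   amino-acid alphabet; `X` scores 0 against everything).
#' @param substitution_matrix Matrix or name, see [substitution_matrix()].
#' @param gap_open Cost of the first gapped residue (default 11).
#' @param gap_extend Cost of each further gapped residue (default 1).
#' @param strict Error on residues outside the matrix alphabet (default);
#'   otherwise they are read as `X`.
#' @return A non-negative alignment score.
#' @export
local_alignment_score <- function(seq1, seq2,
                                  substitution_matrix = "BLOSUM62",
                                  gap_open = 11, gap_extend = 1,
                                  strict = TRUE) {
  if (nchar(seq1) == 0L || nchar(seq2) == 0L) {
    warn("empty sequence; local alignment score is 0")
    return(0)
  }
  mat <- substitution_matrix(substitution_matrix)
  alph <- rownames(mat)
  seq1 <- validate_protein(seq1, alph, strict)
  seq2 <- validate_protein(seq2, alph, strict)
  score <- Biostrings::pairwiseAlignment(
    seq1, seq2, type = "local", substitutionMatrix = mat,
    gapOpening = gap_open - gap_extend, gapExtension = gap_extend,
    scoreOnly = TRUE)
  max(0, score)
}

#' Pairwise local alignment scores for a set of sequences
#'
#' Scores `query` sequences against `reference` sequences with the built-in
#' local aligner, returning a long score table. Self pairs are skipped and
#' each unordered pair is scored once.
#'
#' @param sequences Named character vector of protein sequences, or a tibble
#'   with columns `gene` and `sequence` (as from [simulate_sequences()]).
#' @param query,reference Identifier subsets (default: all sequences).
#' @inheritParams local_alignment_score
#' @return A score-table tibble (`id_a`, `id_b`, `score`).
#' @export
alignment_scores <- function(sequences, query = NULL, reference = NULL,
                             substitution_matrix = "BLOSUM62",
                             gap_open = 11, gap_extend = 1) {
  seqs <- as_sequence_vector(sequences)
  query <- if (is.null(query)) names(seqs) else intersect(query, names(seqs))
  reference <- if (is.null(reference)) names(seqs) else
    intersect(reference, names(seqs))
  mat <- substitution_matrix(substitution_matrix)
  pairs <- tidyr::expand_grid(id_a = query, id_b = reference) %>%
    mutate(a = pmin(.data$id_a, .data$id_b),
           b = pmax(.data$id_a, .data$id_b)) %>%
    filter(.data$a != .data$b) %>%
    distinct(.data$a, .data$b)
  if (nrow(pairs) == 0L) {
    return(tibble(id_a = character(), id_b = character(), score = numeric()))
  }
  score <- Biostrings::pairwiseAlignment(
    seqs[pairs$a], seqs[pairs$b], type = "local", substitutionMatrix = mat,
    gapOpening = gap_open - gap_extend, gapExtension = gap_extend,
    scoreOnly = TRUE)
  tibble(id_a = pairs$a, id_b = pairs$b, score = pmax(0, score))
}

as_sequence_vector <- function(sequences) {
  if (is.data.frame(sequences)) {
    return(setNames(sequences$sequence, sequences$gene))
  }
  if (inherits(sequences, "AAStringSet")) {
    return(setNames(as.character(sequences), names(sequences)))
  }
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  sequences
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA path.
#' @return Named character vector of sequences (taxon prefixes stripped from
#'   names).
#' @export
read_fasta_sequences <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), strip_taxon(sub("\\s.*$", "", names(x))))
}

#' Read a pairwise alignment-score table
#'
#' Expects a TSV with columns `id_a`, `id_b`, `score` (header optional when
#' the columns come in that order). Scores are treated as opaque
#' non-negative reals on whatever scale the producing aligner used.
#'
#' @param path TSV path.
#' @return A score-table tibble (`id_a`, `id_b`, `score`).
#' @export
read_score_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id_a", "id_b", "score") %in% names(df))) {
    if (ncol(df) < 3L) abort("score table needs columns id_a, id_b, score")
    names(df)[1:3] <- c("id_a", "id_b", "score")
  }
  if (any(df$score < 0)) abort("alignment scores must be non-negative")
  tibble(id_a = strip_taxon(as.character(df$id_a)),
         id_b = strip_taxon(as.character(df$id_b)),
         score = as.numeric(df$score))
}

symmetrize_scores <- function(scores) {
  bind_rows(
    scores %>% select("id_a", "id_b", "score"),
    scores %>% select(id_a = "id_b", id_b = "id_a", "score")
  ) %>%
    group_by(.data$id_a, .data$id_b) %>%
    summarise(score = max(.data$score), .groups = "drop")
}

#' Maximum score of a gene against a reference set
#'
#' For each query gene, the maximum pairwise score against members of
#' `reference` (the gene itself is always excluded), with the score-partner
#' attaining it; ties go to the lexicographically smallest partner. Genes
#' with no scored pair against the reference get score 0 and no partner.
#'
#' @param scores A score-table tibble (`id_a`, `id_b`, `score`); treated as
#'   symmetric.
#' @param genes Query gene identifiers.
#' @param reference Reference set identifiers (non-empty).
#' @return A tibble (`gene`, `score`, `partner`), one row per query gene.
#' @export
v_max <- function(scores, genes, reference) {
  stopifnot(length(reference) > 0L)
  genes <- unique(genes)
  best <- symmetrize_scores(scores) %>%
    filter(.data$id_a %in% genes, .data$id_b %in% reference,
           .data$id_a != .data$id_b) %>%
    group_by(gene = .data$id_a) %>%
    arrange(desc(.data$score), .data$id_b, .by_group = TRUE) %>%
    slice(1L) %>%
    ungroup() %>%
    select("gene", "score", partner = "id_b")
  tibble(gene = genes) %>%
    left_join(best, by = "gene") %>%
    mutate(score = ifelse(is.na(.data$score), 0, .data$score))
}

#' Similarity-based candidate classification
#'
#' A query gene is called a candidate when its maximum alignment score to
#' the positive set `s_r` strictly exceeds its maximum score to the
#' unlabeled set `s_nr` (ties are not candidates). By default `s_nr` is
#' every scored gene outside `s_r`.
#'
#' @param scores A score-table tibble.
#' @param genes Query gene identifiers.
#' @param s_r Positive (seed) set.
#' @param s_nr Unlabeled set; default all other identifiers in the score
#'   table. Must be disjoint from `s_r`.
#' @return A verdict tibble (`gene`, `v_r`, `argmax_r`, `v_nr`, `argmax_nr`,
#'   `is_candidate`).
#' @export
similarity_classify <- function(scores, genes, s_r, s_nr = NULL) {
  if (is.null(s_nr)) {
    universe <- unique(c(scores$id_a, scores$id_b))
    s_nr <- setdiff(universe, s_r)
  }
  if (length(intersect(s_r, s_nr)) > 0L) {
    abort("s_r and s_nr must be disjoint")
  }
  vr <- v_max(scores, genes, s_r)
  vnr <- v_max(scores, genes, s_nr)
  tibble(
    gene = vr$gene,
    v_r = vr$score, argmax_r = vr$partner,
    v_nr = vnr$score, argmax_nr = vnr$partner,
    is_candidate = vr$score > vnr$score
  )
}

#' Write a classifier verdict table as TSV
#'
#' @param verdicts Tibble from [similarity_classify()] or
#'   [interaction_classify()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_verdicts <- function(verdicts, path) {
  write.table(verdicts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
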