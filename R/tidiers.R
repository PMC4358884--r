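# broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a hybrid result
#'
#' @param x A `hybrid_result`.
#' @param stage Which table to return: the final `"candidates"` (default)
#'   or one of the intermediate stages `"shortest_path"`, `"fdr_filtered"`,
#'   `"alignment_filtered"`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy hybrid_result
#' @export
tidy.hybrid_result <- function(x, stage = c("candidates", "shortest_path",
                                            "fdr_filtered",
                                            "alignment_filtered"), ...) {
  stage <- match.arg(stage)
  if (stage == "candidates") x$candidates else x$stages[[stage]]
}

#' One-row summary of a hybrid result
#'
#' @param x A `hybrid_result`.
#' @param ... Unused.
#' @return A one-row tibble with seed and per-stage candidate counts.
#' @method glance hybrid_result
#' @export
glance.hybrid_result <- function(x, ...) {
  tibble(
    n_seeds = length(x$seeds),
    n_shortest_path_genes = nrow(x$stages$shortest_path),
    n_fdr_filtered = nrow(x$stages$fdr_filtered),
    n_alignment_filtered = nrow(x$stages$alignment_filtered),
    n_candidates = nrow(x$candidates),
    fdr_threshold = x$config$fdr_threshold,
    alignment_threshold = x$config$alignment_threshold,
    interaction_threshold = x$config$interaction_threshold
  )
}

#' Stage-by-stage candidate funnel of a hybrid run
#'
#' @param object A `hybrid_result`.
#' @param ... Unused.
#' @return A ggplot: candidate counts surviving each pipeline stage.
#' @method autoplot hybrid_result
#' @export
autoplot.hybrid_result <- function(object, ...) {
  g <- glance(object)
  df <- tibble(
    stage = factor(
      c("shortest-path\ngenes", "FDR filter", "alignment\nfilter",
        "interaction\nfilter"),
      levels = c("shortest-path\ngenes", "FDR filter", "alignment\nfilter",
                 "interaction\nfilter")),
    count = c(g$n_shortest_path_genes, g$n_fdr_filtered,
              g$n_alignment_filtered, g$n_candidates)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "genes retained",
                  title = "Hybrid pipeline candidate funnel") +
    ggplot2::theme_minimal()
}

#' @rdname tidy.hybrid_result
#' @method tidy rwr_result
#' @export
tidy.rwr_result <- function(x, ...) as_tibble(x)

#' One-row summary of an RWR run
#'
#' @param x An `rwr_result`.
#' @param ... Unused.
#' @return A one-row tibble (`iterations`, `converged`, `restart`,
#'   `n_seeds`, `total_probability`).
#' @method glance rwr_result
#' @export
glance.rwr_result <- function(x, ...) {
  tibble(
    iterations = attr(x, "iterations"),
    converged = attr(x, "converged"),
    restart = attr(x, "restart"),
    n_seeds = length(attr(x, "seeds")),
    total_probability = sum(x$probability)
  )
}

#' Stationary probabilities of an RWR run
#'
#' @param object An `rwr_result`.
#' @param top Number of highest-probability genes to show (default 25).
#' @param ... Unused.
#' @return A ggplot: top stationary probabilities, seeds marked.
#' @method autoplot rwr_result
#' @export
autoplot.rwr_result <- function(object, top = 25L, ...) {
  seeds <- attr(object, "seeds")
  df <- as_tibble(object) %>%
    arrange(desc(.data$probability)) %>%
    head(top) %>%
    mutate(seed = .data$gene %in% seeds,
           gene = factor(.data$gene, levels = rev(.data$gene)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$probability, y = .data$gene,
                                   fill = .data$seed)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey55",
                                          `TRUE` = "firebrick"),
                               name = "seed gene") +
    ggplot2::labs(x = "stationary probability", y = NULL,
                  title = "Random walk with restart") +
    ggplot2::theme_minimal()
}

#' @rdname glance.path_evidence
#' @method tidy path_evidence
#' @export
tidy.path_evidence <- function(x, ...) x$edges

#' One-row summary of path-evidence statistics
#'
#' @param x A `path_evidence`.
#' @param ... Unused.
#' @return The summary tibble (`n_total`, `n_experimental`, `fraction`,
#'   `percentage`, `n_paths`).
#' @method glance path_evidence
#' @export
glance.path_evidence <- function(x, ...) x$summary

#' @rdname glance.jackknife_result
#' @method tidy jackknife_result
#' @export
tidy.jackknife_result <- function(x, ...) as_tibble(x)

#' One-row summary of a jackknife evaluation
#'
#' @param x A `jackknife_result`.
#' @param ... Unused.
#' @return A one-row tibble (`method`, `n_seeds`, `identified`,
#'   `recovery_rate`).
#' @method glance jackknife_result
#' @export
glance.jackknife_result <- function(x, ...) {
  tibble(
    method = attr(x, "method"),
    n_seeds = nrow(x),
    identified = attr(x, "identified_count"),
    recovery_rate = attr(x, "identified_count") / nrow(x)
  )
}

#' Per-seed recovery of a jackknife evaluation
#'
#' @param object A `jackknife_result`.
#' @param ... Unused.
#' @return A ggplot: which held-out seeds the method recovered.
#' @method autoplot jackknife_result
#' @export
autoplot.jackknife_result <- function(object, ...) {
  df <- as_tibble(object) %>%
    mutate(seed = factor(.data$seed, levels = rev(sort(.data$seed))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$identified, y = .data$seed)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "held-out seed recovered", y = NULL,
                  title = paste0("Jackknife recovery (",
                                 attr(object, "method"), " method)")) +
    ggplot2::theme_minimal()
}
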