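#' Plot a ceRNA network edge table
#'
#' Shared-family count against edge significance, coloured by the query
#' gene's family-set size; the FDR threshold used to call edges is drawn
#' as a reference line.
#'
#' @param object A `cerna_network` tibble from [build_cerna_network()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot cerna_network
#' @export
autoplot.cerna_network <- function(object, ...) {
  thr <- attr(object, "fdr_threshold") %||% 0.05
  ggplot2::ggplot(object, ggplot2::aes(x = .data$c,
                                       y = -log10(.data$q_value),
                                       colour = .data$K)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(thr), linetype = "dashed") +
    ggplot2::labs(
      x = "shared miRNA families (c)",
      y = expression(-log[10] ~ "FDR q-value"),
      colour = "K (query\nfamilies)",
      title = "ceRNA pair significance"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an enrichment result
#'
#' Classic dot plot: top terms by significance, dot size giving the
#' query/term overlap.
#'
#' @param object An `enrichment_result` tibble from [enrich()].
#' @param n_terms Number of top terms to show (default 15).
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, n_terms = 15L, ...) {
  top <- utils::head(object, n_terms) %>%
    mutate(term = stats::reorder(.data$term_name, -.data$p_value))
  ggplot2::ggplot(top, ggplot2::aes(x = -log10(.data$p_value),
                                    y = .data$term,
                                    size = .data$overlap_count,
                                    colour = .data$q_value < 0.05)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(-log[10] ~ "p-value"), y = NULL,
                  size = "overlap", colour = "q < 0.05",
                  title = "Functional-term enrichment") +
    ggplot2::theme_minimal()
}

#' Plot a super-sponge report
#'
#' Site counts of the top candidate sponge transcripts, with the
#' CLIP-supported subset overlaid.
#'
#' @param object A `sponge_report` tibble from [rank_sponges()].
#' @param n_top Number of transcripts to show (default 20).
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot sponge_report
#' @export
autoplot.sponge_report <- function(object, n_top = 20L, ...) {
  top <- utils::head(object, n_top) %>%
    mutate(label = paste(.data$transcript_id, .data$family_id, sep = " / "),
           label = stats::reorder(.data$label, .data$site_count))
  ggplot2::ggplot(top) +
    ggplot2::geom_col(ggplot2::aes(x = .data$site_count, y = .data$label),
                      fill = "grey70") +
    ggplot2::geom_col(ggplot2::aes(x = .data$clip_supported_site_count,
                                   y = .data$label),
                      fill = "steelblue") +
    ggplot2::labs(x = "target sites (grey: all, blue: CLIP-supported)",
                  y = NULL, title = "Candidate super-sponges") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
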