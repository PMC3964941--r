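#' Tidy a ceRNA network
#'
#' Returns the edge table as a plain tibble (one row per ceRNA pair).
#'
#' @param x A `cerna_network` from [build_cerna_network()].
#' @param ... Ignored.
#' @return A tibble.
#' @method tidy cerna_network
#' @export
tidy.cerna_network <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "cerna_network")
  as_tibble(out)
}

#' One-row summary of a ceRNA network
#'
#' @param x A `cerna_network` from [build_cerna_network()].
#' @param ... Ignored.
#' @return A one-row tibble: genes profiled, pairs tested, edges called,
#'   universe size `N` and the parameters used.
#' @method glance cerna_network
#' @export
glance.cerna_network <- function(x, ...) {
  tibble(
    n_genes = attr(x, "n_genes"),
    n_pairs_tested = attr(x, "n_pairs_tested"),
    n_edges = nrow(x),
    universe_N = attr(x, "universe_N"),
    min_common = attr(x, "min_common"),
    fdr_threshold = attr(x, "fdr_threshold"),
    median_shared = if (nrow(x)) stats::median(x$c) else NA_real_
  )
}

#' Tidy an enrichment result
#'
#' @param x An `enrichment_result` from [enrich()].
#' @param ... Ignored.
#' @return The result as a plain tibble.
#' @method tidy enrichment_result
#' @export
tidy.enrichment_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "enrichment_result")
  as_tibble(out)
}

#' One-row summary of an enrichment result
#'
#' @param x An `enrichment_result` from [enrich()].
#' @param ... Ignored.
#' @return A one-row tibble: terms tested, terms significant at q < 0.05
#'   and Bonferroni < 0.05, query and universe sizes.
#' @method glance enrichment_result
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(
    n_terms = nrow(x),
    n_q05 = sum(x$q_value < 0.05),
    n_bonferroni05 = sum(x$p_bonferroni < 0.05),
    query_size = if (nrow(x)) x$query_size[1] else NA_integer_,
    universe_size = if (nrow(x)) x$universe_size[1] else NA_integer_
  )
}
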