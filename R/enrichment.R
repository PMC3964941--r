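#' Read gene sets in GMT format
#'
#' One term per line: `term_id <tab> description <tab> gene1 <tab> gene2
#' ...`. Gene symbols are uppercased and deduplicated per term; terms with
#' no genes are dropped with a warning.
#'
#' @param path Path to a GMT file, or a character vector of GMT lines.
#' @param category_name Label for the annotation category (e.g. `"GO-BP"`,
#'   `"KEGG"`).
#' @return Tibble with `category`, `term_id`, `term_name`, `genes`
#'   (list-column of character vectors), `term_size`.
#' @export
read_gmt <- function(path, category_name = "custom") {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    warn(sprintf("%d GMT lines with no genes dropped (first at line %d)",
                 length(short), short[1]))
    fields <- fields[-short]
  }
  if (!length(fields)) {
    return(tibble(category = character(), term_id = character(),
                  term_name = character(), genes = list(),
                  term_size = integer()))
  }
  genes <- lapply(fields, function(f) unique(toupper(f[-(1:2)])))
  tibble(
    category = category_name,
    term_id = vapply(fields, `[[`, character(1), 1L),
    term_name = vapply(fields, `[[`, character(1), 2L),
    genes = genes,
    term_size = lengths(genes)
  )
}

#' Hypergeometric enrichment of a gene set against annotation terms
#'
#' For each term, tests over-representation of the query in the term with
#' the upper-tail hypergeometric test on `(N_u, K_t, n_q, k)` =
#' (universe size, term size in universe, query size in universe, overlap).
#' Raw p-values receive a per-category Bonferroni correction
#' (`p_bonferroni = min(1, p * m)`, `m` terms tested) and BH FDR
#' (`q_value`). Query genes outside the universe are dropped (and counted);
#' term sets are clipped to the universe. Gene identity is by uppercased
#' symbol.
#'
#' @param query_genes Character vector of gene symbols.
#' @param category Annotation tibble from [read_gmt()].
#' @param universe Background gene symbols; defaults to the union of all
#'   term sets in the category. The background choice dominates enrichment
#'   p-values, so overriding it with the assayed gene universe is
#'   recommended when one exists.
#' @return An `enrichment_result` tibble sorted by `p_value`: `category`,
#'   `term_id`, `term_name`, `overlap_count`, `term_size`, `query_size`,
#'   `universe_size`, `p_value`, `p_bonferroni`, `q_value`; attribute
#'   `dropped_query_genes`.
#' @export
enrich <- function(query_genes, category, universe = NULL) {
  if (!nrow(category)) abort("domain error: empty annotation category")
  universe <- unique(toupper(universe %||%
                               unlist(category$genes, use.names = FALSE)))
  if (!length(universe)) abort("domain error: empty universe")
  query <- unique(toupper(query_genes))
  dropped <- sum(!query %in% universe)
  query <- intersect(query, universe)
  if (!length(query)) abort("domain error: no query genes in the universe")
  term_in_u <- lapply(category$genes, intersect, y = universe)
  K_t <- lengths(term_in_u)
  k <- vapply(term_in_u, function(g) length(intersect(g, query)), integer(1))
  n_q <- length(query)
  N_u <- length(universe)
  keep <- K_t > 0L
  m <- sum(keep)
  p <- hypergeom_pvalue(N_u, K_t[keep], n_q, k[keep])
  cat_col <- category$category[keep]
  id_col <- category$term_id[keep]
  name_col <- category$term_name[keep]
  out <- tibble(
    category = cat_col,
    term_id = id_col,
    term_name = name_col,
    overlap_count = k[keep],
    term_size = K_t[keep],
    query_size = n_q,
    universe_size = N_u,
    p_value = p,
    p_bonferroni = pmin(1, p * m),
    q_value = bh_fdr(p)
  ) %>%
    arrange(.data$p_value, .data$term_id)
  attr(out, "dropped_query_genes") <- dropped
  new_cernet_tbl(out, "enrichment_result")
}

#' Target gene set of selected miRNA families
#'
#' The union, over the selected families, of genes with at least one
#' interaction site passing the stringency filters — the input set for
#' miRNA function prediction.
#'
#' @param families Character vector of family ids.
#' @param interactions Interaction-site tibble (with
#'   `supporting_experiments` and `program_count`).
#' @param min_experiments,min_programs Stringency thresholds, as in
#'   [filter_interactions()].
#' @return Character vector of gene ids.
#' @export
mirfunction_gene_set <- function(families, interactions,
                                 min_experiments = 1L, min_programs = 1L) {
  if (!length(families)) abort("at least one family must be selected")
  unknown <- setdiff(families, interactions$family_id)
  if (length(unknown)) {
    abort(paste0("lookup error: unknown families: ",
                 paste(unknown, collapse = ", ")))
  }
  interactions %>%
    filter(.data$family_id %in% families) %>%
    filter_interactions(min_experiments, min_programs) %>%
    pull("gene_id") %>%
    unique() %>%
    sort()
}

#' ceRNA partner gene set of one gene
#'
#' Partners of `gene` in a ceRNA edge table with `q_value` below the
#' threshold — the input set for ceRNA function prediction.
#' A profiled gene with no passing edges yields an
#' empty set; a gene absent from the network altogether is a lookup error.
#'
#' @param gene Query gene id.
#' @param cerna_edges Edge tibble from [build_cerna_network()].
#' @param fdr_threshold Keep partners with `q_value` below this.
#' @param known_genes Optional character vector of profiled genes used to
#'   distinguish "edgeless" from "unknown"; defaults to genes in the edge
#'   table.
#' @return Character vector of partner gene ids.
#' @export
cernafunction_gene_set <- function(gene, cerna_edges, fdr_threshold = 0.05,
                                   known_genes = NULL) {
  known <- known_genes %||% unique(c(cerna_edges$gene_a, cerna_edges$gene_b))
  if (!gene %in% known) {
    abort(sprintf("lookup error: gene '%s' not in the network", gene))
  }
  hits <- cerna_edges %>%
    filter((.data$gene_a == gene | .data$gene_b == gene),
           .data$q_value < fdr_threshold)
  if (!nrow(hits)) return(character(0))
  sort(unique(ifelse(hits$gene_a == gene, hits$gene_b, hits$gene_a)))
}
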