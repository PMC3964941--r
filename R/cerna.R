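#' Upper-tail hypergeometric p-value
#'
#' Probability of observing `c` or more shared items when `n` items are
#' drawn without replacement from a universe of `N` items of which `K` are
#' marked:
#' \deqn{P(X \ge c) = \sum_{t=c}^{\min(K,n)} \frac{\binom{K}{t}\binom{N-K}{n-t}}{\binom{N}{n}}.}
#'
#' This is the ceRNA-pair statistic: `N` miRNA families in the prediction
#' universe, `K` families targeting the query gene, `n` families targeting
#' the candidate, `c` families shared. Terms are accumulated in log space
#' (log-gamma binomial coefficients, shifted by the modal term) so the tail
#' is stable for large universes. Vectorised over all four arguments.
#'
#' @param N,K,n,c Integer vectors (recycled): universe size, marked count,
#'   draw count, observed shared count.
#' @return Numeric vector of upper-tail probabilities in `[0, 1]`.
#' @examples
#' hypergeom_pvalue(10, 5, 5, 5)  # 1/252
#' hypergeom_pvalue(4, 2, 2, 1)   # 5/6
#' @export
hypergeom_pvalue <- function(N, K, n, c) {
  len <- max(length(N), length(K), length(n), length(c))
  N <- rep_len(as.numeric(N), len); K <- rep_len(as.numeric(K), len)
  n <- rep_len(as.numeric(n), len); c <- rep_len(as.numeric(c), len)
  if (any(K > N)) abort("domain error: K > N")
  if (any(n > N)) abort("domain error: n > N")
  if (any(c > pmin(K, n))) abort("domain error: c > min(K, n)")
  if (any(c < 0)) abort("domain error: c < 0")
  max_t <- pmin(K, n)
  nt <- as.integer(max_t - c + 1)
  idx <- rep(seq_len(len), nt)
  t <- sequence(nt, from = as.integer(c))
  logterm <- lchoose(K[idx], t) + lchoose(N[idx] - K[idx], n[idx] - t) -
    lchoose(N[idx], n[idx])
  # modal term of the hypergeometric pmf, clamped to [c, min(K, n)]:
  # the largest term in the tail, used as the log-sum-exp shift
  tmode <- pmin(pmax(floor((n + 1) * (K + 1) / (N + 2)), c), max_t)
  shift <- lchoose(K, tmode) + lchoose(N - K, n - tmode) - lchoose(N, n)
  sums <- rowsum(exp(logterm - shift[idx]), idx)[, 1]
  p <- pmin(1, exp(log(sums) + shift))
  p[c == 0] <- 1  # P(X >= 0) is exactly 1
  p
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Adjusted p-values \eqn{q_{(i)} = \min_{j \ge i} m\, p_{(j)} / j}
#' (clipped to 1), returned in the input order. Ties are handled by a
#' stable sort, so the output is invariant under input permutation.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    abort("domain error: p-values must lie in [0, 1]")
  }
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(m * p[o] / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Build per-gene miRNA-family profiles
#'
#' Collapses filtered interaction sites to the set of miRNA families with
#' at least one surviving site per gene. Each family is counted once per
#' gene regardless of how many binding sites it has — the counting rule of
#' the ceRNA hypergeometric test. Genes with no surviving sites are absent.
#'
#' @param interactions Interaction-site tibble (post
#'   [filter_interactions()]) with `gene_id`, `family_id` and optionally
#'   `biotype_class`.
#' @param n_families Universe size `N`: the number of miRNA families used
#'   for target prediction (the full collapsed catalog, not just families
#'   with a target). Stored as an attribute and used as the default `N`
#'   downstream.
#' @return Tibble with `gene_id`, optional `biotype_class`, `families`
#'   (comma-joined, sorted) and `n_families` (the per-gene count `K`);
#'   attribute `universe_n_families` = `n_families`.
#' @export
build_family_profiles <- function(interactions, n_families = NULL) {
  keys <- intersect(c("gene_id", "biotype_class"), names(interactions))
  prof <- interactions %>%
    group_by(dplyr::across(dplyr::all_of(keys))) %>%
    summarise(
      families = paste(sort(unique(.data$family_id)), collapse = ","),
      n_families = dplyr::n_distinct(.data$family_id),
      .groups = "drop"
    ) %>%
    arrange(.data$gene_id)
  attr(prof, "universe_n_families") <- n_families
  prof
}

profile_family_list <- function(profiles) {
  fl <- strsplit(profiles$families, ",", fixed = TRUE)
  names(fl) <- profiles$gene_id
  fl
}

profile_incidence <- function(profiles) {
  fl <- profile_family_list(profiles)
  fams <- sort(unique(unlist(fl, use.names = FALSE)))
  mat <- matrix(0L, nrow = length(fl), ncol = length(fams),
                dimnames = list(names(fl), fams))
  mat[cbind(rep(seq_along(fl), lengths(fl)),
            match(unlist(fl, use.names = FALSE), fams))] <- 1L
  mat
}

resolve_universe_n <- function(profiles, N) {
  N <- N %||% attr(profiles, "universe_n_families")
  if (is.null(N)) {
    abort("universe size N not given and profiles carry no universe_n_families attribute")
  }
  if (N < max(profiles$n_families)) {
    abort("domain error: N < max profile size")
  }
  N
}

empty_cerna_pairs <- function() {
  tibble(gene_a = character(), gene_b = character(), N = integer(),
         K = integer(), n = integer(), c = integer(),
         p_value = numeric(), q_value = numeric())
}

# Tests every candidate pair sharing >= 1 family; BH spans all tested
# pairs, and min_common only gates which pairs are reported. Restricting
# the correction to pairs already passing min_common would condition on a
# small tail probability and forfeit FDR control.
cerna_pairs_from_counts <- function(gene_a, gene_b, K, n, c, N,
                                    min_common, fdr_threshold) {
  if (length(gene_a) == 0L) return(empty_cerna_pairs())
  p <- hypergeom_pvalue(N, K, n, c)
  q <- bh_fdr(p)
  tibble(gene_a = gene_a, gene_b = gene_b, N = as.integer(N),
         K = as.integer(K), n = as.integer(n), c = as.integer(c),
         p_value = p, q_value = q) %>%
    filter(.data$c >= min_common, .data$q_value < fdr_threshold) %>%
    arrange(.data$q_value, .data$p_value, .data$gene_b)
}

#' Find ceRNA partners of one query gene
#'
#' Tests the query gene against every other profiled gene sharing at least
#' one miRNA family, using the upper-tail hypergeometric test on the
#' shared-family count. FDR is adjusted across all tested candidates of
#' this query (per-query BH, mirroring an interactive database query);
#' reported partners must additionally share at least `min_common`
#' families, the display stringency of a ceRNA query. Use
#' [build_cerna_network()] for a global adjustment across all pairs.
#'
#' @param profiles Profile tibble from [build_family_profiles()].
#' @param gene Query `gene_id`.
#' @param N Universe size (number of miRNA families used for prediction);
#'   defaults to the profiles' `universe_n_families` attribute.
#' @param min_common Minimum shared-family count for a pair to be
#'   reported (default 3; must be at least 1). Pairs below it are still
#'   part of the FDR correction, never of the output.
#' @param fdr_threshold Report pairs with `q_value` below this (default
#'   0.05).
#' @return Tibble of ceRNA pairs: `gene_a` (query), `gene_b`, `N`, `K`,
#'   `n`, `c`, `p_value`, `q_value`, sorted by `q_value`, `p_value`,
#'   `gene_b`.
#' @export
find_cerna_partners <- function(profiles, gene, N = NULL, min_common = 3L,
                                fdr_threshold = 0.05) {
  if (min_common < 1L) abort("configuration error: min_common must be >= 1")
  if (!gene %in% profiles$gene_id) {
    abort(sprintf("lookup error: gene '%s' not in profiles", gene))
  }
  N <- resolve_universe_n(profiles, N)
  fl <- profile_family_list(profiles)
  fam_g <- fl[[gene]]
  others <- profiles %>% filter(.data$gene_id != gene)
  c_val <- vapply(fl[others$gene_id],
                  function(f) length(intersect(fam_g, f)), integer(1))
  keep <- c_val >= 1L
  if (!any(keep)) return(empty_cerna_pairs())
  cerna_pairs_from_counts(
    gene_a = gene, gene_b = others$gene_id[keep],
    K = length(fam_g), n = others$n_families[keep], c = c_val[keep],
    N = N, min_common = min_common, fdr_threshold = fdr_threshold
  )
}

#' Build the full ceRNA pair network
#'
#' Tests every unordered pair of profiled genes sharing at least one miRNA
#' family with the upper-tail hypergeometric test, adjusts FDR globally
#' across all tested pairs (database-construction mode), and returns the
#' pairs with `q_value` below `fdr_threshold` that share at least
#' `min_common` families. Each pair is reported once with
#' `gene_a < gene_b` lexicographically.
#'
#' @inheritParams find_cerna_partners
#' @return A `cerna_network` tibble of edges (`gene_a`, `gene_b`, `N`, `K`,
#'   `n`, `c`, `p_value`, `q_value`) with attributes `n_genes`,
#'   `n_pairs_tested`, `universe_N`, `min_common`, `fdr_threshold`.
#' @export
build_cerna_network <- function(profiles, N = NULL, min_common = 3L,
                                fdr_threshold = 0.05) {
  if (min_common < 1L) abort("configuration error: min_common must be >= 1")
  if (nrow(profiles) < 2L) abort("need at least two gene profiles")
  N <- resolve_universe_n(profiles, N)
  mat <- profile_incidence(profiles)
  shared <- tcrossprod(mat)
  ut <- which(upper.tri(shared) & shared >= 1L, arr.ind = TRUE)
  genes <- rownames(mat)
  sizes <- profiles$n_families[match(genes, profiles$gene_id)]
  if (nrow(ut)) {
    ga <- genes[ut[, 1]]; gb <- genes[ut[, 2]]
    swap <- ga > gb
    tmp <- ga[swap]; ga[swap] <- gb[swap]; gb[swap] <- tmp
    Kv <- sizes[ut[, 1]]; nv <- sizes[ut[, 2]]
    Kv2 <- Kv; Kv2[swap] <- nv[swap]; nv[swap] <- Kv[swap]
    edges <- cerna_pairs_from_counts(ga, gb, Kv2, nv, shared[ut], N,
                                     min_common, fdr_threshold) %>%
      arrange(.data$q_value, .data$p_value, .data$gene_a, .data$gene_b)
  } else {
    edges <- empty_cerna_pairs()
  }
  new_cernet_tbl(edges, "cerna_network",
                 n_genes = nrow(profiles), n_pairs_tested = nrow(ut),
                 universe_N = as.integer(N), min_common = as.integer(min_common),
                 fdr_threshold = fdr_threshold)
}
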