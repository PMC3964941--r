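#' Count per-transcript target sites of each miRNA family
#'
#' A transcript carrying many sites of one miRNA family is a candidate
#' "super-sponge" for that family (the circRNA CDR1as, with dozens of
#' miR-7 sites, is the archetype). Counts use deduplicated sites — one per
#' locus, highest seed class — so nested matches are not double counted.
#' Both the total site count and the CLIP-supported subset are reported,
#' since either can be the ranking display.
#'
#' @param sites Interaction- or predicted-site tibble with `family_id`, a
#'   transcript attribution (`transcript_id`, falling back to `gene_id`)
#'   and, optionally, `supporting_experiments`.
#' @return Tibble with one row per (family, transcript):
#'   `family_id`, `transcript_id`, `site_count`,
#'   `clip_supported_site_count`.
#' @export
count_family_sites <- function(sites) {
  id_col <- if ("transcript_id" %in% names(sites)) "transcript_id" else "gene_id"
  supported <- if ("supporting_experiments" %in% names(sites)) {
    sites$supporting_experiments >= 1L
  } else {
    rep(FALSE, nrow(sites))
  }
  sites %>%
    mutate(.supported = supported, transcript_id = .data[[id_col]]) %>%
    group_by(.data$family_id, .data$transcript_id) %>%
    summarise(
      site_count = n(),
      clip_supported_site_count = sum(.data$.supported),
      .groups = "drop"
    )
}

#' Rank super-sponge candidates
#'
#' Filters to transcripts with at least `min_sites` sites of one family and
#' sorts descending by site count, breaking ties by CLIP-supported site
#' count and then transcript id.
#'
#' @param records Tibble from [count_family_sites()].
#' @param min_sites Minimum site count to report (default 5).
#' @return The filtered, ordered `sponge_report` tibble.
#' @export
rank_sponges <- function(records, min_sites = 5L) {
  if (min_sites < 1L) abort("configuration error: min_sites must be >= 1")
  out <- records %>%
    filter(.data$site_count >= min_sites) %>%
    arrange(desc(.data$site_count), desc(.data$clip_supported_site_count),
            .data$transcript_id)
  new_cernet_tbl(out, "sponge_report", min_sites = as.integer(min_sites))
}
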