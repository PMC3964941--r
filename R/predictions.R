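KNOWN_PROGRAMS <- c("TargetScan", "miRanda", "PITA", "PicTar2", "RNA22", "builtin")

#' Load target-site predictions produced by external programs
#'
#' Reads BED-like TSV prediction files (columns `program`, `mirna_id`,
#' `gene_id`, `chrom`, `start`, `end`, `strand`; 0-based half-open) and maps
#' each miRNA id to its seed family via the catalog. Records whose miRNA is
#' absent from the catalog are dropped (the drop count is reported as a
#' warning and in the `dropped` attribute); unknown program tags are kept
#' with their literal tag after a warning.
#'
#' @param paths Character vector of prediction TSV paths.
#' @param mirnas miRNA catalog tibble (`mirna_id`, `family_id`,
#'   `mature_sequence`).
#' @return Tibble of predicted sites: `family_id`, `gene_id`, `chrom`,
#'   `start`, `end`, `strand`, `site_type` (`"external"`), `program`; with
#'   attribute `dropped` = number of unmappable records.
#' @export
load_program_predictions <- function(paths, mirnas) {
  raw <- purrr::map(paths, readr::read_tsv, show_col_types = FALSE,
                    progress = FALSE) %>% bind_rows()
  required <- c("program", "mirna_id", "gene_id", "chrom", "start", "end", "strand")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    abort(paste0("prediction files missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  unknown <- setdiff(unique(raw$program), KNOWN_PROGRAMS)
  if (length(unknown)) {
    warn(paste0("unknown program tags kept as-is: ",
                paste(unknown, collapse = ", ")))
  }
  fam <- family_of(raw$mirna_id, mirnas)
  n_drop <- sum(is.na(fam))
  if (n_drop > 0L) {
    warn(sprintf("%d prediction records dropped: miRNA id not in catalog", n_drop))
  }
  out <- raw %>%
    mutate(family_id = fam) %>%
    filter(!is.na(.data$family_id)) %>%
    mutate(site_type = "external") %>%
    select("family_id", "gene_id", "chrom", "start", "end", "strand",
           "site_type", "program")
  attr(out, "dropped") <- n_drop
  out
}

#' Merge per-program predicted sites into interaction sites
#'
#' Sites for the same (family, gene) whose intervals overlap by at least
#' 1 bp are merged transitively into one interaction site spanning their
#' union, with the union of program tags as evidence. This is the unit on
#' which the "predicted by at least k programs" stringency is evaluated.
#' When `chrom`/`strand` columns are present, merging additionally requires
#' the same chromosome and strand.
#'
#' If CLIP-support columns are already present they are aggregated by
#' maximum; in the standard pipeline support is annotated on the merged
#' intervals instead.
#'
#' @param sites Predicted-site tibble with columns `family_id`, `gene_id`
#'   and either genomic `start`/`end` or transcript-space
#'   `site_start`/`site_end`.
#' @return Tibble of interaction sites: grouping keys, merged `start`/`end`,
#'   `programs` (comma-joined, sorted), `program_count`, `n_sites`.
#' @export
merge_evidence <- function(sites) {
  if (!nrow(sites)) {
    return(tibble(family_id = character(), gene_id = character(),
                  start = integer(), end = integer(),
                  programs = character(), program_count = integer(),
                  n_sites = integer()))
  }
  x <- sites
  if (!"start" %in% names(x)) {
    x <- x %>% rename(start = "site_start", end = "site_end")
  }
  keys <- intersect(c("family_id", "gene_id", "chrom", "strand", "transcript_id"),
                    names(x))
  x %>%
    arrange(dplyr::across(dplyr::all_of(keys)), .data$start, .data$end) %>%
    group_by(dplyr::across(dplyr::all_of(keys))) %>%
    mutate(.block = cumsum(.data$start >= cummax(dplyr::lag(.data$end,
                                                            default = -1L)))) %>%
    group_by(.data$.block, .add = TRUE) %>%
    summarise(
      start = min(.data$start),
      end = max(.data$end),
      # program values may themselves be comma-joined (re-merging merged
      # sites is a no-op)
      programs = paste(sort(unique(unlist(strsplit(.data$program, ",",
                                                   fixed = TRUE)))),
                       collapse = ","),
      program_count = length(unique(unlist(strsplit(.data$program, ",",
                                                    fixed = TRUE)))),
      n_sites = n(),
      dplyr::across(dplyr::any_of(c("supporting_experiments",
                                    "total_overlapping_read_count")), max),
      .groups = "drop"
    ) %>%
    select(-".block") %>%
    arrange(dplyr::across(dplyr::all_of(keys)), .data$start)
}

#' Apply CLIP-support and program-count stringency to interaction sites
#'
#' Keeps interaction sites with at least `min_experiments` supporting CLIP
#' experiments and predicted by at least `min_programs` programs (sites from
#' the built-in scanner count as one program). These are the stringency
#' knobs of targetome queries, e.g. "supported by at least one experiment
#' and predicted by at least three of five programs".
#'
#' @param sites Interaction-site tibble with `supporting_experiments` and
#'   `program_count` columns.
#' @param min_experiments,min_programs Non-negative integer thresholds.
#' @return The filtered tibble.
#' @export
filter_interactions <- function(sites, min_experiments = 1L, min_programs = 1L) {
  if (min_experiments < 0L || min_programs < 0L) {
    abort("stringency thresholds must be non-negative")
  }
  sites %>%
    filter(.data$supporting_experiments >= min_experiments,
           .data$program_count >= min_programs)
}
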