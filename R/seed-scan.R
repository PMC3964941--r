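SITE_TYPES <- c("8mer", "7mer-m8", "7mer-A1", "6mer")

#' Scan transcripts for canonical miRNA seed-match sites
#'
#' Finds canonical seed-match target sites of each miRNA family on each
#' transcript sequence (DNA, sense orientation). A locus is anchored at a
#' match to the reverse complement of seed positions 2-7; it is classified
#' by whether the transcript also pairs with seed position 8 (one base
#' 5' of the match on the transcript) and/or carries an `A` opposite miRNA
#' position 1 (one base 3' of the match):
#'
#' * `8mer`: positions 2-8 matched plus the A1 adenosine (8 nt);
#' * `7mer-m8`: positions 2-8 matched, no A1 (7 nt);
#' * `7mer-A1`: positions 2-7 matched plus A1 (7 nt);
#' * `6mer`: positions 2-7 only (6 nt).
#'
#' Each locus yields exactly one site of its highest class, so nested
#' matches are never double-reported. `6mer` sites are excluded by default,
#' mirroring strict seed-pairing stringency. Coordinates are transcript-space,
#' 0-based half-open.
#'
#' @param transcripts Tibble with columns `transcript_id`, `gene_id`,
#'   `sequence` (DNA, A/C/G/T/N).
#' @param families Family tibble from [collapse_families()] (columns
#'   `family_id`, `seed7`), or a single family row.
#' @param site_types Site classes to report; subset of
#'   `c("8mer", "7mer-m8", "7mer-A1", "6mer")`.
#' @return Tibble of predicted sites: `family_id`, `transcript_id`,
#'   `gene_id`, `site_start`, `site_end`, `site_type`, `program` (always
#'   `"builtin"`).
#' @examples
#' tx <- tibble::tibble(transcript_id = "t1", gene_id = "g1",
#'                      sequence = "GGGATAAGCTAGGG")
#' fam <- tibble::tibble(family_id = "miR-21-5p", seed7 = "AGCUUAU")
#' scan_seed_sites(tx, fam)
#' @export
scan_seed_sites <- function(transcripts, families,
                            site_types = c("8mer", "7mer-m8", "7mer-A1")) {
  bad <- setdiff(site_types, SITE_TYPES)
  if (length(bad)) {
    abort(paste0("unknown site types: ", paste(bad, collapse = ", ")))
  }
  if (!nrow(transcripts) || !nrow(families)) return(empty_sites())
  seqs <- toupper(transcripts$sequence)
  if (any(!nzchar(seqs))) abort("transcript sequences must be non-empty")
  out <- purrr::map(seq_len(nrow(families)), function(i) {
    scan_one_family(
      seqs, transcripts$transcript_id, transcripts$gene_id,
      families$family_id[i], families$seed7[i]
    )
  })
  bind_rows(out) %>%
    filter(.data$site_type %in% site_types) %>%
    arrange(.data$family_id, .data$transcript_id, .data$site_start)
}

empty_sites <- function() {
  tibble(
    family_id = character(), transcript_id = character(),
    gene_id = character(), site_start = integer(), site_end = integer(),
    site_type = character(), program = character()
  )
}

scan_one_family <- function(seqs, transcript_ids, gene_ids, family_id, seed) {
  stopifnot(nchar(seed) == 7L)
  seed_dna <- rna_to_dna(seed)
  core6 <- revcomp_dna(substr(seed_dna, 1L, 6L))    # complements seed 2-7
  m8_base <- revcomp_dna(substr(seed_dna, 7L, 7L))  # complements seed 8
  # overlap = TRUE: two core matches 1-5 bp apart are distinct loci
  loc <- stringi::stri_locate_all_fixed(seqs, core6, overlap = TRUE,
                                        omit_no_match = TRUE)
  hits_per_seq <- vapply(loc, nrow, integer(1))
  if (sum(hits_per_seq) == 0L) return(empty_sites())
  idx <- rep(seq_along(seqs), hits_per_seq)
  p1 <- unlist(lapply(loc, function(m) m[, 1L]), use.names = FALSE) # 1-based
  seq_at <- seqs[idx]
  len <- nchar(seq_at)
  has_m8 <- p1 > 1L & substr(seq_at, p1 - 1L, p1 - 1L) == m8_base
  has_a1 <- p1 + 6L <= len & substr(seq_at, p1 + 6L, p1 + 6L) == "A"
  type <- case_when(
    has_m8 & has_a1 ~ "8mer",
    has_m8 ~ "7mer-m8",
    has_a1 ~ "7mer-A1",
    TRUE ~ "6mer"
  )
  start0 <- ifelse(has_m8, p1 - 2L, p1 - 1L)  # 0-based
  end0 <- ifelse(has_a1, p1 + 6L, p1 + 5L)    # half-open (= 1-based last)
  tibble(
    family_id = family_id,
    transcript_id = transcript_ids[idx],
    gene_id = gene_ids[idx],
    site_start = as.integer(start0),
    site_end = as.integer(end0),
    site_type = type,
    program = "builtin"
  )
}
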