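# Seed arithmetic. miRNA seeds are read off the mature sequence (RNA,
# 5'->3'): positions 2-8 form the 7-nt seed; its reverse complement in DNA
# is what a target transcript carries.

rna_to_dna <- function(x) chartr("Uu", "Tt", toupper(x))

revcomp_dna <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Seed of a mature miRNA sequence
#'
#' Positions 2-8 (the 7-nt seed) of a mature miRNA sequence, in RNA alphabet.
#'
#' @param mature_sequence Character vector of mature sequences (A/C/G/U).
#' @return Character vector of 7-mers.
#' @export
seed7 <- function(mature_sequence) {
  stopifnot(all(nchar(mature_sequence) >= 8L))
  toupper(substr(mature_sequence, 2L, 8L))
}

validate_mirna_catalog <- function(mirnas) {
  required <- c("mirna_id", "family_id", "mature_sequence")
  missing <- setdiff(required, names(mirnas))
  if (length(missing)) {
    abort(paste0("miRNA catalog missing columns: ", paste(missing, collapse = ", ")))
  }
  seqs <- toupper(mirnas$mature_sequence)
  if (any(nchar(seqs) < 8L)) {
    abort("mature sequences must be at least 8 nt")
  }
  if (any(grepl("[^ACGU]", seqs))) {
    abort("mature sequences must use the RNA alphabet A/C/G/U")
  }
  invisible(mirnas)
}

#' Collapse miRNAs into seed families
#'
#' Groups a miRNA catalog by `family_id`; miRNAs with an empty or missing
#' family become singleton families named after the miRNA itself, so no
#' catalog entry is silently dropped. All members of a family must share
#' seed positions 2-8 (that shared 7-mer is the family seed, the unit the
#' ceRNA test counts).
#'
#' @param mirnas Tibble with columns `mirna_id`, `family_id`,
#'   `mature_sequence`.
#' @return Tibble with one row per family: `family_id`, `seed7`,
#'   `n_members`, `member_ids` (comma-joined).
#' @examples
#' mirnas <- tibble::tibble(
#'   mirna_id = c("miR-a", "miR-b", "miR-c"),
#'   family_id = c("F1", "F1", ""),
#'   mature_sequence = c("UAGCUUAUCAGACUGAUGUUGA", "UAGCUUAUCAGUCUGAUGUUGA",
#'                       "UGGAAGACUAGUGAUUUUGUUGU")
#' )
#' collapse_families(mirnas)
#' @export
collapse_families <- function(mirnas) {
  if (nrow(mirnas) == 0L) {
    return(tibble(family_id = character(), seed7 = character(),
                  n_members = integer(), member_ids = character()))
  }
  validate_mirna_catalog(mirnas)
  fams <- mirnas %>%
    mutate(
      family_id = ifelse(is.na(.data$family_id) | !nzchar(.data$family_id),
                         .data$mirna_id, .data$family_id),
      seed = seed7(.data$mature_sequence)
    ) %>%
    group_by(.data$family_id) %>%
    summarise(
      n_seeds = dplyr::n_distinct(.data$seed),
      seed7 = .data$seed[1],
      n_members = n(),
      member_ids = paste(.data$mirna_id, collapse = ","),
      .groups = "drop"
    )
  bad <- fams$family_id[fams$n_seeds > 1L]
  if (length(bad)) {
    abort(paste0("families with discordant seeds (positions 2-8): ",
                 paste(bad, collapse = ", ")))
  }
  fams %>% select("family_id", "seed7", "n_members", "member_ids") %>%
    arrange(.data$family_id)
}

#' Map miRNA identifiers to family identifiers
#'
#' @param mirna_id Character vector of miRNA ids.
#' @param mirnas The miRNA catalog tibble.
#' @return Character vector of family ids (`NA` for ids absent from the
#'   catalog). Unassigned miRNAs map to their singleton family (their own
#'   id), mirroring [collapse_families()].
#' @export
family_of <- function(mirna_id, mirnas) {
  fam <- ifelse(is.na(mirnas$family_id) | !nzchar(mirnas$family_id),
                mirnas$mirna_id, mirnas$family_id)
  fam[match(mirna_id, mirnas$mirna_id)]
}
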