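BIOTYPE_MAP <- c(
  protein_coding = "protein_coding",
  processed_transcript = "lncRNA", lincRNA = "lncRNA",
  `3prime_overlapping_ncrna` = "lncRNA", antisense = "lncRNA",
  non_coding = "lncRNA", sense_intronic = "lncRNA",
  sense_overlapping = "lncRNA",
  snRNA = "sncRNA", snoRNA = "sncRNA", rRNA = "sncRNA", Mt_tRNA = "sncRNA",
  Mt_rRNA = "sncRNA", misc_RNA = "sncRNA", miRNA = "sncRNA",
  polymorphic_pseudogene = "pseudogene", pseudogene = "pseudogene",
  IG_C_pseudogene = "pseudogene", IG_J_pseudogene = "pseudogene",
  IG_V_pseudogene = "pseudogene", TR_V_pseudogene = "pseudogene",
  TR_J_pseudogene = "pseudogene",
  circRNA = "circRNA"
)

#' Classify an annotation gene biotype into a coarse transcript class
#'
#' Maps GENCODE-style gene-biotype strings onto the coarse classes used for
#' target-gene stratification: `protein_coding`, `lncRNA`, `sncRNA`,
#' `pseudogene`, `circRNA`; any unlisted biotype maps to `other`.
#'
#' @param gene_biotype Character vector of biotype strings.
#' @return Character vector of classes.
#' @examples
#' classify_biotype(c("lincRNA", "TR_J_pseudogene", "made_up"))
#' @export
classify_biotype <- function(gene_biotype) {
  out <- unname(BIOTYPE_MAP[gene_biotype])
  out[is.na(out)] <- "other"
  out
}

#' Read a transcriptome bundle (FASTA sequences plus annotation table)
#'
#' @param fasta_path Transcript sequences, FASTA; record names must match
#'   `transcript_id` in the table.
#' @param table_path TSV with columns `transcript_id`, `gene_id`,
#'   `gene_symbol`, `gene_biotype`.
#' @return Tibble with those columns plus `biotype_class` and `sequence`.
#' @export
read_transcriptome <- function(fasta_path, table_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  tab <- readr::read_tsv(table_path, show_col_types = FALSE, progress = FALSE)
  required <- c("transcript_id", "gene_id", "gene_symbol", "gene_biotype")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    abort(paste0("transcript table missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  ids <- sub("\\s.*$", "", names(seqs))
  hit <- match(tab$transcript_id, ids)
  if (anyNA(hit)) {
    abort(paste0("transcripts absent from FASTA: ",
                 paste(tab$transcript_id[is.na(hit)][1:5], collapse = ", ")))
  }
  tab %>%
    mutate(
      biotype_class = classify_biotype(.data$gene_biotype),
      sequence = as.character(seqs[hit])
    )
}

#' Project transcript-space sites to genomic coordinates
#'
#' Uses an exon table (0-based half-open genomic intervals, `exon_rank`
#' ordered 5' to 3' along the transcript) to place each transcript-space
#' site on the genome. Sites that span an exon junction are not split: they
#' keep transcript-space coordinates only and are flagged
#' (`spans_junction = TRUE`, genomic columns `NA`).
#'
#' @param sites Predicted-site tibble from [scan_seed_sites()].
#' @param exons Tibble with columns `transcript_id`, `chrom`, `start`,
#'   `end`, `strand`, `exon_rank`.
#' @return `sites` with `chrom`, `start`, `end`, `strand`,
#'   `spans_junction` appended (genomic coordinates, 0-based half-open).
#' @export
project_sites_to_genome <- function(sites, exons) {
  ex <- exons %>%
    arrange(.data$transcript_id, .data$exon_rank) %>%
    group_by(.data$transcript_id) %>%
    mutate(
      width = .data$end - .data$start,
      tx_off = cumsum(dplyr::lag(.data$width, default = 0L))
    ) %>%
    ungroup()
  joined <- sites %>%
    mutate(.row = row_number()) %>%
    left_join(ex, by = "transcript_id", relationship = "many-to-many") %>%
    filter(.data$site_start >= .data$tx_off,
           .data$site_end <= .data$tx_off + .data$width) %>%
    distinct(.data$.row, .keep_all = TRUE)
  res <- sites %>%
    mutate(.row = row_number()) %>%
    left_join(
      joined %>%
        mutate(
          g_start = ifelse(.data$strand == "-",
                           .data$end - (.data$site_end - .data$tx_off),
                           .data$start + (.data$site_start - .data$tx_off)),
          g_end = ifelse(.data$strand == "-",
                         .data$end - (.data$site_start - .data$tx_off),
                         .data$start + (.data$site_end - .data$tx_off))
        ) %>%
        select(".row", "chrom", g_start2 = "g_start", g_end2 = "g_end",
               strand2 = "strand"),
      by = ".row"
    ) %>%
    mutate(
      start = as.integer(.data$g_start2),
      end = as.integer(.data$g_end2),
      strand = ifelse(is.na(.data$strand2), ".", .data$strand2),
      spans_junction = is.na(.data$g_start2) &
        .data$transcript_id %in% exons$transcript_id
    ) %>%
    select(-".row", -"g_start2", -"g_end2", -"strand2")
  res
}
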