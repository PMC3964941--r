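#' Read CLIP binding-site clusters from a BED file
#'
#' Parses BED (3 to 6 columns) into a tibble of binding-site clusters in the
#' BED convention: 0-based, half-open `[start, end)` coordinates. Lines
#' starting with `#`, `track` or `browser` are skipped. A missing strand
#' column becomes `"."` (matches either strand in overlap operations); a
#' missing score column becomes a read count of 0.
#'
#' @param path Path to a BED file, or a character vector of BED lines.
#' @param experiment_id Experiment identifier stamped on every cluster.
#' @return A tibble with columns `chrom`, `start`, `end`, `cluster_id`,
#'   `read_count`, `strand`, `experiment_id`.
#' @examples
#' read_bed(c("chr1\t100\t200\tc1\t15\t+"), experiment_id = "E1")
#' @export
read_bed <- function(path, experiment_id = NA_character_) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(tibble(
      chrom = character(), start = integer(), end = integer(),
      cluster_id = character(), read_count = integer(),
      strand = character(), experiment_id = character()
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    abort(sprintf("BED parse error: fewer than 3 fields at line %d", lineno[which(nf < 3L)[1]]))
  }
  grab <- function(i, default) {
    vapply(fields, function(f) if (length(f) >= i) f[[i]] else default, character(1))
  }
  start <- suppressWarnings(as.integer(grab(2L, NA_character_)))
  end <- suppressWarnings(as.integer(grab(3L, NA_character_)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    abort(sprintf("BED parse error: non-integer start/end at line %d", lineno[bad[1]]))
  }
  bad <- which(end <= start)
  if (length(bad)) {
    abort(sprintf("BED parse error: end <= start at line %d", lineno[bad[1]]))
  }
  name <- grab(4L, "")
  name[!nzchar(name)] <- paste0("cluster_", seq_len(sum(!nzchar(name))))
  score <- suppressWarnings(as.integer(grab(5L, "0")))
  score[is.na(score)] <- 0L
  strand <- grab(6L, ".")
  strand[!strand %in% STRANDS] <- "."
  tibble(
    chrom = grab(1L, NA_character_), start = start, end = end,
    cluster_id = name, read_count = score, strand = strand,
    experiment_id = as.character(experiment_id)
  )
}

#' Write intervals to a BED6 file
#'
#' Inverse of [read_bed()] on the retained fields (chrom, start, end, name,
#' score, strand).
#'
#' @param x Tibble with columns `chrom`, `start`, `end` and optionally
#'   `cluster_id`, `read_count`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  bed <- tibble(
    chrom = x$chrom, start = x$start, end = x$end,
    name = x$cluster_id %||% ".",
    score = x$read_count %||% 0L,
    strand = x$strand %||% "."
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Read a CLIP experiment collection from a metadata sidecar
#'
#' The sidecar is a TSV with columns `experiment_id`, `rbp_name`,
#' `cell_line`, `protocol`, `bed_path` (relative paths resolved against the
#' sidecar's directory). Each referenced BED file is read with [read_bed()].
#'
#' @param path Path to the sidecar TSV.
#' @return A list with `experiments` (the metadata tibble) and `clusters`
#'   (one tibble of all clusters, stamped with their `experiment_id`).
#' @export
read_clip_experiments <- function(path) {
  meta <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("experiment_id", "rbp_name", "cell_line", "protocol", "bed_path")
  missing <- setdiff(required, names(meta))
  if (length(missing)) {
    abort(paste0("experiment sidecar missing columns: ", paste(missing, collapse = ", ")))
  }
  base <- dirname(path)
  clusters <- purrr::map2(meta$bed_path, meta$experiment_id, function(bp, eid) {
    full <- if (file.exists(bp)) bp else file.path(base, bp)
    read_bed(full, experiment_id = eid)
  })
  list(experiments = meta, clusters = bind_rows(clusters))
}
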