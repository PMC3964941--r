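#' Overlap length between genomic intervals
#'
#' Length in bp of the intersection of two intervals in 0-based half-open
#' coordinates. Zero when the chromosomes differ, when strand matching is
#' required and the strands conflict, or when the intervals do not intersect
#' (adjacent intervals share 0 bp). Strand `"."` is compatible with any
#' strand. Vectorised over all arguments.
#'
#' @param chrom_a,start_a,end_a,strand_a First interval.
#' @param chrom_b,start_b,end_b,strand_b Second interval.
#' @param same_strand_required Require strand compatibility (default `TRUE`).
#' @return Integer vector of overlap lengths (bp), `>= 0`.
#' @examples
#' overlap_length("chr1", 0, 10, "+", "chr1", 5, 15, "+")  # 5
#' overlap_length("chr1", 0, 10, "+", "chr1", 10, 20, "+") # 0, half-open
#' @export
overlap_length <- function(chrom_a, start_a, end_a, strand_a,
                           chrom_b, start_b, end_b, strand_b,
                           same_strand_required = TRUE) {
  ov <- pmax(0L, pmin(end_a, end_b) - pmax(start_a, start_b))
  ok <- chrom_a == chrom_b
  if (same_strand_required) {
    ok <- ok & (strand_a == strand_b | strand_a == "." | strand_b == ".")
  }
  as.integer(ov * ok)
}

as_granges0 <- function(x, normalize_chr = FALSE) {
  chrom <- as.character(x$chrom)
  if (normalize_chr) chrom <- sub("^chr", "", chrom)
  strand <- as.character(x$strand %||% rep(".", nrow(x)))
  strand[strand == "."] <- "*"
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
}

#' Annotate sites with CLIP-cluster support
#'
#' For each site, counts the distinct CLIP experiments with at least one
#' cluster overlapping it by `min_overlap` bp or more, and the total read
#' count of all overlapping clusters. A site is CLIP-supported when at least
#' one experiment supports it; multiple clusters from the same experiment
#' count as one supporting experiment.
#'
#' Overlap is strand-aware by default (Argonaute binds the transcribed
#' strand); strand `"."`/`"*"` matches either strand.
#'
#' @param sites Tibble with columns `chrom`, `start`, `end`, `strand`
#'   (0-based half-open).
#' @param clusters Tibble of CLIP clusters as from [read_bed()], with
#'   `experiment_id` and `read_count`.
#' @param min_overlap Minimum overlap in bp for a cluster to count
#'   (default 1, BEDTools-style any-overlap).
#' @param same_strand_required Require strand compatibility (default `TRUE`).
#' @param normalize_chr Strip a leading `"chr"` from chromosome names on both
#'   sides before comparing (default `FALSE`: exact string match).
#' @return `sites` with columns `supporting_experiments`,
#'   `total_overlapping_read_count` and `is_clip_supported` appended.
#' @export
annotate_clip_support <- function(sites, clusters, min_overlap = 1L,
                                  same_strand_required = TRUE,
                                  normalize_chr = FALSE) {
  stopifnot(min_overlap >= 1L)
  n_sites <- nrow(sites)
  supp <- integer(n_sites)
  reads <- integer(n_sites)
  if (n_sites > 0L && nrow(clusters) > 0L) {
    gr_sites <- as_granges0(sites, normalize_chr)
    gr_clust <- as_granges0(clusters, normalize_chr)
    hits <- suppressWarnings(GenomicRanges::findOverlaps(
      gr_sites, gr_clust,
      minoverlap = min_overlap,
      ignore.strand = !same_strand_required
    ))
    if (length(hits)) {
      q <- S4Vectors::queryHits(hits)
      s <- S4Vectors::subjectHits(hits)
      agg_r <- rowsum(as.numeric(clusters$read_count[s]), q)
      reads[as.integer(rownames(agg_r))] <- as.integer(agg_r[, 1])
      eid <- clusters$experiment_id[s]
      uniq <- !duplicated(paste(q, eid, sep = "\r"))
      agg_e <- rowsum(rep(1, sum(uniq)), q[uniq])
      supp[as.integer(rownames(agg_e))] <- as.integer(agg_e[, 1])
    }
  }
  sites %>%
    mutate(
      supporting_experiments = supp,
      total_overlapping_read_count = reads,
      is_clip_supported = supp >= 1L
    )
}
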