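pred_file <- function(rows) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  readr::write_tsv(rows, path)
  path
}

test_that("external predictions load and map miRNAs to families", {
  rows <- tibble::tibble(
    program = c("TargetScan", "PITA", "FancyNew", "TargetScan"),
    mirna_id = c("miR-a1", "miR-a2", "miR-b", "absent-miR"),
    gene_id = c("G1", "G1", "G2", "G3"),
    chrom = "chr1", start = c(10L, 12L, 40L, 5L), end = c(17L, 19L, 47L, 12L),
    strand = "+"
  )
  expect_warning(
    expect_warning(x <- load_program_predictions(pred_file(rows),
                                                 tiny_catalog()),
                   "unknown program"),
    "dropped")
  expect_equal(nrow(x), 3L)
  expect_equal(attr(x, "dropped"), 1L)
  # both famA members map to the same family
  expect_equal(x$family_id[1:2], c("famA", "famA"))
  expect_equal(x$program[3], "FancyNew")  # literal tag preserved
})

test_that("overlapping same-family sites merge transitively with program union", {
  sites <- tibble::tibble(
    family_id = "famA", gene_id = "G",
    start = c(10L, 12L, 30L), end = c(17L, 19L, 37L),
    program = c("TargetScan", "PITA", "RNA22")
  )
  m <- merge_evidence(sites)
  expect_equal(nrow(m), 2L)
  expect_equal(m$start, c(10L, 30L))
  expect_equal(m$end, c(19L, 37L))
  expect_equal(m$programs[1], "PITA,TargetScan")
  expect_equal(m$program_count, c(2L, 1L))

  # adjacency (half-open) does not merge
  adj <- merge_evidence(tibble::tibble(
    family_id = "f", gene_id = "G", start = c(0L, 7L), end = c(7L, 14L),
    program = "builtin"))
  expect_equal(nrow(adj), 2L)

  # five programs on one locus
  five <- merge_evidence(tibble::tibble(
    family_id = "f", gene_id = "G", start = 10L + 0:4, end = 18L + 0:4,
    program = c("TargetScan", "miRanda", "PITA", "PicTar2", "RNA22")))
  expect_equal(five$program_count, 5L)
})

test_that("merging is idempotent and order-independent", {
  set.seed(404)
  sites <- tibble::tibble(
    family_id = sample(c("f1", "f2"), 200, replace = TRUE),
    gene_id = sample(c("G1", "G2", "G3"), 200, replace = TRUE),
    start = sample.int(500, 200, replace = TRUE),
    program = sample(c("TargetScan", "PITA", "builtin"), 200, replace = TRUE)
  ) |>
    dplyr::mutate(end = start + sample(6:9, 200, replace = TRUE))
  m1 <- merge_evidence(sites)
  m2 <- merge_evidence(sites[sample.int(nrow(sites)), ])
  expect_equal(m1, m2)
  remerged <- merge_evidence(
    m1 |> dplyr::mutate(program = programs) |> dplyr::select(-programs))
  expect_equal(remerged$start, m1$start)
  expect_equal(remerged$end, m1$end)
  expect_equal(remerged$program_count, m1$program_count)
})

test_that("stringency filtering combines experiment and program thresholds", {
  sites <- tibble::tibble(
    family_id = "f", gene_id = c("G1", "G2", "G3"),
    start = 1L, end = 9L, programs = "x",
    program_count = c(3L, 5L, 1L),
    supporting_experiments = c(2L, 0L, 1L)
  )
  expect_equal(filter_interactions(sites, 1, 3)$gene_id, "G1")
  expect_equal(filter_interactions(sites, 1, 1)$gene_id, c("G1", "G3"))
  expect_equal(nrow(filter_interactions(sites, 0, 0)), 3L)
  expect_error(filter_interactions(sites, -1, 0), "non-negative")
})

test_that("transcript-space sites project through single-exon mappings", {
  sites <- tibble::tibble(
    family_id = "f", transcript_id = c("tp", "tm", "tu"), gene_id = "g",
    site_start = 10L, site_end = 18L, site_type = "8mer", program = "builtin"
  )
  exons <- tibble::tibble(
    transcript_id = c("tp", "tm"), chrom = "chr1",
    start = c(1000L, 2000L), end = c(1500L, 2400L),
    strand = c("+", "-"), exon_rank = 1L
  )
  p <- project_sites_to_genome(sites, exons)
  expect_equal(p$start[p$transcript_id == "tp"], 1010L)
  expect_equal(p$end[p$transcript_id == "tp"], 1018L)
  # minus strand counts from the exon's genomic end
  expect_equal(p$start[p$transcript_id == "tm"], 2400L - 18L)
  expect_equal(p$end[p$transcript_id == "tm"], 2400L - 10L)
  # unmapped transcript keeps NA coordinates without a junction flag
  expect_true(is.na(p$start[p$transcript_id == "tu"]))
  expect_false(p$spans_junction[p$transcript_id == "tu"])
})

test_that("sites spanning an exon junction are flagged, not split", {
  sites <- tibble::tibble(
    family_id = "f", transcript_id = "t2", gene_id = "g",
    site_start = c(5L, 98L), site_end = c(13L, 106L),
    site_type = "8mer", program = "builtin"
  )
  exons <- tibble::tibble(
    transcript_id = "t2", chrom = "chr1",
    start = c(0L, 500L), end = c(100L, 700L), strand = "+",
    exon_rank = c(1L, 2L)
  )
  p <- project_sites_to_genome(sites, exons)
  expect_equal(p$spans_junction, c(FALSE, TRUE))
  expect_equal(p$start[1], 5L)
  expect_true(is.na(p$start[2]))
})
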