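small_cfg <- function(seed = 7, ...) {
  fixture_config(rng_seed = seed, n_families = 30, n_genes = 30,
                 n_planted_pairs = 4, n_experiments = 2,
                 n_decoy_clusters = 10, ...)
}

test_that("identical configs emit byte-identical bundles", {
  b1 <- simulate_universe(small_cfg(), withr::local_tempdir())
  b2 <- simulate_universe(small_cfg(), withr::local_tempdir())
  f1 <- sort(list.files(b1$dir))
  expect_equal(f1, sort(list.files(b2$dir)))
  h1 <- unname(tools::md5sum(file.path(b1$dir, f1)))
  h2 <- unname(tools::md5sum(file.path(b2$dir, f1)))
  expect_equal(h1, h2)
  # a different seed changes the content
  b3 <- simulate_universe(small_cfg(seed = 8), withr::local_tempdir())
  expect_false(all(unname(tools::md5sum(file.path(b3$dir, f1))) == h1))
})

test_that("re-scanning the emitted bundle reproduces the planted truth", {
  b <- simulate_universe(small_cfg(), withr::local_tempdir())
  tx <- read_transcriptome(b$paths$fasta, b$paths$transcripts)
  fams <- collapse_families(
    readr::read_tsv(b$paths$mirnas, show_col_types = FALSE))
  got <- scan_seed_sites(tx, fams) |>
    dplyr::arrange(transcript_id, site_start)
  want <- b$truth_sites |>
    dplyr::arrange(transcript_id, site_start)
  expect_equal(got$transcript_id, want$transcript_id)
  expect_equal(got$family_id, want$family_id)
  expect_equal(got$site_start, want$site_start)
  expect_equal(got$site_end, want$site_end)
  expect_equal(unique(got$site_type), "8mer")
})

test_that("p_support saturates or zeroes CLIP support of planted sites", {
  b1 <- simulate_universe(small_cfg(), withr::local_tempdir())
  clip <- read_clip_experiments(b1$paths$experiments)
  proj <- b1$truth_sites |> dplyr::select(chrom, start, end, strand)
  ann <- annotate_clip_support(proj, clip$clusters)
  expect_true(all(ann$supporting_experiments == 2L))  # p_support = 1, E = 2

  b0 <- simulate_universe(small_cfg(p_support = 0), withr::local_tempdir())
  clip0 <- read_clip_experiments(b0$paths$experiments)
  ann0 <- annotate_clip_support(
    b0$truth_sites |> dplyr::select(chrom, start, end, strand),
    clip0$clusters)
  expect_true(all(ann0$supporting_experiments == 0L))
  expect_equal(b0$truth_sites$n_supporting, rep(0, nrow(b0$truth_sites)))
})

test_that("infeasible fixture configurations are rejected", {
  expect_error(fixture_config(p_support = 1.5), "p_support")
  expect_error(fixture_config(planted_shared = 11, families_per_gene = 10),
               "planted_shared")
  expect_error(fixture_config(n_genes = 10, n_planted_pairs = 20), "planted")
  expect_error(fixture_config(transcript_length = c(100, 120)),
               "too short")
})

test_that("null profiles draw independent uniform k-subsets", {
  expect_error(simulate_null_profiles(10, 20, 0), "k must be >= 1")
  expect_error(simulate_null_profiles(10, 20, 25), "k > F")
  # degenerate k = F: every pair shares everything
  prof <- simulate_null_profiles(4, 6, 6, rng_seed = 3)
  fl <- strsplit(prof$families, ",")
  expect_true(all(lengths(fl) == 6))
  expect_equal(length(intersect(fl[[1]], fl[[2]])), 6L)

  # shared counts between disjoint gene pairs follow hypergeometric(F, k, k):
  # check the mean against k^2 / F within 3 standard errors
  prof <- simulate_null_profiles(2000, 40, 5, rng_seed = 4)
  fl <- strsplit(prof$families, ",")
  cc <- vapply(seq_len(1000), function(i) {
    length(intersect(fl[[2 * i - 1]], fl[[2 * i]]))
  }, integer(1))
  mu <- 5 * 5 / 40
  sdv <- sqrt(sum((0:5 - mu)^2 * (dhyper(0:5, 5, 35, 5))))
  expect_lt(abs(mean(cc) - mu), 3 * sdv / sqrt(1000))
  # deterministic for a fixed seed
  expect_equal(simulate_null_profiles(50, 20, 4, rng_seed = 9),
               simulate_null_profiles(50, 20, 4, rng_seed = 9))
})
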