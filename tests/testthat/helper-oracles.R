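# Independent oracles used to validate the package's implementations.
# Each deliberately uses different mechanics than the code under test.

# Exact rational enumeration of the hypergeometric upper tail. For N <= 40
# every choose() value is below 2^53, so the arithmetic is exact.
enum_hyper_tail <- function(N, K, n, c) {
  t <- c:min(K, n)
  sum(choose(K, t) * choose(N - K, n - t)) / choose(N, n)
}

# Pure-regex seed-site oracle: one zero-width lookaround pattern per site
# class, run with base gregexpr (PCRE), independent of the stringr-based
# core-and-extend scanner.
regex_scan_oracle <- function(sequence, seed7_rna, include_6mer = FALSE) {
  seed_dna <- chartr("Uu", "Tt", toupper(seed7_rna))
  m8 <- paste(rev(strsplit(chartr("ACGT", "TGCA", seed_dna), "")[[1]]),
              collapse = "")
  f <- substr(m8, 1, 1)
  s6 <- substr(m8, 2, 7)
  hit_rows <- function(pattern, type, off_end) {
    h <- gregexpr(pattern, sequence, perl = TRUE)[[1]]
    h <- h[h > 0]
    if (!length(h)) return(NULL)
    data.frame(p = h, type = type, off_end = off_end)
  }
  rows <- list(
    hit_rows(sprintf("(?=%sA)", m8), "8mer", 7L),
    hit_rows(sprintf("(?=%s(?!A))", m8), "7mer-m8", 6L),
    hit_rows(sprintf("(?<!%s)(?=%sA)", f, s6), "7mer-A1", 6L),
    if (include_6mer) hit_rows(sprintf("(?<!%s)(?=%s(?!A))", f, s6),
                               "6mer", 5L)
  )
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out)) {
    return(data.frame(site_start = integer(), site_end = integer(),
                      site_type = character()))
  }
  res <- data.frame(site_start = out$p - 1L, site_end = out$p + out$off_end,
                    site_type = out$type)
  res[order(res$site_start), , drop = FALSE]
}

# O(sites x clusters) brute-force CLIP support, plain loops and arithmetic.
brute_support <- function(sites, clusters, min_overlap = 1,
                          same_strand = TRUE) {
  n <- nrow(sites)
  supp <- integer(n)
  reads <- integer(n)
  for (i in seq_len(n)) {
    ov <- pmax(0, pmin(sites$end[i], clusters$end) -
                 pmax(sites$start[i], clusters$start))
    ok <- clusters$chrom == sites$chrom[i]
    if (same_strand) {
      ok <- ok & (clusters$strand == sites$strand[i] |
                    clusters$strand == "." | sites$strand[i] == ".")
    }
    hit <- ok & ov >= min_overlap
    supp[i] <- length(unique(clusters$experiment_id[hit]))
    reads[i] <- sum(clusters$read_count[hit])
  }
  list(supporting_experiments = supp, total_overlapping_read_count = reads)
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_start = 10000,
                             max_len = 500) {
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = sample.int(max_start, n, replace = TRUE) - 1L,
    end = 0L,
    strand = sample(c("+", "-", "."), n, replace = TRUE)
  ) |>
    dplyr::mutate(end = start + sample.int(max_len, n, replace = TRUE))
}

random_rna_seed <- function() {
  paste(sample(c("A", "C", "G", "U"), 7, replace = TRUE), collapse = "")
}

random_dna_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

tiny_catalog <- function() {
  tibble::tibble(
    mirna_id = c("miR-a1", "miR-a2", "miR-b", "miR-c"),
    family_id = c("famA", "famA", "famB", ""),
    mature_sequence = c(
      "UAGCUUAUCAGACUGAUGUUGA",  # seed AGCUUAU
      "AAGCUUAUCAGUCUGAUGUUGA",  # same positions 2-8
      "UGGAAGACUAGUGAUUUUGUUGU",
      "UUCAAGUAAUCCAGGAUAGGCU"
    )
  )
}
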