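# Deterministic synthetic universes with planted ground truth: miRNA
# families with unique seeds, transcripts carrying planted 8mer sites,
# CLIP clusters covering planted sites with a configurable probability,
# and a planted ceRNA / sponge structure. Every emitted file is derived
# from its own RNG stream (master seed + stable label), so adding an
# output never perturbs existing ones and identical configs are
# byte-identical.

stream_seed <- function(seed, label) {
  h <- 0
  for (code in utf8ToInt(label)) h <- (h * 31 + code) %% 2147483647
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

with_stream <- function(seed, label, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(stream_seed(seed, label))
  expr
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Configuration for a synthetic fixture universe
#'
#' Defaults describe the standard study conditions used throughout the
#' package's validation: 150 miRNA families (the prediction universe), 220
#' genes of which the first 40 form 20 planted ceRNA pairs sharing 8 of
#' their 10 families, 3 CLIP experiments each covering every planted site
#' (`p_support = 1`), 50 decoy clusters per experiment placed intergenic,
#' and one planted sponge transcript with 12 sites of one family.
#'
#' @param rng_seed Master seed; every emitted file derives its own RNG
#'   stream from it.
#' @param n_families Number of miRNA families (universe size `N`).
#' @param n_genes Number of genes (planted-pair genes included; the sponge
#'   transcript is added on top).
#' @param families_per_gene Families targeting each gene (`K`).
#' @param transcript_length Length range (bp) for transcripts.
#' @param n_experiments Number of CLIP experiments.
#' @param p_support Probability that a planted site is covered by a cluster
#'   in any given experiment.
#' @param n_decoy_clusters Decoy (intergenic) clusters per experiment.
#' @param n_planted_pairs Number of planted ceRNA pairs (consumes
#'   `2 * n_planted_pairs` genes).
#' @param planted_shared Shared-family count `c` of each planted pair.
#' @param sponge_sites Sites of one family on the planted sponge
#'   transcript (0 disables the sponge).
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(rng_seed = 1L, n_families = 150L, n_genes = 220L,
                           families_per_gene = 10L,
                           transcript_length = c(600L, 1200L),
                           n_experiments = 3L, p_support = 1,
                           n_decoy_clusters = 50L, n_planted_pairs = 20L,
                           planted_shared = 8L, sponge_sites = 12L) {
  cfg <- list(
    rng_seed = as.integer(rng_seed), n_families = as.integer(n_families),
    n_genes = as.integer(n_genes),
    families_per_gene = as.integer(families_per_gene),
    transcript_length = as.integer(transcript_length),
    n_experiments = as.integer(n_experiments), p_support = p_support,
    n_decoy_clusters = as.integer(n_decoy_clusters),
    n_planted_pairs = as.integer(n_planted_pairs),
    planted_shared = as.integer(planted_shared),
    sponge_sites = as.integer(sponge_sites)
  )
  if (cfg$p_support < 0 || cfg$p_support > 1) {
    abort("configuration error: p_support must lie in [0, 1]")
  }
  if (cfg$planted_shared > cfg$families_per_gene) {
    abort("configuration error: planted_shared > families_per_gene")
  }
  if (2L * cfg$n_planted_pairs > cfg$n_genes) {
    abort("configuration error: planted pairs need more genes than n_genes")
  }
  if (cfg$families_per_gene > cfg$n_families) {
    abort("configuration error: families_per_gene > n_families")
  }
  max_sites <- max(cfg$families_per_gene, cfg$sponge_sites)
  if (min(cfg$transcript_length) < max_sites * 20L + 60L) {
    abort("configuration error: transcripts too short for the planted sites")
  }
  structure(cfg, class = "fixture_config")
}

# Draw unique family seeds such that (a) each seed's 6-mer target core
# occurs exactly once in its own planted 8-mer string and (b) no core
# occurs in any other family's 8-mer string. This makes the scanner's
# family attribution on planted fixtures exact.
draw_family_seeds <- function(n_families) {
  seeds <- character(0)
  s8s <- character(0)
  cores <- character(0)
  tries <- 0L
  while (length(seeds) < n_families) {
    tries <- tries + 1L
    if (tries > n_families * 200L) {
      abort("failed to draw non-interfering family seeds")
    }
    cand <- paste(sample(c("A", "C", "G", "U"), 7, replace = TRUE),
                  collapse = "")
    cand_dna <- rna_to_dna(cand)
    s8 <- paste0(revcomp_dna(cand_dna), "A")
    core <- revcomp_dna(substr(cand_dna, 1L, 6L))
    own_hits <- gregexpr(core, s8, fixed = TRUE)[[1]]
    ok <- !cand %in% seeds &&
      length(own_hits) == 1L && own_hits[1] == 2L &&
      !any(vapply(cores, grepl, logical(1), x = s8, fixed = TRUE)) &&
      !any(vapply(s8s, function(s) grepl(core, s, fixed = TRUE), logical(1)))
    if (ok) {
      seeds <- c(seeds, cand)
      s8s <- c(s8s, s8)
      cores <- c(cores, core)
    }
  }
  list(seed7 = seeds, site8 = s8s, core6 = cores)
}

random_mature <- function(seed7) {
  vapply(seed7, function(s) {
    paste0(paste(sample(c("A", "C", "G", "U"), 1), collapse = ""), s,
           paste(sample(c("A", "C", "G", "U"), 14, replace = TRUE),
                 collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# Replace spurious occurrences of any family core by point mutations at
# positions outside planted windows until only planted sites remain.
scrub_sequence <- function(seq, cores, planted_start0, planted_end0) {
  protected <- integer(0)
  if (length(planted_start0)) {
    protected <- unlist(purrr::map2(planted_start0 + 1L, planted_end0,
                                    seq.int), use.names = FALSE)
  }
  planted_core_pos <- planted_start0 + 2L  # 1-based core position in an 8mer
  for (iter in seq_len(100L)) {
    spurious <- integer(0)
    for (core in cores) {
      hits <- gregexpr(core, seq, fixed = TRUE)[[1]]
      if (hits[1] == -1L) next
      # a planted position excuses exactly one core (cores are unique
      # 6-mers), so excusing by position is exact
      extra <- setdiff(hits, planted_core_pos)
      spurious <- c(spurious, lapply(extra, function(h) h:(h + 5L)))
    }
    spurious <- unique(unlist(spurious, use.names = FALSE))
    spurious <- setdiff(spurious, protected)
    if (!length(spurious)) {
      if (sequence_clean(seq, cores, planted_core_pos)) return(seq)
      abort("fixture error: spurious seed core inside a planted window")
    }
    pos <- spurious[sample.int(length(spurious), 1L)]
    old <- substr(seq, pos, pos)
    substr(seq, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
  }
  abort("fixture error: could not scrub spurious seed cores")
}

sequence_clean <- function(seq, cores, planted_core_pos) {
  all_hits <- unlist(lapply(cores, function(core) {
    h <- gregexpr(core, seq, fixed = TRUE)[[1]]
    h[h > 0L]
  }), use.names = FALSE)
  setequal(all_hits, planted_core_pos) && length(all_hits) ==
    length(planted_core_pos)
}

#' Simulate a synthetic universe with planted ground truth
#'
#' Emits, under `out_dir`, every file the pipeline consumes — transcript
#' FASTA, transcript/exon/miRNA TSV tables, per-experiment CLIP BED files
#' with a metadata sidecar, a toy GMT annotation — plus truth tables
#' (planted sites with per-experiment coverage flags, planted pair and
#' sponge structure). Planted sites are exact: family seeds are drawn so no
#' seed core collides with another family's planted string, and the
#' background sequence is point-mutation-scrubbed of every spurious core,
#' so a seed scan recovers precisely the planted sites.
#'
#' @param config A [fixture_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `dir`, file `paths`, and tibbles
#'   `truth_sites`, `truth_pairs`, `truth_sponges`.
#' @export
simulate_universe <- function(config, out_dir) {
  stopifnot(inherits(config, "fixture_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$rng_seed
  Fn <- config$n_families; G <- config$n_genes
  k <- config$families_per_gene

  fam <- with_stream(seed, "family_seeds", draw_family_seeds(Fn))
  family_id <- sprintf("SYNF%03d", seq_len(Fn))

  # miRNA catalog: every family has one member; the first five have a
  # second member sharing seed positions 2-8, exercising family collapsing.
  mirnas <- with_stream(seed, "mirna_catalog", {
    base <- tibble(
      mirna_id = sprintf("syn-miR-%03d-5p", seq_len(Fn)),
      family_id = family_id,
      mature_sequence = random_mature(fam$seed7)
    )
    extra_n <- min(5L, Fn)
    extra <- tibble(
      mirna_id = sprintf("syn-miR-%03db-5p", seq_len(extra_n)),
      family_id = family_id[seq_len(extra_n)],
      mature_sequence = random_mature(fam$seed7[seq_len(extra_n)])
    )
    bind_rows(base, extra) %>% arrange(.data$mirna_id)
  })

  # Family assignment: planted pairs first, then independent null genes.
  gene_id <- sprintf("g%04d", seq_len(G))
  assignments <- with_stream(seed, "gene_families", {
    out <- vector("list", G)
    pair_genes <- seq_len(2L * config$n_planted_pairs)
    i <- 1L
    while (i < 2L * config$n_planted_pairs) {
      fa <- sort(sample(Fn, k))
      shared <- sample(fa, config$planted_shared)
      fb <- sort(c(shared, sample(setdiff(seq_len(Fn), fa),
                                  k - config$planted_shared)))
      out[[i]] <- fa; out[[i + 1L]] <- fb
      i <- i + 2L
    }
    for (j in setdiff(seq_len(G), pair_genes)) {
      out[[j]] <- sort(sample(Fn, k))
    }
    out
  })

  truth_pairs <- if (config$n_planted_pairs > 0L) {
    idx <- seq_len(config$n_planted_pairs)
    tibble(
      gene_a = gene_id[2L * idx - 1L], gene_b = gene_id[2L * idx],
      n_shared = vapply(idx, function(i) {
        length(intersect(assignments[[2L * i - 1L]], assignments[[2L * i]]))
      }, integer(1))
    )
  } else {
    tibble(gene_a = character(), gene_b = character(), n_shared = integer())
  }

  # Sponge transcript: one extra gene carrying sponge_sites sites of the
  # first family (CDR1as-like, biotype circRNA).
  has_sponge <- config$sponge_sites > 0L
  all_gene_id <- gene_id
  if (has_sponge) all_gene_id <- c(gene_id, "sponge01")
  site_fams <- c(assignments,
                 if (has_sponge) list(rep(1L, config$sponge_sites)))

  biotypes <- with_stream(seed, "biotypes", {
    bt <- sample(c("protein_coding", "lincRNA", "pseudogene", "antisense",
                   "snoRNA"),
                 G, replace = TRUE, prob = c(0.6, 0.15, 0.1, 0.1, 0.05))
    if (has_sponge) c(bt, "circRNA") else bt
  })

  # Transcript sequences with planted 8mer sites, then genome layout:
  # single-exon transcripts laid end-to-end on chr1 with 200 bp gaps.
  lens <- with_stream(seed, "transcript_lengths", {
    sample(seq(config$transcript_length[1], config$transcript_length[2]),
           length(all_gene_id), replace = TRUE)
  })
  strands <- with_stream(seed, "strands", {
    sample(c("+", "-"), length(all_gene_id), replace = TRUE)
  })

  n_tx <- length(all_gene_id)
  tx_id <- paste0("tx_", all_gene_id)
  gap <- 200L
  g_start <- cumsum(c(gap, utils::head(lens, -1) + gap))
  g_end <- g_start + lens

  seqs <- character(n_tx)
  site_rows <- vector("list", n_tx)
  for (i in seq_len(n_tx)) {
    made <- with_stream(seed, paste0("sequence_", tx_id[i]), {
      L <- lens[i]
      fams_i <- site_fams[[i]]
      ns <- length(fams_i)
      slot <- (L - 60L) %/% max(ns, 1L)
      # jitter keeps consecutive planted starts >= 20 bp apart, so sites
      # (8 bp) stay >= 12 bp clear of each other
      jitter <- sample.int(max(1L, slot - 19L), ns, replace = TRUE) - 1L
      starts0 <- 30L + (seq_len(ns) - 1L) * slot + jitter
      s <- random_dna(L)
      for (j in seq_len(ns)) {
        substr(s, starts0[j] + 1L, starts0[j] + 8L) <- fam$site8[fams_i[j]]
      }
      s <- scrub_sequence(s, fam$core6, starts0, starts0 + 8L)
      list(seq = s, starts0 = starts0, fams_i = fams_i)
    })
    seqs[i] <- made$seq
    site_rows[[i]] <- tibble(
      transcript_id = tx_id[i], gene_id = all_gene_id[i],
      family_id = family_id[made$fams_i],
      site_start = made$starts0, site_end = made$starts0 + 8L,
      site_type = "8mer"
    )
  }

  truth_sites <- bind_rows(site_rows) %>%
    mutate(
      chrom = "chr1",
      strand = strands[match(.data$transcript_id, tx_id)],
      start = ifelse(.data$strand == "-",
                     g_end[match(.data$transcript_id, tx_id)] - .data$site_end,
                     g_start[match(.data$transcript_id, tx_id)] + .data$site_start),
      end = .data$start + 8L
    )

  # Per-experiment coverage of planted sites plus intergenic decoys.
  experiments <- tibble(
    experiment_id = sprintf("E%02d", seq_len(config$n_experiments)),
    rbp_name = "AGO2",
    cell_line = sprintf("CELL%d", seq_len(config$n_experiments)),
    protocol = rep(c("HITS-CLIP", "PAR-CLIP", "iCLIP"),
                   length.out = config$n_experiments),
    bed_path = sprintf("clip_E%02d.bed", seq_len(config$n_experiments))
  )
  cover_flags <- matrix(FALSE, nrow(truth_sites), config$n_experiments)
  beds <- vector("list", config$n_experiments)
  for (e in seq_len(config$n_experiments)) {
    made <- with_stream(seed, paste0("clip_", experiments$experiment_id[e]), {
      covered <- stats::runif(nrow(truth_sites)) < config$p_support
      planted <- truth_sites[covered, ]
      n_cov <- nrow(planted)
      # extensions capped at 8 bp: planted sites sit >= 12 bp apart, so a
      # covering cluster never reaches a neighbouring site
      cl <- tibble(
        chrom = planted$chrom,
        start = pmax(0L, planted$start - sample(0:8, n_cov, replace = TRUE)),
        end = planted$end + sample(0:8, n_cov, replace = TRUE),
        read_count = sample(1:50, n_cov, replace = TRUE),
        strand = planted$strand
      )
      n_dec <- config$n_decoy_clusters
      gap_idx <- sample(n_tx, n_dec, replace = TRUE)
      dlen <- sample(20:80, n_dec, replace = TRUE)
      doff <- sample(0:100, n_dec, replace = TRUE)
      decoys <- tibble(
        chrom = "chr1",
        start = g_start[gap_idx] - gap + doff,
        end = pmin(g_start[gap_idx] - 10L, g_start[gap_idx] - gap + doff + dlen),
        read_count = sample(1:50, n_dec, replace = TRUE),
        strand = sample(c("+", "-"), n_dec, replace = TRUE)
      ) %>% filter(.data$end > .data$start)
      clusters <- bind_rows(cl, decoys) %>%
        arrange(.data$start, .data$end) %>%
        mutate(cluster_id = sprintf("%s_c%04d", experiments$experiment_id[e],
                                    row_number()),
               experiment_id = experiments$experiment_id[e]) %>%
        select("chrom", "start", "end", "cluster_id", "read_count",
               "strand", "experiment_id")
      list(clusters = clusters, covered = covered)
    })
    beds[[e]] <- made$clusters
    cover_flags[, e] <- made$covered
  }
  colnames(cover_flags) <- experiments$experiment_id
  truth_sites <- bind_cols(truth_sites, as_tibble(cover_flags)) %>%
    mutate(n_supporting = rowSums(cover_flags))

  truth_sponges <- if (has_sponge) {
    tibble(family_id = family_id[1], transcript_id = "tx_sponge01",
           n_sites = config$sponge_sites)
  } else {
    tibble(family_id = character(), transcript_id = character(),
           n_sites = integer())
  }

  # Toy annotation: random gene-set terms plus one term collecting the
  # planted-pair genes.
  gmt_lines <- with_stream(seed, "annotation", {
    terms <- vapply(1:8, function(t) {
      members <- sort(sample(all_gene_id, 25L))
      paste(c(sprintf("TERM%02d", t), sprintf("synthetic term %d", t),
              toupper(members)), collapse = "\t")
    }, character(1))
    planted_term <- paste(
      c("PLANTED_PAIRS", "genes of the planted ceRNA pairs",
        toupper(sort(unique(c(truth_pairs$gene_a, truth_pairs$gene_b))))),
      collapse = "\t")
    c(terms, planted_term)
  })

  paths <- list(
    fasta = file.path(out_dir, "transcripts.fa"),
    transcripts = file.path(out_dir, "transcripts.tsv"),
    exons = file.path(out_dir, "exons.tsv"),
    mirnas = file.path(out_dir, "mirnas.tsv"),
    experiments = file.path(out_dir, "experiments.tsv"),
    beds = file.path(out_dir, experiments$bed_path),
    gmt = file.path(out_dir, "annotation.gmt"),
    truth_sites = file.path(out_dir, "truth_sites.tsv"),
    truth_pairs = file.path(out_dir, "truth_pairs.tsv"),
    truth_sponges = file.path(out_dir, "truth_sponges.tsv")
  )

  dss <- Biostrings::DNAStringSet(stats::setNames(seqs, tx_id))
  Biostrings::writeXStringSet(dss, paths$fasta)
  readr::write_tsv(
    tibble(transcript_id = tx_id, gene_id = all_gene_id,
           gene_symbol = toupper(all_gene_id), gene_biotype = biotypes),
    paths$transcripts)
  readr::write_tsv(
    tibble(transcript_id = tx_id, chrom = "chr1", start = g_start,
           end = g_end, strand = strands, exon_rank = 1L),
    paths$exons)
  readr::write_tsv(mirnas, paths$mirnas)
  readr::write_tsv(experiments, paths$experiments)
  for (e in seq_along(beds)) write_bed(beds[[e]], paths$beds[e])
  writeLines(gmt_lines, paths$gmt)
  readr::write_tsv(truth_sites, paths$truth_sites)
  readr::write_tsv(truth_pairs, paths$truth_pairs)
  readr::write_tsv(truth_sponges, paths$truth_sponges)

  invisible(list(dir = out_dir, paths = paths, config = config,
                 truth_sites = truth_sites, truth_pairs = truth_pairs,
                 truth_sponges = truth_sponges))
}

#' Simulate null gene-family profiles
#'
#' Each gene's family set is an independent uniform `k`-subset of `F`
#' families — exactly the null model under which the upper-tail
#' hypergeometric probability is the correct p-value for the shared count
#' of a gene pair. Used for FDR-calibration experiments.
#'
#' @param G Number of genes.
#' @param F_total Number of families (universe size).
#' @param k Families per gene (at least 1).
#' @param rng_seed Seed.
#' @return Profile tibble as from [build_family_profiles()], with
#'   `universe_n_families = F_total`.
#' @export
simulate_null_profiles <- function(G, F_total, k, rng_seed = 1L) {
  if (k < 1L) abort("configuration error: k must be >= 1 (families non-empty)")
  if (k > F_total) abort("configuration error: k > F_total")
  fams <- sprintf("F%03d", seq_len(F_total))
  prof <- with_stream(rng_seed, "null_profiles", {
    tibble(
      gene_id = sprintf("g%04d", seq_len(G)),
      families = vapply(seq_len(G), function(i) {
        paste(sort(sample(fams, k)), collapse = ",")
      }, character(1)),
      n_families = as.integer(k)
    )
  })
  attr(prof, "universe_n_families") <- as.integer(F_total)
  prof
}
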