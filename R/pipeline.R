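#' Run the full target-to-ceRNA pipeline on an input bundle
#'
#' Executes every stage end-to-end on a bundle directory laid out as
#' [simulate_universe()] emits it: seed-site scan on all transcripts,
#' projection to genomic coordinates, per-program evidence merging,
#' CLIP-support annotation, stringency filtering, per-gene family profiles,
#' the global ceRNA network, the sponge report and (when `annotation.gmt`
#' is present) functional enrichment of the ceRNA-network genes. All stage
#' tables are written as TSV under `out_dir` together with a run manifest
#' of MD5 checksums; reruns on identical inputs and parameters are
#' byte-identical. On a stage failure the partial outputs are moved to a
#' `<out_dir>.quarantine` directory and the error names the failed stage.
#'
#' @param bundle_dir Directory with `transcripts.fa`, `transcripts.tsv`,
#'   `exons.tsv`, `mirnas.tsv`, `experiments.tsv` (+ BED files) and
#'   optionally `annotation.gmt`.
#' @param out_dir Output directory (created; must not already contain a
#'   manifest from another run you want to keep).
#' @param prediction_paths Optional external prediction TSVs to combine
#'   with the built-in scanner (see [load_program_predictions()]).
#' @param min_experiments,min_programs Stringency thresholds for
#'   [filter_interactions()].
#' @param min_common,fdr_threshold ceRNA parameters for
#'   [build_cerna_network()].
#' @param min_sites Sponge-report threshold for [rank_sponges()].
#' @param site_types Seed-site classes for [scan_seed_sites()].
#' @return Invisibly, a list with the stage tibbles (`sites`,
#'   `interactions`, `profiles`, `network`, `sponges`, `enrichment`), the
#'   output `paths` and the `manifest` tibble.
#' @export
run_full_pipeline <- function(bundle_dir, out_dir,
                              prediction_paths = NULL,
                              min_experiments = 1L, min_programs = 1L,
                              min_common = 3L, fdr_threshold = 0.05,
                              min_sites = 5L,
                              site_types = c("8mer", "7mer-m8", "7mer-A1")) {
  staging <- tempfile("cernet_run_")
  dir.create(staging, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      quarantine <- paste0(sub("/+$", "", out_dir), ".quarantine")
      unlink(quarantine, recursive = TRUE)
      if (length(list.files(staging))) file.rename(staging, quarantine)
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  emit <- function(x, file) {
    readr::write_tsv(as_tibble(x), file.path(staging, file))
    x
  }

  inputs <- stage("load", {
    list(
      transcripts = read_transcriptome(file.path(bundle_dir, "transcripts.fa"),
                                       file.path(bundle_dir, "transcripts.tsv")),
      exons = readr::read_tsv(file.path(bundle_dir, "exons.tsv"),
                              show_col_types = FALSE, progress = FALSE),
      mirnas = readr::read_tsv(file.path(bundle_dir, "mirnas.tsv"),
                               show_col_types = FALSE, progress = FALSE),
      clip = read_clip_experiments(file.path(bundle_dir, "experiments.tsv"))
    )
  })

  families <- stage("collapse_families", collapse_families(inputs$mirnas))

  sites <- stage("scan", {
    s <- scan_seed_sites(inputs$transcripts, families, site_types) %>%
      project_sites_to_genome(inputs$exons)
    if (any(s$spans_junction)) {
      warn(sprintf("%d sites span exon junctions and are excluded from genome-space support annotation",
                   sum(s$spans_junction)))
      s <- s %>% filter(!.data$spans_junction)
    }
    if (!is.null(prediction_paths)) {
      ext <- load_program_predictions(prediction_paths, inputs$mirnas)
      s <- bind_rows(s, ext)
    }
    s
  })

  interactions_all <- stage("support", {
    merge_evidence(sites) %>%
      annotate_clip_support(inputs$clip$clusters) %>%
      emit("sites.tsv")
  })

  interactions <- stage("filter", {
    filter_interactions(interactions_all, min_experiments, min_programs) %>%
      left_join(
        inputs$transcripts %>% distinct(.data$gene_id, .data$biotype_class),
        by = "gene_id"
      ) %>%
      emit("interactions.tsv")
  })

  profiles <- stage("profiles", {
    emit(build_family_profiles(interactions, n_families = nrow(families)),
         "profiles.tsv")
  })

  network <- stage("cerna", {
    if (nrow(profiles) >= 2L) {
      build_cerna_network(profiles, min_common = min_common,
                          fdr_threshold = fdr_threshold)
    } else {
      empty_cerna_pairs()
    }
  })
  emit(network, "cerna_edges.tsv")

  sponges <- stage("sponge", {
    emit(rank_sponges(count_family_sites(interactions_all), min_sites),
         "sponges.tsv")
  })

  gmt_path <- file.path(bundle_dir, "annotation.gmt")
  enrichment <- stage("enrich", {
    network_genes <- unique(c(network$gene_a, network$gene_b))
    if (file.exists(gmt_path) && length(network_genes)) {
      category <- read_gmt(gmt_path, category_name = "bundle")
      enrich(toupper(network_genes), category)
    } else {
      tibble(category = character(), term_id = character(),
             term_name = character(), overlap_count = integer(),
             term_size = integer(), query_size = integer(),
             universe_size = integer(), p_value = numeric(),
             p_bonferroni = numeric(), q_value = numeric())
    }
  })
  emit(enrichment, "enrichment.tsv")

  manifest <- stage("manifest", {
    params <- c(
      min_experiments = min_experiments, min_programs = min_programs,
      min_common = min_common, fdr_threshold = fdr_threshold,
      min_sites = min_sites,
      site_types = paste(site_types, collapse = ",")
    )
    readr::write_tsv(tibble(key = names(params),
                            value = as.character(params)),
                     file.path(staging, "params.tsv"))
    files <- sort(list.files(staging))
    tibble(
      file = files,
      md5 = unname(tools::md5sum(file.path(staging, files)))
    )
  })
  readr::write_tsv(manifest, file.path(staging, "manifest.tsv"))

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (f in list.files(staging)) {
    file.copy(file.path(staging, f), file.path(out_dir, f), overwrite = TRUE)
  }
  unlink(staging, recursive = TRUE)

  invisible(list(
    sites = interactions_all, interactions = interactions,
    profiles = profiles, network = network, sponges = sponges,
    enrichment = enrichment, manifest = manifest,
    paths = file.path(out_dir, manifest$file)
  ))
}
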