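#' Run the full genome-architecture pipeline
#'
#' Wires every stage into one deterministic run: input (FASTA + annotations,
#' or a simulated cohort), tandem-array detection, region merging and
#' filtering, genic/intergenic classification, per-genome and cohort
#' summaries, repeat position tracks, ITR detection, normalized gene-position
#' conservation, subfamily copy-number matrix and proximity clusters. All
#' tables are written to `out_dir` with external 1-based coordinates plus a
#' JSON run manifest recording every threshold, the seed and a config hash;
#' re-running with an identical config reproduces identical tables.
#'
#' @param config Either a path to a YAML file or a list. Recognised entries:
#'   `genomes` / `annotations` (input paths) or `simulate` (a list of
#'   [sim_config()] arguments) — exactly one of the two; `repeat_params`
#'   (list of [repeat_params()] arguments); `sd_threshold`, `min_genomes`,
#'   `max_index_gap`, `itr_max_mismatch_frac`, `itr_min_len`, `bin_size`,
#'   `novelty_threshold`, `group_col`; `seed`.
#' @param out_dir Output directory.
#' @return Invisibly, a list with every in-memory result (`genomes`,
#'   `annotations`, `regions`, `classified`, `per_genome`, `cohort`, `track`,
#'   `itr`, `conservation`, `subfam_matrix`, `clusters`, `novelty`,
#'   `recovery` when simulating, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  has_sim <- !is.null(config$simulate)
  has_input <- !is.null(config$genomes)
  if (has_sim == has_input) {
    stop("config must contain exactly one of 'genomes' or 'simulate'",
         call. = FALSE)
  }
  cfg <- utils::modifyList(
    list(
      sd_threshold = 0.1, min_genomes = 2L, max_index_gap = 3L,
      itr_max_mismatch_frac = 0.05, itr_min_len = 20L,
      bin_size = 10000L, novelty_threshold = 0.8,
      group_col = "subfamily", seed = 1L
    ),
    config
  )
  params <- do.call(repeat_params, as.list(cfg$repeat_params))

  recovery <- NULL
  if (has_sim) {
    sim_args <- as.list(cfg$simulate)
    if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
    sim <- simulate_cohort(do.call(sim_config, sim_args))
    genomes <- sim$genomes
    annotations <- sim$annotations
  } else {
    genomes <- read_genomes(cfg$genomes)
    annotations <- if (!is.null(cfg$annotations)) {
      read_annotations(cfg$annotations, genomes)
    } else {
      validate_annotations(tibble::tibble(), genomes)
    }
  }

  regions <- find_repeat_regions(genomes, params)
  classified <- classify_regions(regions, annotations)
  per_genome <- summarize_genomes(classified, genomes)
  cohort <- summarize_cohort(per_genome)
  track <- repeat_track(classified, genomes, bin_size = cfg$bin_size)
  itr <- detect_itr(genomes,
                    max_mismatch_frac = cfg$itr_max_mismatch_frac,
                    min_len = cfg$itr_min_len)
  positions <- normalized_positions(annotations, genomes)
  conservation <- position_conservation(
    positions, group_col = cfg$group_col,
    sd_threshold = cfg$sd_threshold, min_genomes = cfg$min_genomes
  )
  sf_matrix <- subfamily_matrix(annotations)
  clusters <- if (nrow(sf_matrix) > 0L) {
    purrr::map(rownames(sf_matrix), function(sf) {
      proximity_clusters(annotations, sf, max_index_gap = cfg$max_index_gap)
    }) |>
      stats::setNames(rownames(sf_matrix)) |>
      dplyr::bind_rows(.id = "subfamily")
  } else {
    tibble::tibble()
  }
  novelty <- if (nrow(classified) >= 2L) {
    unit_novelty(classified, identity_threshold = cfg$novelty_threshold)
  } else {
    NULL
  }
  if (has_sim) {
    recovery <- evaluate_recovery(sim$truth$repeats, classified)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("tandemarch")),
    seed = cfg$seed,
    repeat_params = unclass(params),
    thresholds = cfg[c("sd_threshold", "min_genomes", "max_index_gap",
                       "itr_max_mismatch_frac", "itr_min_len", "bin_size",
                       "novelty_threshold")],
    simulate = if (has_sim) cfg$simulate else NULL,
    inputs = if (has_input) cfg[c("genomes", "annotations")] else NULL,
    config_hash = rlang::hash(cfg),
    n_genomes = nrow(genomes),
    n_regions = nrow(classified)
  )

  out <- list(
    genomes = genomes[, c("genome_id", "length", "topology")],
    annotations = annotations,
    regions = regions,
    classified = classified,
    per_genome = per_genome,
    cohort = cohort,
    track_midpoints = track$midpoints,
    track_bins = track$bins,
    itr = itr,
    conservation_groups = conservation$groups,
    subfam_matrix = tidy(sf_matrix),
    clusters = if (nrow(clusters)) {
      dplyr::mutate(clusters,
                    gene_ids = purrr::map_chr(.data$gene_ids, paste,
                                              collapse = ","),
                    ordinals = purrr::map_chr(.data$ordinals, paste,
                                              collapse = ","))
    } else {
      clusters
    },
    novelty = if (!is.null(novelty)) novelty$per_region else NULL,
    recovery = if (!is.null(recovery)) recovery$matches else NULL
  )
  out <- out[!vapply(out, is.null, logical(1))]
  write_tables(out, out_dir)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(
    list(
      cohort = cohort$cohort,
      categories = cohort$categories,
      conserved_fraction = conservation$conserved_fraction,
      n_conserved_7plus = conservation$n_conserved_7plus,
      shared_unit_fraction = if (!is.null(novelty)) {
        novelty$shared_fraction
      } else {
        NULL
      },
      recovery = if (!is.null(recovery)) {
        list(precision = recovery$precision, recall = recovery$recall)
      } else {
        NULL
      }
    ),
    file.path(out_dir, "cohort_summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "columns"
  )
  invisible(c(
    list(cohort_obj = cohort, track = track, conservation = conservation,
         manifest = manifest),
    out
  ))
}
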