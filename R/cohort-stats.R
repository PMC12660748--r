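#' Per-genome repeat summary statistics
#'
#' For each genome: region count, region density per 100,000 bp, mean
#' complete copies per region, mean unit (period) length, and the counts of
#' the two-way genic/intergenic by div3/not-div3 partition. Genomes with no
#' regions report zeros and are flagged `empty`.
#'
#' @param classified Classified region tibble from [classify_regions()].
#' @param genomes Genome tibble (`genome_id`, `length`). Every genome in this
#'   table gets a row, regions or not.
#' @return A tibble, one row per genome: `genome_id`, `genome_length`,
#'   `n_regions`, `density`, `mean_copies`, `mean_unit_len`, `n_genic`,
#'   `n_intergenic`, `n_genic_div3`, `n_genic_not3`, `n_intergenic_div3`,
#'   `n_intergenic_not3`, `empty`.
#' @export
summarize_genomes <- function(classified, genomes) {
  base <- tibble::tibble(
    genome_id = genomes$genome_id,
    genome_length = as.numeric(genomes$length)
  )
  if (nrow(classified) > 0L) {
    per <- classified |>
      dplyr::group_by(.data$genome_id) |>
      dplyr::summarise(
        n_regions = dplyr::n(),
        mean_copies = mean(.data$copies),
        mean_unit_len = mean(.data$period),
        n_genic = sum(.data$category == "genic"),
        n_intergenic = sum(.data$category == "intergenic"),
        n_genic_div3 = sum(.data$category == "genic" & .data$div3),
        n_genic_not3 = sum(.data$category == "genic" & !.data$div3),
        n_intergenic_div3 = sum(.data$category == "intergenic" & .data$div3),
        n_intergenic_not3 = sum(.data$category == "intergenic" & !.data$div3),
        .groups = "drop"
      )
  } else {
    per <- tibble::tibble(genome_id = character())
  }
  base |>
    dplyr::left_join(per, by = "genome_id") |>
    dplyr::mutate(
      dplyr::across(dplyr::starts_with("n_"), ~ tidyr::replace_na(.x, 0L)),
      mean_copies = tidyr::replace_na(.data$mean_copies, 0),
      mean_unit_len = tidyr::replace_na(.data$mean_unit_len, 0),
      density = .data$n_regions / .data$genome_length * 1e5,
      empty = .data$n_regions == 0L
    ) |>
    dplyr::select(
      "genome_id", "genome_length", "n_regions", "density", "mean_copies",
      "mean_unit_len", "n_genic", "n_intergenic", "n_genic_div3",
      "n_genic_not3", "n_intergenic_div3", "n_intergenic_not3", "empty"
    )
}

#' Cohort summary across genomes
#'
#' Aggregates per-genome summaries into the cohort-level statistics reported
#' for repeat inventories: summed genome length, across-genome mean ± sample
#' SD (n−1; a single genome gets SD 0) of density, copies per region and unit
#' length, plus pooled category counts with integer percentages (rounded
#' half-up) for the genic/intergenic split and, within each category, the
#' div-by-3 split.
#'
#' @param per_genome Tibble from [summarize_genomes()].
#' @return An object of class `cohort_summary`: a list with `per_genome`,
#'   `cohort` (one-row tibble) and `categories` (pooled counts/percentages).
#' @examples
#' # pooled percentages straight from published category counts:
#' category_percentages(genic_div3 = 330, genic_not3 = 2,
#'                      intergenic_div3 = 103, intergenic_not3 = 322)
#' @export
summarize_cohort <- function(per_genome) {
  stopifnot(nrow(per_genome) >= 1L)
  sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)
  cohort <- tibble::tibble(
    n_genomes = nrow(per_genome),
    sum_genome_length = sum(per_genome$genome_length),
    n_regions = sum(per_genome$n_regions),
    mean_density = mean(per_genome$density),
    sd_density = sd0(per_genome$density),
    mean_copies = mean(per_genome$mean_copies),
    sd_copies = sd0(per_genome$mean_copies),
    mean_unit_len = mean(per_genome$mean_unit_len),
    sd_unit_len = sd0(per_genome$mean_unit_len)
  )
  categories <- category_percentages(
    genic_div3 = sum(per_genome$n_genic_div3),
    genic_not3 = sum(per_genome$n_genic_not3),
    intergenic_div3 = sum(per_genome$n_intergenic_div3),
    intergenic_not3 = sum(per_genome$n_intergenic_not3)
  )
  structure(
    list(per_genome = per_genome, cohort = cohort, categories = categories),
    class = "cohort_summary"
  )
}

#' Pooled category percentages from counts
#'
#' Computes the two-way percentage splits of a repeat inventory from pooled
#' counts: genic vs intergenic of all regions, and div-by-3 vs not within
#' each category. Percentages are rounded half-up to integers, mirroring how
#' such tables are printed.
#'
#' @param genic_div3,genic_not3,intergenic_div3,intergenic_not3 Pooled region
#'   counts.
#' @return A tibble with columns `split`, `level`, `count`, `pct`.
#' @export
category_percentages <- function(genic_div3, genic_not3,
                                 intergenic_div3, intergenic_not3) {
  genic <- genic_div3 + genic_not3
  intergenic <- intergenic_div3 + intergenic_not3
  total <- genic + intergenic
  tibble::tibble(
    split = c(
      "all", "all",
      "genic", "genic",
      "intergenic", "intergenic"
    ),
    level = c(
      "genic", "intergenic",
      "div3", "not_div3",
      "div3", "not_div3"
    ),
    count = c(genic, intergenic, genic_div3, genic_not3,
              intergenic_div3, intergenic_not3),
    pct = c(
      pct_round(genic, total), pct_round(intergenic, total),
      pct_round(genic_div3, genic), pct_round(genic_not3, genic),
      pct_round(intergenic_div3, intergenic),
      pct_round(intergenic_not3, intergenic)
    )
  )
}

# integer percentage, rounded half-up (display convention); 0 denominators
# give NA rather than an error
pct_round <- function(count, total) {
  ifelse(total > 0, floor(count / total * 100 + 0.5), NA_real_)
}

#' @export
print.cohort_summary <- function(x, ...) {
  co <- x$cohort
  cat("Cohort repeat summary (", co$n_genomes, " genomes, ",
      format(co$sum_genome_length, big.mark = ","), " bp)\n", sep = "")
  cat(sprintf("  regions: %d | density %.2f +/- %.2f per 100 kbp\n",
              co$n_regions, co$mean_density, co$sd_density))
  cat(sprintf("  copies/region %.1f +/- %.1f | unit length %.1f +/- %.1f bp\n",
              co$mean_copies, co$sd_copies,
              co$mean_unit_len, co$sd_unit_len))
  g <- x$categories[x$categories$split == "all", ]
  cat(sprintf("  genic %d%% (%d) / intergenic %d%% (%d)\n",
              g$pct[1], g$count[1], g$pct[2], g$count[2]))
  invisible(x)
}

#' Repeat position track along a genome
#'
#' Returns region midpoints and binned region counts along each genome, the
#' table behind dot-track displays of repeat distribution (genomes ordered by
#' decreasing length).
#'
#' @param regions Region tibble (`genome_id`, `start`, `end`).
#' @param genomes Genome tibble (`genome_id`, `length`).
#' @param bin_size Bin width in bp (>= 1).
#' @return A list of class `repeat_track`: `midpoints` tibble (`genome_id`,
#'   `midpoint`, `span`), `bins` tibble (`genome_id`, `bin_start`, `bin_end`,
#'   `n_regions`), and `genomes` ordered by decreasing length.
#' @export
repeat_track <- function(regions, genomes, bin_size = 10000L) {
  stopifnot(bin_size >= 1L)
  glen <- genomes[order(-genomes$length), c("genome_id", "length")]
  mids <- if (nrow(regions) > 0L) {
    regions |>
      dplyr::transmute(
        genome_id = .data$genome_id,
        midpoint = (.data$start + .data$end) / 2,
        span = .data$end - .data$start
      )
  } else {
    tibble::tibble(genome_id = character(), midpoint = numeric(),
                   span = integer())
  }
  bins <- purrr::map2(glen$genome_id, glen$length, function(gid, L) {
    starts <- seq(0, L - 1, by = bin_size)
    tibble::tibble(
      genome_id = gid,
      bin_start = starts,
      bin_end = pmin(starts + bin_size, L)
    )
  }) |>
    dplyr::bind_rows()
  counts <- mids |>
    dplyr::mutate(bin_start = (.data$midpoint %/% bin_size) * bin_size) |>
    dplyr::count(.data$genome_id, .data$bin_start, name = "n_regions")
  bins <- bins |>
    dplyr::left_join(counts, by = c("genome_id", "bin_start")) |>
    dplyr::mutate(n_regions = tidyr::replace_na(.data$n_regions, 0L))
  structure(
    list(midpoints = mids, bins = bins, genomes = glen,
         bin_size = as.integer(bin_size)),
    class = "repeat_track"
  )
}

#' @export
print.repeat_track <- function(x, ...) {
  cat("Repeat track:", nrow(x$midpoints), "regions across",
      nrow(x$genomes), "genomes; bin size", x$bin_size, "bp\n")
  invisible(x)
}
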