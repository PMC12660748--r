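#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cohort summary into a per-genome tibble
#'
#' @param x A `cohort_summary` from [summarize_cohort()].
#' @param ... Unused.
#' @return The per-genome summary tibble.
#' @method tidy cohort_summary
#' @export
tidy.cohort_summary <- function(x, ...) x$per_genome

#' One-row cohort-level summary
#'
#' Across-genome means and SDs plus the pooled category percentages as
#' columns (`pct_genic`, `pct_genic_div3`, `pct_intergenic_div3`, ...).
#'
#' @param x A `cohort_summary` from [summarize_cohort()].
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance cohort_summary
#' @export
glance.cohort_summary <- function(x, ...) {
  cat_wide <- x$categories |>
    dplyr::mutate(name = paste0(
      "pct_",
      ifelse(.data$split == "all", "", paste0(.data$split, "_")),
      .data$level
    )) |>
    dplyr::select("name", "pct") |>
    tidyr::pivot_wider(names_from = "name", values_from = "pct")
  dplyr::bind_cols(x$cohort, cat_wide)
}

#' Tidy positional-conservation results into a per-group tibble
#'
#' @param x A `position_conservation` object.
#' @param ... Unused.
#' @return The per-group tibble (`group_id`, `n_genomes`, `mean_position`,
#'   `sd_position`, `conserved`).
#' @method tidy position_conservation
#' @export
tidy.position_conservation <- function(x, ...) x$groups

#' One-row summary of positional conservation
#'
#' @param x A `position_conservation` object.
#' @param ... Unused.
#' @return A one-row tibble with `n_groups`, `conserved_fraction`,
#'   `n_conserved_7plus`, `sd_threshold`, `min_genomes`.
#' @method glance position_conservation
#' @export
glance.position_conservation <- function(x, ...) {
  tibble::tibble(
    n_groups = nrow(x$groups),
    conserved_fraction = x$conserved_fraction,
    n_conserved_7plus = x$n_conserved_7plus,
    sd_threshold = x$sd_threshold,
    min_genomes = x$min_genomes
  )
}

#' Tidy a subfamily matrix into long form
#'
#' @param x A `subfamily_matrix`.
#' @param ... Unused.
#' @return A tibble with `subfamily`, `genome_id`, `n_genes`.
#' @method tidy subfamily_matrix
#' @export
tidy.subfamily_matrix <- function(x, ...) {
  if (nrow(x) == 0L) {
    return(tibble::tibble(subfamily = character(), genome_id = character(),
                          n_genes = integer()))
  }
  m <- unclass(x)
  tibble::tibble(
    subfamily = rep(rownames(m), times = ncol(m)),
    genome_id = rep(colnames(m), each = nrow(m)),
    n_genes = as.integer(m)
  )
}

#' Tidy a recovery report into its per-region match table
#'
#' @param x A `recovery_report` from [evaluate_recovery()].
#' @param ... Unused.
#' @return The matches tibble.
#' @method tidy recovery_report
#' @export
tidy.recovery_report <- function(x, ...) x$matches

#' One-row precision/recall summary of a recovery report
#'
#' @param x A `recovery_report` from [evaluate_recovery()].
#' @param ... Unused.
#' @return A one-row tibble with `precision`, `recall`, `n_detected`,
#'   `no_detections`.
#' @method glance recovery_report
#' @export
glance.recovery_report <- function(x, ...) {
  tibble::tibble(
    precision = x$precision,
    recall = x$recall,
    n_detected = nrow(x$matches),
    no_detections = x$no_detections
  )
}

#' Tidy a novelty report into its per-region table
#'
#' @param x A `novelty_report` from [unit_novelty()].
#' @param ... Unused.
#' @return The per-region tibble.
#' @method tidy novelty_report
#' @export
tidy.novelty_report <- function(x, ...) x$per_region
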