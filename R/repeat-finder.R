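#' Parameters for tandem-repeat detection and region filtering
#'
#' Defaults follow the inventory thresholds used for the cohort statistics:
#' regions at least 50 bp long, at least 3 complete unit copies and a minimum
#' unit (period) length of 9 bp. `max_unit_len` bounds the period search;
#' 500 bp is generous given typical unit lengths around 25 bp. `merge_gap = 0`
#' merges only overlapping or abutting arrays, so a region is a single tandem
#' locus.
#'
#' @param min_region_span Minimum region span in bp kept by
#'   [filter_regions()].
#' @param min_copies Minimum number of complete unit copies.
#' @param min_unit_len Minimum primitive period in bp.
#' @param max_unit_len Maximum period searched by [find_tandem_arrays()].
#' @param merge_gap Maximum gap in bp between arrays merged into one region.
#' @return A list of class `repeat_params`.
#' @export
repeat_params <- function(min_region_span = 50L, min_copies = 3L,
                          min_unit_len = 9L, max_unit_len = 500L,
                          merge_gap = 0L) {
  stopifnot(
    min_unit_len >= 1L, min_unit_len <= max_unit_len,
    min_copies >= 2L, min_region_span >= 1L, merge_gap >= 0L
  )
  structure(
    list(
      min_region_span = as.integer(min_region_span),
      min_copies = as.integer(min_copies),
      min_unit_len = as.integer(min_unit_len),
      max_unit_len = as.integer(max_unit_len),
      merge_gap = as.integer(merge_gap)
    ),
    class = "repeat_params"
  )
}

#' Find all maximal perfect tandem arrays
#'
#' Scans each genome for maximal perfect tandem repetitions: intervals that
#' consist of at least two exact copies of a unit (plus possibly an exact
#' partial trailing copy), cannot be extended by one base on either side at
#' the same period, and are reported at their primitive period only — a
#' period-2k reading of a period-k repeat is suppressed, so a homopolymer is
#' one period-1 array, never a period-9 one. `N` matches nothing, so arrays
#' never cross an `N`.
#'
#' @param genomes Genome tibble from [read_genomes()] or [simulate_cohort()]
#'   (columns `genome_id`, `sequence`).
#' @param params [repeat_params()]; only `max_unit_len` matters here (all
#'   arrays with `copies >= 2` are returned; filtering happens in
#'   [filter_regions()]).
#' @return A tibble of arrays: `genome_id`, `start`, `end` (0-based
#'   half-open), `period`, `copies` (complete copies, `span %/% period`),
#'   `unit` (first unit), sorted by genome, start, period.
#' @examples
#' g <- tibble::tibble(genome_id = "g", sequence = "ACGTACGTACGT",
#'                     length = 12L, topology = "linear")
#' find_tandem_arrays(g)
#' @export
find_tandem_arrays <- function(genomes, params = repeat_params()) {
  stopifnot(inherits(params, "repeat_params"))
  res <- purrr::map2(
    genomes$genome_id, genomes$sequence,
    function(gid, seq) {
      hits <- scan_tandem_arrays(seq, params$max_unit_len, 2L)
      if (nrow(hits) == 0L) return(NULL)
      tibble::tibble(
        genome_id = gid,
        start = as.integer(hits$start),
        end = as.integer(hits$end),
        period = as.integer(hits$period),
        copies = as.integer((hits$end - hits$start) %/% hits$period),
        unit = substr(rep(seq, nrow(hits)), hits$start + 1L,
                      hits$start + hits$period)
      )
    }
  )
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0L) return(empty_array_tbl())
  dplyr::arrange(out, .data$genome_id, .data$start, .data$period)
}

empty_array_tbl <- function() {
  tibble::tibble(
    genome_id = character(), start = integer(), end = integer(),
    period = integer(), copies = integer(), unit = character()
  )
}

#' Merge tandem arrays into repeat regions
#'
#' Arrays whose intervals overlap or lie within `merge_gap` bp of each other
#' (per genome) are merged into one region spanning their union. The merged
#' region inherits `period`, `copies` and `unit` from its longest-span
#' constituent array; ties are broken by smaller period, then leftmost start.
#'
#' Only arrays whose primitive period reaches `min_unit_len` take part in
#' region assembly: shorter periods are the microsatellite/homopolymer class
#' that the unit-length threshold exists to exclude, and random sequence is
#' dense in such micro-arrays — letting them merge would perturb the
#' boundaries of essentially every region they happen to touch.
#'
#' @param arrays Array tibble from [find_tandem_arrays()].
#' @param params [repeat_params()] supplying `merge_gap` and `min_unit_len`.
#' @return A region tibble: `genome_id`, `start`, `end`, `span`, `period`,
#'   `copies`, `unit`.
#' @export
merge_into_regions <- function(arrays, params = repeat_params()) {
  stopifnot(inherits(params, "repeat_params"))
  arrays <- dplyr::filter(arrays, .data$period >= params$min_unit_len)
  if (nrow(arrays) == 0L) return(empty_region_tbl())
  gap <- params$merge_gap
  clustered <- arrays |>
    dplyr::arrange(.data$genome_id, .data$start, .data$end) |>
    dplyr::group_by(.data$genome_id) |>
    dplyr::mutate(
      .prev_max = dplyr::lag(cummax(.data$end)),
      .cl = cumsum(is.na(.data$.prev_max) |
                     .data$start > .data$.prev_max + gap)
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(.span = .data$end - .data$start)
  bounds <- clustered |>
    dplyr::group_by(.data$genome_id, .data$.cl) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     .groups = "drop")
  reps <- clustered |>
    dplyr::arrange(.data$genome_id, .data$.cl, dplyr::desc(.data$.span),
                   .data$period, .data$start) |>
    dplyr::distinct(.data$genome_id, .data$.cl, .keep_all = TRUE) |>
    dplyr::select("genome_id", ".cl", "period", "copies", "unit")
  bounds |>
    dplyr::inner_join(reps, by = c("genome_id", ".cl")) |>
    dplyr::mutate(span = .data$end - .data$start) |>
    dplyr::select("genome_id", "start", "end", "span", "period", "copies",
                  "unit") |>
    dplyr::arrange(.data$genome_id, .data$start)
}

empty_region_tbl <- function() {
  tibble::tibble(
    genome_id = character(), start = integer(), end = integer(),
    span = integer(), period = integer(), copies = integer(),
    unit = character()
  )
}

#' Filter repeat regions by the inventory thresholds
#'
#' Keeps regions with `span >= min_region_span`, `copies >= min_copies` and
#' `period >= min_unit_len` (all three conjunctively; defaults 50 bp /
#' 3 copies / 9 bp). Order is preserved.
#'
#' @param regions Region tibble from [merge_into_regions()].
#' @param params [repeat_params()].
#' @return The filtered region tibble.
#' @export
filter_regions <- function(regions, params = repeat_params()) {
  stopifnot(inherits(params, "repeat_params"))
  dplyr::filter(
    regions,
    .data$span >= params$min_region_span,
    .data$copies >= params$min_copies,
    .data$period >= params$min_unit_len
  )
}

#' Detect, merge and filter repeat regions in one call
#'
#' Convenience wrapper chaining [find_tandem_arrays()],
#' [merge_into_regions()] and [filter_regions()].
#'
#' @inheritParams find_tandem_arrays
#' @return A filtered region tibble.
#' @export
find_repeat_regions <- function(genomes, params = repeat_params()) {
  genomes |>
    find_tandem_arrays(params) |>
    merge_into_regions(params) |>
    filter_regions(params)
}
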