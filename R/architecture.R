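#' Detect terminal inverted repeats of linear genomes
#'
#' Extends inward from both termini, comparing base `i` (from the left end)
#' with the complement of base `L - 1 - i` (from the right end). The reported
#' ITR is the extension maximising the alignment score
#' `matches - penalty * mismatches` with
#' `penalty = (1 - max_mismatch_frac) / max_mismatch_frac`, so mismatches are
#' tolerated up to the configured fraction but a run of unrelated sequence
#' immediately ends the repeat — a plain cumulative-budget rule would drift
#' tens of bases past the true boundary of a long ITR before exhausting the
#' budget it accumulated inside it. Extensions shorter than `min_len`, with a
#' non-positive score, or violating the mismatch fraction report length 0.
#' Extension is capped at half the genome so the two copies never overlap;
#' an `N` on either side counts as a mismatch.
#'
#' @param genomes Genome tibble; all rows must be `topology == "linear"`.
#' @param max_mismatch_frac Allowed mismatch fraction (default 0.05).
#' @param min_len Minimum reported ITR length in bp (default 20).
#' @return A tibble, one row per genome: `genome_id`, `itr_length`,
#'   `left_start`, `left_end`, `right_start`, `right_end` (0-based
#'   half-open; left interval starts at 0, right ends at the genome length),
#'   `mismatch_count`. Zero-length ITRs report empty intervals at the
#'   termini.
#' @export
detect_itr <- function(genomes, max_mismatch_frac = 0.05, min_len = 20L) {
  stopifnot(max_mismatch_frac > 0, max_mismatch_frac < 1)
  if (any(genomes$topology != "linear")) {
    stop("ITR detection requires linear genomes; circular genome(s): ",
         paste(genomes$genome_id[genomes$topology != "linear"],
               collapse = ", "),
         call. = FALSE)
  }
  penalty <- (1 - max_mismatch_frac) / max_mismatch_frac
  res <- purrr::map2(genomes$genome_id, genomes$sequence, function(gid, seq) {
    L <- nchar(seq)
    half <- L %/% 2L
    fwd <- charToRaw(substr(seq, 1L, half))
    rev_comp <- .complement_raw(rev(charToRaw(substr(seq, L - half + 1L, L))))
    is_mism <- fwd != rev_comp | fwd == charToRaw("N")
    mism <- cumsum(is_mism)
    lens <- seq_len(half)
    score <- (lens - mism) - penalty * mism
    ok <- lens >= min_len & score > 0 & mism <= max_mismatch_frac * lens
    if (!any(ok)) {
      itr <- 0L
      mm <- 0L
    } else {
      best <- max(score[ok])
      itr <- max(lens[ok & score == best])   # longest extension at max score
      mm <- mism[itr]
    }
    tibble::tibble(
      genome_id = gid,
      itr_length = as.integer(itr),
      left_start = 0L, left_end = as.integer(itr),
      right_start = as.integer(L - itr), right_end = as.integer(L),
      mismatch_count = as.integer(mm)
    )
  })
  dplyr::bind_rows(res)
}

.complement_raw <- function(r) {
  out <- r
  out[r == charToRaw("A")] <- charToRaw("T")
  out[r == charToRaw("T")] <- charToRaw("A")
  out[r == charToRaw("C")] <- charToRaw("G")
  out[r == charToRaw("G")] <- charToRaw("C")
  out[!(r %in% charToRaw("ACGT"))] <- charToRaw("N")
  out
}

#' Normalized gene positions along their genomes
#'
#' Position of a gene is its interval midpoint divided by the genome length,
#' a fraction in \[0,1\] comparable across genomes of different sizes.
#'
#' @param annotations Annotation tibble (internal 0-based half-open coords).
#' @param genomes Genome tibble (`genome_id`, `length`).
#' @return The annotation tibble with an added `position` column.
#' @export
normalized_positions <- function(annotations, genomes) {
  glen <- stats::setNames(as.numeric(genomes$length), genomes$genome_id)
  dplyr::mutate(
    annotations,
    position = (.data$start + .data$end) / 2 /
      unname(glen[.data$genome_id])
  )
}

#' Gene-position conservation across genomes
#'
#' Groups genes by a shared label (ortholog group or subfamily), keeps groups
#' that are single-copy in each contributing genome and present in at least
#' `min_genomes` genomes, and reports each group's mean and sample SD of
#' normalized position. The conserved fraction is the share of groups with
#' SD at or below `sd_threshold`; the same threshold defines the count of
#' well-conserved groups present in at least 7 genomes. Genomes carrying a
#' group in multiple copies are dropped from that group with a warning (the
#' group survives if enough single-copy genomes remain).
#'
#' @param positions Tibble from [normalized_positions()] (needs `genome_id`,
#'   `position` and a group label column).
#' @param group_col Name of the group label column (default `"subfamily"`).
#' @param sd_threshold SD at or below which a group counts as positionally
#'   conserved (default 0.1).
#' @param min_genomes Minimum genomes a group must occur in (default 2).
#' @return An object of class `position_conservation`: `groups` tibble
#'   (`group_id`, `n_genomes`, `mean_position`, `sd_position`, `conserved`),
#'   `conserved_fraction`, `n_conserved_7plus`, and the thresholds used.
#' @export
position_conservation <- function(positions, group_col = "subfamily",
                                  sd_threshold = 0.1, min_genomes = 2L) {
  stopifnot(group_col %in% names(positions))
  df <- positions |>
    dplyr::filter(!is.na(.data[[group_col]])) |>
    dplyr::rename(group_id = dplyr::all_of(group_col))
  multi <- df |>
    dplyr::count(.data$group_id, .data$genome_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(multi) > 0L) {
    warning(nrow(multi), " (group, genome) pair(s) multicopy; ",
            "those genomes excluded from the affected groups",
            call. = FALSE)
    df <- dplyr::anti_join(df, multi, by = c("group_id", "genome_id"))
  }
  groups <- df |>
    dplyr::group_by(.data$group_id) |>
    dplyr::summarise(
      n_genomes = dplyr::n_distinct(.data$genome_id),
      mean_position = mean(.data$position),
      sd_position = ifelse(dplyr::n() > 1L, stats::sd(.data$position), NA_real_),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_genomes >= min_genomes) |>
    dplyr::mutate(conserved = .data$sd_position <= sd_threshold)
  structure(
    list(
      groups = groups,
      conserved_fraction = if (nrow(groups)) mean(groups$conserved) else NA_real_,
      n_conserved_7plus = sum(groups$conserved & groups$n_genomes >= 7L),
      sd_threshold = sd_threshold,
      min_genomes = as.integer(min_genomes)
    ),
    class = "position_conservation"
  )
}

#' @export
print.position_conservation <- function(x, ...) {
  cat("Gene-position conservation:", nrow(x$groups), "groups in >=",
      x$min_genomes, "genomes\n")
  cat(sprintf("  conserved (SD <= %.2f): %.0f%%; %d such groups in >= 7 genomes\n",
              x$sd_threshold, 100 * x$conserved_fraction,
              x$n_conserved_7plus))
  invisible(x)
}

#' Subfamily-by-genome copy-number matrix
#'
#' Counts annotated genes per (subfamily, genome). Genes without a subfamily
#' label are excluded.
#'
#' @param annotations Annotation tibble with a `subfamily` column.
#' @return An object of class `subfamily_matrix`: an integer matrix with
#'   subfamilies as rows (ordered by decreasing total count) and genomes as
#'   columns (alphabetical).
#' @export
subfamily_matrix <- function(annotations) {
  lab <- dplyr::filter(annotations, !is.na(.data$subfamily))
  if (nrow(lab) == 0L) {
    m <- matrix(integer(), 0L, 0L)
    return(structure(m, class = c("subfamily_matrix", class(m))))
  }
  counts <- lab |>
    dplyr::count(.data$subfamily, .data$genome_id)
  wide <- tidyr::pivot_wider(
    counts,
    names_from = "genome_id", values_from = "n", values_fill = 0L
  )
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$subfamily
  m <- m[order(-rowSums(m)), order(colnames(m)), drop = FALSE]
  storage.mode(m) <- "integer"
  structure(m, class = c("subfamily_matrix", class(m)))
}

#' @export
print.subfamily_matrix <- function(x, ...) {
  cat("Subfamily copy-number matrix:", nrow(x), "subfamilies x",
      ncol(x), "genomes;", sum(x), "genes\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Proximity clusters of a subfamily's genes
#'
#' Within each genome, genes are ranked by start coordinate (the gene
#' ordinal); genes of the chosen subfamily are clustered by single linkage on
#' ordinal distance, joining members whose ordinals differ by at most
#' `max_index_gap`. Captures the tendency of multicopy genes to be encoded in
#' close genomic proximity, as expected under origination by tandem gene
#' duplication.
#'
#' @param annotations Annotation tibble.
#' @param subfamily Subfamily label to cluster.
#' @param max_index_gap Maximum ordinal difference joining two members
#'   (default 3).
#' @return A tibble, one row per cluster: `genome_id`, `cluster`, `size`,
#'   `gene_ids` (list column), `ordinals` (list column).
#' @export
proximity_clusters <- function(annotations, subfamily, max_index_gap = 3L) {
  stopifnot(max_index_gap >= 1L)
  ranked <- annotations |>
    dplyr::group_by(.data$genome_id) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(ordinal = dplyr::row_number()) |>
    dplyr::ungroup()
  members <- dplyr::filter(ranked, .data$subfamily == !!subfamily)
  if (nrow(members) == 0L) {
    return(tibble::tibble(
      genome_id = character(), cluster = integer(), size = integer(),
      gene_ids = list(), ordinals = list()
    ))
  }
  members |>
    dplyr::group_by(.data$genome_id) |>
    dplyr::arrange(.data$ordinal, .by_group = TRUE) |>
    dplyr::mutate(
      cluster = cumsum(c(TRUE, diff(.data$ordinal) > max_index_gap))
    ) |>
    dplyr::group_by(.data$genome_id, .data$cluster) |>
    dplyr::summarise(
      size = dplyr::n(),
      gene_ids = list(.data$gene_id),
      ordinals = list(.data$ordinal),
      .groups = "drop"
    )
}
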