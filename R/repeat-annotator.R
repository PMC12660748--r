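#' Classify repeat regions as genic or intergenic
#'
#' A region is genic iff it is fully contained within an annotated gene
#' interval (`gene.start <= region.start` and `region.end <= gene.end`);
#' everything else — including regions partially overlapping a gene — is
#' intergenic, giving the two-way split used by the cohort tables. When a
#' region is contained in several overlapping genes the shortest (most
#' specific) gene is recorded, ties broken leftmost. Strand is ignored.
#' `div3` flags unit lengths divisible by 3, i.e. repeats that preserve
#' reading frame and generate amino-acid repeats when genic.
#'
#' @param regions Region tibble from [filter_regions()] (or any tibble with
#'   `genome_id`, `start`, `end`, `period`).
#' @param annotations Annotation tibble from [read_annotations()].
#' @return The region tibble with added columns `category` (`"genic"` /
#'   `"intergenic"`), `div3` (logical) and `containing_gene` (`NA` when
#'   intergenic).
#' @export
classify_regions <- function(regions, annotations) {
  if (nrow(regions) == 0L) {
    return(dplyr::mutate(
      regions,
      category = character(), div3 = logical(),
      containing_gene = character()
    ))
  }
  ann_split <- if (nrow(annotations) > 0L) {
    split(annotations, annotations$genome_id)
  } else {
    list()
  }
  containing <- purrr::pmap_chr(
    list(regions$genome_id, regions$start, regions$end),
    function(gid, s, e) {
      g <- ann_split[[gid]]
      if (is.null(g)) return(NA_character_)
      hit <- g$start <= s & e <= g$end
      if (!any(hit)) return(NA_character_)
      cand <- g[hit, ]
      cand <- cand[order(cand$end - cand$start, cand$start), ]
      cand$gene_id[1L]
    }
  )
  regions |>
    dplyr::mutate(
      category = ifelse(is.na(containing), "intergenic", "genic"),
      div3 = .data$period %% 3L == 0L,
      containing_gene = containing
    )
}

#' Cross-region repeat-unit novelty
#'
#' Measures how often a region's repeat unit recurs elsewhere in the cohort.
#' Identity between two units is the maximal number of matched positions in a
#' global alignment (match 1, mismatch/indel 0) divided by the longer unit
#' length, maximised over all cyclic rotations of the second unit and of its
#' reverse complement — tandem units have arbitrary phase and strand. A
#' region is "shared" when its best identity against any other region reaches
#' `identity_threshold`.
#'
#' @param regions Region tibble with a `unit` column.
#' @param identity_threshold Fraction in \[0,1\]; default 0.8.
#' @return A list of class `novelty_report`: `per_region` tibble
#'   (`genome_id`, `start`, `end`, `unit`, `best_identity`, `shared`) and
#'   `shared_fraction`.
#' @export
unit_novelty <- function(regions, identity_threshold = 0.8) {
  n <- nrow(regions)
  if (n < 2L) {
    warning("fewer than 2 regions: shared_fraction reported as 0",
            call. = FALSE)
    per <- dplyr::mutate(
      regions[, intersect(c("genome_id", "start", "end", "unit"),
                          names(regions))],
      best_identity = if (n) 0 else numeric(),
      shared = if (n) FALSE else logical()
    )
    return(structure(
      list(per_region = per, shared_fraction = 0,
           identity_threshold = identity_threshold),
      class = "novelty_report"
    ))
  }
  units <- regions$unit
  best <- numeric(n)
  # pairwise upper triangle; identity is symmetric
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      id <- unit_identity(units[i], units[j])
      if (id > best[i]) best[i] <- id
      if (id > best[j]) best[j] <- id
    }
  }
  per <- regions[, intersect(c("genome_id", "start", "end", "unit"),
                             names(regions))]
  per$best_identity <- best
  per$shared <- best >= identity_threshold
  structure(
    list(
      per_region = tibble::as_tibble(per),
      shared_fraction = mean(per$shared),
      identity_threshold = identity_threshold
    ),
    class = "novelty_report"
  )
}

#' @export
print.novelty_report <- function(x, ...) {
  cat("Repeat-unit novelty report\n")
  cat("  regions:        ", nrow(x$per_region), "\n", sep = "")
  cat("  shared fraction:", format(x$shared_fraction, digits = 3),
      "at identity >=", x$identity_threshold, "\n")
  invisible(x)
}
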