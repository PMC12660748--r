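#' Read genomes from a FASTA file
#'
#' Reads one or more linear genome sequences into the tabular genome
#' representation used throughout the package: one row per replicon, with the
#' full sequence held as an uppercase character string over `A`, `C`, `G`,
#' `T`, `N`. Characters outside that alphabet (including IUPAC ambiguity
#' codes) are mapped to `N` with a warning giving the replacement count.
#'
#' @param path Path to a FASTA file. Record ids are taken as the first
#'   whitespace-delimited token of each header.
#' @param topology Topology recorded for every genome, `"linear"` (default)
#'   or `"circular"`. Terminal-inverted-repeat detection requires linear.
#' @return A tibble with columns `genome_id`, `sequence`, `length`,
#'   `topology`, one row per record, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">g1", "ACGTACGTACGT"), fa)
#' read_genomes(fa)
#' @export
read_genomes <- function(path, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("FASTA file contains no records: ", path, call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate genome ids in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  n_bad <- sum(vapply(
    seqs,
    function(s) nchar(s) - sum(charToRaw(s) %in% charToRaw("ACGTN")),
    integer(1)
  ))
  if (n_bad > 0) {
    warning(n_bad, " characters outside {A,C,G,T,N} mapped to N",
            call. = FALSE)
    seqs <- vapply(seqs, .mask_non_acgtn, character(1), USE.NAMES = FALSE)
  }
  lens <- nchar(seqs)
  if (any(lens == 0L)) {
    stop("empty sequence for record(s): ",
         paste(ids[lens == 0L], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    genome_id = unname(ids),
    sequence = unname(seqs),
    length = unname(lens),
    topology = topology
  )
}

.mask_non_acgtn <- function(s) {
  r <- charToRaw(s)
  keep <- charToRaw("ACGTN")
  r[!(r %in% keep)] <- charToRaw("N")
  rawToChar(r)
}

#' Read gene annotations (GFF3 or TSV) against a genome table
#'
#' Accepts either GFF3 (features of type `gene` or `CDS`; id from the `ID`,
#' `locus_tag` or `Name` attribute) or the package's simple TSV dialect:
#' tab-separated with a header row and columns `genome_id`, `gene_id`,
#' `start`, `end`, `strand` and optionally `subfamily`. File coordinates are
#' 1-based inclusive in both dialects; internally genes are stored 0-based
#' half-open (`start = file_start - 1`, `end = file_end`), the convention used
#' by every interval in this package.
#'
#' @param path Annotation file. Files ending in `.gff`, `.gff3` (optionally
#'   `.gz`) are parsed as GFF3, anything else as the TSV dialect.
#' @param genomes Genome tibble from [read_genomes()]; used to validate
#'   `genome_id` references and coordinate bounds.
#' @return A tibble with columns `genome_id`, `gene_id`, `start`, `end`
#'   (0-based half-open), `strand`, `subfamily` (`NA` when absent), sorted by
#'   genome then start.
#' @export
read_annotations <- function(path, genomes) {
  if (!file.exists(path)) {
    stop("annotation file not found: ", path, call. = FALSE)
  }
  ann <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) {
    .read_gff3(path)
  } else {
    .read_annotation_tsv(path)
  }
  validate_annotations(ann, genomes)
}

.read_annotation_tsv <- function(path) {
  df <- readr::read_tsv(
    path,
    col_types = readr::cols(
      genome_id = readr::col_character(),
      gene_id = readr::col_character(),
      start = readr::col_integer(),
      end = readr::col_integer(),
      strand = readr::col_character(),
      subfamily = readr::col_character(),
      .default = readr::col_character()
    ),
    progress = FALSE
  )
  required <- c("genome_id", "gene_id", "start", "end", "strand")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("annotation TSV lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"subfamily" %in% names(df)) df$subfamily <- NA_character_
  tibble::tibble(
    genome_id = df$genome_id,
    gene_id = df$gene_id,
    start = df$start - 1L,   # to 0-based half-open
    end = df$end,
    strand = df$strand,
    subfamily = df$subfamily
  )
}

.read_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("GFF3 input requires the rtracklayer package; ",
         "use the TSV annotation dialect otherwise", call. = FALSE)
  }
  g <- rtracklayer::readGFF(path)
  g <- g[g$type %in% c("gene", "CDS"), , drop = FALSE]
  id <- g$ID
  if (is.null(id)) id <- rep(NA_character_, nrow(g))
  for (alt in c("locus_tag", "Name")) {
    if (!is.null(g[[alt]])) id <- ifelse(is.na(id), g[[alt]], id)
  }
  if (anyNA(id)) {
    id[is.na(id)] <- paste0("gene_", which(is.na(id)))
  }
  sub <- if (!is.null(g$subfamily)) as.character(g$subfamily) else NA_character_
  tibble::tibble(
    genome_id = as.character(g$seqid),
    gene_id = as.character(id),
    start = as.integer(g$start) - 1L,
    end = as.integer(g$end),
    strand = as.character(g$strand),
    subfamily = sub
  )
}

#' Validate an annotation tibble against a genome table
#'
#' Checks genome references, per-genome gene-id uniqueness and coordinate
#' bounds (0-based half-open, so `0 <= start < end <= genome length`).
#' Called by [read_annotations()]; exported so programmatically built
#' annotation tables can be checked the same way.
#'
#' @param annotations Annotation tibble (internal 0-based half-open coords).
#' @param genomes Genome tibble from [read_genomes()] or [simulate_cohort()].
#' @return The annotation tibble, sorted by genome then start.
#' @export
validate_annotations <- function(annotations, genomes) {
  ann <- tibble::as_tibble(annotations)
  if (nrow(ann) == 0L) {
    return(tibble::tibble(
      genome_id = character(), gene_id = character(),
      start = integer(), end = integer(),
      strand = character(), subfamily = character()
    ))
  }
  unknown <- setdiff(unique(ann$genome_id), genomes$genome_id)
  if (length(unknown) > 0) {
    stop("annotations reference unknown genome id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  dup <- ann |>
    dplyr::count(.data$genome_id, .data$gene_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0) {
    stop("duplicate gene id(s) within a genome: ",
         paste(dup$gene_id, collapse = ", "), call. = FALSE)
  }
  glen <- stats::setNames(genomes$length, genomes$genome_id)
  bad <- ann$start < 0L | ann$start >= ann$end |
    ann$end > glen[ann$genome_id]
  if (any(bad)) {
    stop("gene(s) with out-of-bounds coordinates: ",
         paste(ann$gene_id[bad], collapse = ", "), call. = FALSE)
  }
  dplyr::arrange(ann, .data$genome_id, .data$start)
}

#' Write result tables for a pipeline run
#'
#' Writes every table of a result bundle as TSV with the package's external
#' conventions: coordinates converted to 1-based inclusive, rows ordered by
#' genome id then start, densities formatted with 2 decimals, percentages as
#' integers and means/SDs with 1 decimal. A cohort summary, when present, is
#' additionally written as JSON.
#'
#' @param results Named list of tibbles (and optionally a `cohort_summary`
#'   object under the name `cohort`). Interval tables are recognised by the
#'   presence of `start`/`end` columns.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the character vector of files written.
#' @export
write_tables <- function(results, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) {
      stop("cannot create output directory: ", out_dir, call. = FALSE)
    }
  }
  written <- character()
  for (nm in names(results)) {
    x <- results[[nm]]
    if (inherits(x, "cohort_summary")) {
      jf <- file.path(out_dir, paste0(nm, ".json"))
      jsonlite::write_json(
        list(
          per_genome = format_summary_table(x$per_genome),
          cohort = format_summary_table(x$cohort),
          categories = x$categories
        ),
        jf, auto_unbox = TRUE, digits = NA, pretty = TRUE
      )
      written <- c(written, jf)
      x <- x$per_genome
    }
    if (!is.data.frame(x)) next
    tf <- file.path(out_dir, paste0(nm, ".tsv"))
    readr::write_tsv(externalize_coords(x), tf, progress = FALSE)
    written <- c(written, tf)
  }
  invisible(written)
}

#' Convert a table's interval columns to external 1-based inclusive form
#'
#' The inverse of the conversion applied on read: `start + 1`, `end`
#' unchanged. Tables without `start`/`end` columns pass through untouched.
#' Rows are ordered by `genome_id` then `start` when those columns exist.
#'
#' @param x A tibble, possibly with `start` and `end` columns in the internal
#'   0-based half-open convention.
#' @return The tibble with 1-based inclusive coordinates.
#' @export
externalize_coords <- function(x) {
  if (all(c("start", "end") %in% names(x))) {
    x <- dplyr::mutate(x, start = .data$start + 1L)
    ord <- intersect(c("genome_id", "start"), names(x))
    if (length(ord) > 0) x <- dplyr::arrange(x, !!!rlang::syms(ord))
  }
  x
}

#' Convert a table's interval columns from external to internal coordinates
#'
#' @param x A tibble with 1-based inclusive `start`/`end` columns.
#' @return The tibble in the internal 0-based half-open convention.
#' @export
internalize_coords <- function(x) {
  if (all(c("start", "end") %in% names(x))) {
    x <- dplyr::mutate(x, start = .data$start - 1L)
  }
  x
}

# Fixed display formatting mirroring the cohort-table conventions:
# densities 2 dp, percentages 0 dp, means/SDs 1 dp. Returns a list of
# formatted strings for JSON emission; numeric values stay numeric in R.
format_summary_table <- function(df) {
  out <- as.list(df)
  for (nm in names(out)) {
    v <- out[[nm]]
    if (!is.numeric(v)) next
    if (grepl("density", nm)) {
      out[[nm]] <- formatC(v, format = "f", digits = 2)
    } else if (grepl("^pct_|_pct$", nm)) {
      out[[nm]] <- formatC(v, format = "f", digits = 0)
    } else if (grepl("^(mean|sd)_|_mean$|_sd$", nm)) {
      out[[nm]] <- formatC(v, format = "f", digits = 1)
    }
  }
  if (is.data.frame(df)) out <- tibble::as_tibble(out)
  out
}

#' Write a genome tibble as FASTA
#'
#' @param genomes Genome tibble (`genome_id`, `sequence`).
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_genomes <- function(genomes, path) {
  set <- Biostrings::DNAStringSet(stats::setNames(
    genomes$sequence, genomes$genome_id
  ))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write an annotation tibble in the TSV dialect
#'
#' Coordinates are emitted 1-based inclusive, the inverse of
#' [read_annotations()].
#'
#' @param annotations Annotation tibble (internal coordinates).
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_annotations <- function(annotations, path) {
  readr::write_tsv(externalize_coords(annotations), path, progress = FALSE)
  invisible(path)
}
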