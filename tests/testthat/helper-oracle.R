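# Independent reference implementation of maximal-primitive tandem-array
# enumeration, used to cross-check the package's compiled scanner. Takes a
# different route on purpose: per-period lag comparison as an R logical
# vector, run detection with rle(), and primitivity by exhaustively testing
# every smaller candidate period on the interval string.

oracle_tandem_arrays <- function(seq, max_period = 100L, min_copies = 2L) {
  n <- nchar(seq)
  ch <- strsplit(seq, "")[[1]]
  rows <- list()
  for (p in seq_len(min(max_period, n %/% 2L))) {
    a <- ch[seq_len(n - p)]
    b <- ch[seq.int(p + 1L, n)]
    eq <- a == b & a != "N" & b != "N"
    r <- rle(eq)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    for (k in seq_along(r$values)) {
      if (!r$values[k]) next
      L <- r$lengths[k]
      if (L < p) next
      s0 <- run_start[k] - 1L          # 0-based interval [s0, s0 + L + p)
      span <- L + p
      if (span %/% p < min_copies) next
      if (oracle_min_period(ch, s0, span) == p) {
        rows[[length(rows) + 1L]] <- c(s0, s0 + span, p)
      }
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(start = integer(), end = integer(),
                          period = integer()))
  }
  m <- do.call(rbind, rows)
  out <- tibble::tibble(start = m[, 1], end = m[, 2], period = m[, 3])
  dplyr::arrange(out, .data$start, .data$period)
}

# smallest q such that x[i] == x[i + q] for all i in the interval
oracle_min_period <- function(ch, s0, span) {
  x <- ch[seq.int(s0 + 1L, s0 + span)]
  for (q in seq_len(span - 1L)) {
    if (all(x[seq_len(span - q)] == x[seq.int(q + 1L, span)])) return(q)
  }
  span
}

# uniform random DNA string
random_dna <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# overwrite seq with `copies` exact copies of `unit` at 0-based `at`,
# forcing non-extending flanks so the planted array is exactly maximal
plant_array <- function(seq, unit, copies, at) {
  p <- nchar(unit)
  arr <- strrep(unit, copies)
  alen <- nchar(arr)
  ch <- strsplit(seq, "")[[1]]
  ch[seq.int(at + 1L, at + alen)] <- strsplit(arr, "")[[1]]
  ub <- strsplit(unit, "")[[1]]
  if (at >= 1L) ch[at] <- setdiff(c("A", "C", "G", "T"), ub[p])[1]
  if (at + alen + 1L <= length(ch)) {
    ch[at + alen + 1L] <- setdiff(c("A", "C", "G", "T"), ub[1])[1]
  }
  paste(ch, collapse = "")
}

genome_tbl <- function(seqs, ids = sprintf("g%d", seq_along(seqs))) {
  tibble::tibble(
    genome_id = ids,
    sequence = toupper(seqs),
    length = nchar(seqs),
    topology = "linear"
  )
}

annotation_tbl <- function(genome_id, gene_id, start, end,
                           strand = "+", subfamily = NA_character_) {
  tibble::tibble(
    genome_id = genome_id, gene_id = gene_id,
    start = as.integer(start), end = as.integer(end),
    strand = strand, subfamily = subfamily
  )
}

region_tbl <- function(genome_id, start, end, period, copies,
                       unit = strrep("A", period)) {
  tibble::tibble(
    genome_id = genome_id,
    start = as.integer(start), end = as.integer(end),
    span = as.integer(end - start),
    period = as.integer(period), copies = as.integer(copies),
    unit = unit
  )
}
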