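test_that("constructed exact repeats are reported at the primitive period", {
  g <- genome_tbl("ACGTACGTACGT")
  arr <- find_tandem_arrays(g)
  expect_equal(nrow(arr), 1L)
  expect_equal(arr$start, 0L)
  expect_equal(arr$end, 12L)
  expect_equal(arr$period, 4L)
  expect_equal(arr$copies, 3L)
  expect_equal(arr$unit, "ACGT")

  # homopolymer canonicalises to period 1; harmonic readings suppressed
  h <- find_tandem_arrays(genome_tbl(strrep("A", 100)))
  expect_equal(nrow(h), 1L)
  expect_equal(h$period, 1L)
  expect_equal(h$copies, 100L)
})

test_that("a planted array in random sequence is recovered exactly and
           agrees with the independent oracle", {
  set.seed(421)
  seq <- random_dna(2000)
  unit <- "GATTACACGGTTAGC"  # 15 bp, primitive
  seq <- plant_array(seq, unit, copies = 4L, at = 700L)
  arr <- find_tandem_arrays(genome_tbl(seq),
                            repeat_params(max_unit_len = 100L))
  hit <- dplyr::filter(arr, .data$period == 15L)
  expect_equal(hit$start, 700L)
  expect_equal(hit$end, 760L)
  expect_equal(hit$copies, 4L)
  expect_equal(hit$unit, unit)
  # direct string verification, independent of the scanner
  expect_identical(substr(seq, 701, 760), strrep(unit, 4))

  orc <- oracle_tandem_arrays(seq, max_period = 100L)
  expect_equal(arr[, c("start", "end", "period")],
               orc, ignore_attr = TRUE)
})

test_that("arrays never cross an N and partial trailing copies extend the
           span but not the copy count", {
  # perfect 3.67 copies: span 11 at period 3, copies floor(11/3) = 3
  g <- genome_tbl("TTACGACGACGAC")  # ACG x3 + AC partial, flanked by TT
  arr <- find_tandem_arrays(g)
  row <- dplyr::filter(arr, .data$period == 3L)
  expect_equal(row$start, 2L)
  expect_equal(row$end, 13L)
  expect_equal(row$copies, 3L)

  gn <- genome_tbl("ACGACGACGNACGACGACG")
  arrn <- find_tandem_arrays(gn)
  p3 <- dplyr::filter(arrn, .data$period == 3L)
  expect_equal(nrow(p3), 2L)
  expect_true(all(p3$end <= 9L | p3$start >= 10L))
})

test_that("scanner matches the oracle across random sequences with and
           without planted arrays", {
  set.seed(99)
  params <- repeat_params(max_unit_len = 60L)
  for (i in 1:30) {
    n <- sample(200:600, 1)
    seq <- random_dna(n)
    if (i %% 2 == 0) {
      p <- sample(9:30, 1)
      unit <- random_dna(p)
      if (oracle_min_period(strsplit(unit, "")[[1]], 0L, p) != p) next
      copies <- sample(3:6, 1)
      at <- sample(seq_len(n - p * copies - 2L), 1)
      seq <- plant_array(seq, unit, copies, at)
    }
    arr <- find_tandem_arrays(genome_tbl(seq), params)
    orc <- oracle_tandem_arrays(seq, max_period = 60L)
    expect_equal(arr[, c("start", "end", "period")], orc,
                 ignore_attr = TRUE)
  }
})

test_that("merging unions overlapping arrays and keeps the longest-span
           representative with smaller-period tie-break", {
  # equal spans, harmonic periods: smaller period wins
  a <- tibble::tibble(
    genome_id = "g", start = c(0L, 0L), end = c(120L, 120L),
    period = c(10L, 20L), copies = c(12L, 6L),
    unit = c(strrep("AC", 5), strrep("AC", 10))
  )
  m <- merge_into_regions(a)
  expect_equal(nrow(m), 1L)
  expect_equal(m$period, 10L)

  # disjoint arrays stay separate at merge_gap 0
  b <- tibble::tibble(
    genome_id = "g", start = c(0L, 160L), end = c(60L, 220L),
    period = c(10L, 12L), copies = c(6L, 5L),
    unit = c(strrep("A", 10), strrep("A", 12))
  )
  expect_equal(nrow(merge_into_regions(b)), 2L)

  # overlap union: [0,60) + [58,130) -> [0,130), representative is the
  # longer-span [58,130) array
  c2 <- tibble::tibble(
    genome_id = "g", start = c(0L, 58L), end = c(60L, 130L),
    period = c(10L, 12L), copies = c(6L, 6L),
    unit = c(strrep("A", 10), strrep("C", 12))
  )
  mc <- merge_into_regions(c2)
  expect_equal(nrow(mc), 1L)
  expect_equal(mc$start, 0L)
  expect_equal(mc$end, 130L)
  expect_equal(mc$span, 130L)
  expect_equal(mc$period, 12L)
})

test_that("micro-period arrays are excluded from region assembly", {
  a <- tibble::tibble(
    genome_id = "g", start = c(100L, 150L), end = c(152L, 160L),
    period = c(13L, 2L), copies = c(4L, 5L),
    unit = c(strrep("A", 13), "AC")
  )
  m <- merge_into_regions(a)
  expect_equal(nrow(m), 1L)
  expect_equal(m$end, 152L)  # the period-2 array neither merges nor extends
})

test_that("region filters apply span, copies and unit-length thresholds
           conjunctively", {
  regs <- dplyr::bind_rows(
    region_tbl("g", 0, 45, 9, 5),     # span 45 < 50: out
    region_tbl("g", 100, 175, 25, 3), # kept
    region_tbl("g", 200, 300, 1, 100), # period 1 < 9: out (homopolymer)
    region_tbl("g", 400, 460, 30, 2)  # copies 2 < 3: out
  )
  kept <- filter_regions(regs)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$start, 100L)
})

test_that("detection is deterministic and shift-equivariant", {
  set.seed(7)
  seq <- random_dna(1500)
  seq <- plant_array(seq, "ACGTTGCAGGTA", 4L, 500L)
  g <- genome_tbl(seq)
  r1 <- find_repeat_regions(g)
  r2 <- find_repeat_regions(g)
  expect_identical(r1, r2)

  # prepend 100 bases: every array not touching the old left edge shifts
  # by exactly 100 (arrays at position 0 may gain a left extension)
  prefix <- random_dna(100)
  g2 <- genome_tbl(paste0(prefix, seq))
  a1 <- dplyr::filter(find_tandem_arrays(g), .data$start >= 1L)
  a2 <- dplyr::filter(find_tandem_arrays(g2), .data$start >= 101L)
  shifted <- dplyr::mutate(a1, start = .data$start + 100L,
                           end = .data$end + 100L)
  expect_equal(shifted[, c("start", "end", "period")],
               a2[, c("start", "end", "period")], ignore_attr = TRUE)
})

test_that("repeat params reject inconsistent thresholds", {
  expect_error(repeat_params(min_unit_len = 0L))
  expect_error(repeat_params(min_unit_len = 600L, max_unit_len = 500L))
  expect_error(repeat_params(min_copies = 1L))
})
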