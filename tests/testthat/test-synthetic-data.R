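# small desk-scale config used throughout this file
small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_genomes = 2L, genome_length = 1e5, itr_length = 500L,
         n_groups = 20L, n_multicopy_subfams = 2L, seed = 42L),
    list(...)
  )
  do.call(sim_config, args)
}

test_that("the same seed reproduces byte-identical cohorts", {
  s1 <- simulate_cohort(small_cfg())
  s2 <- simulate_cohort(small_cfg())
  expect_identical(s1$genomes$sequence, s2$genomes$sequence)
  expect_identical(s1$annotations, s2$annotations)
  expect_identical(s1$truth$repeats, s2$truth$repeats)

  s3 <- simulate_cohort(small_cfg(seed = 43L))
  expect_false(identical(s1$genomes$sequence, s3$genomes$sequence))
})

test_that("truth tables exactly describe the planted features", {
  sim <- simulate_cohort(small_cfg())
  tr <- sim$truth$repeats
  # bookkeeping: density 5 per 100 kbp on a 100 kbp genome -> 5 regions
  expect_equal(nrow(tr), 2L * 5L)
  expect_true(all(tr$period >= 9 & tr$period <= 200))
  expect_true(all(tr$copies >= 3))
  expect_true(all(tr$period * tr$copies >= 50))
  expect_identical(tr$div3, tr$period %% 3L == 0L)

  seqs <- stats::setNames(sim$genomes$sequence, sim$genomes$genome_id)
  for (i in seq_len(nrow(tr))) {
    r <- tr[i, ]
    s <- seqs[[r$genome_id]]
    # planted interval is exact copies of a primitive unit...
    expect_identical(substr(s, r$start + 1, r$end),
                     strrep(r$unit, r$copies))
    # unit is primitive: not an exact repetition of any shorter string
    divisors <- which(r$period %% seq_len(r$period %/% 2) == 0L)
    expect_false(any(vapply(divisors, function(d) {
      identical(strrep(substr(r$unit, 1, d), r$period / d), r$unit)
    }, logical(1))))
    # ...and exactly maximal: flanks do not extend the period
    expect_false(substr(s, r$start, r$start) ==
                   substr(s, r$start + r$period, r$start + r$period))
    expect_false(substr(s, r$end + 1, r$end + 1) ==
                   substr(s, r$end - r$period + 1, r$end - r$period + 1))
  }
})

test_that("planted genic regions sit inside genes and intergenic ones
           outside", {
  sim <- simulate_cohort(small_cfg())
  ann <- sim$annotations
  for (i in seq_len(nrow(sim$truth$repeats))) {
    r <- sim$truth$repeats[i, ]
    g <- ann[ann$genome_id == r$genome_id, ]
    contained <- any(g$start <= r$start & r$end <= g$end)
    expect_equal(contained, r$category == "genic")
  }
})

test_that("ortholog-group members are single-copy with jitter around the
           group position", {
  sim <- simulate_cohort(small_cfg(n_groups = 30L, group_jitter_sd = 0.01))
  mem <- sim$truth$group_members
  per <- dplyr::count(mem, .data$group_id, .data$genome_id)
  expect_true(all(per$n == 1L))
  est <- mem |>
    dplyr::inner_join(sim$truth$groups, by = "group_id") |>
    dplyr::group_by(.data$group_id) |>
    dplyr::summarise(err = abs(mean(.data$position) -
                                 .data$true_position[1]))
  expect_lt(stats::median(est$err), 0.05)
})

test_that("stage seeds are isolated: group and subfamily settings never
           touch sequences or planted repeats", {
  a <- simulate_cohort(small_cfg(n_groups = 5L, n_multicopy_subfams = 0L))
  b <- simulate_cohort(small_cfg(n_groups = 50L, n_multicopy_subfams = 3L))
  expect_identical(a$genomes$sequence, b$genomes$sequence)
  expect_identical(a$truth$repeats, b$truth$repeats)
})

test_that("infeasible packing is a config error naming the constraint", {
  expect_error(sim_config(genome_length = 2e4, repeat_density = 500),
               "infeasible packing")
})

test_that("recovery evaluation is exact on identity and degenerate
           inputs", {
  sim <- simulate_cohort(small_cfg())
  tr <- sim$truth$repeats
  det <- tr[, c("genome_id", "start", "end", "period", "copies", "unit")]
  rec <- evaluate_recovery(tr, det)
  expect_equal(rec$precision, 1)
  expect_equal(rec$recall, 1)

  empty <- det[0, ]
  rec0 <- evaluate_recovery(tr, empty)
  expect_equal(rec0$recall, 0)
  expect_equal(rec0$precision, 1)
  expect_true(rec0$no_detections)

  # harmonic periods still match
  det2 <- dplyr::mutate(det, period = .data$period * 2L)
  expect_equal(evaluate_recovery(tr, det2)$recall, 1)
})

test_that("a planted region split by an N yields two halves that fail the
           reciprocal-overlap rule", {
  set.seed(5)
  seq <- random_dna(400)
  unit <- "ACGGTTCAGATG"  # 12 bp
  seq <- plant_array(seq, unit, copies = 9L, at = 100L)  # [100, 208)
  ch <- strsplit(seq, "")[[1]]
  ch[155] <- "N"  # 0-based 154: splits the array into ~54 + ~53 bp halves
  g <- genome_tbl(paste(ch, collapse = ""))
  det <- find_repeat_regions(g)
  expect_equal(nrow(det), 2L)
  expect_true(all(det$period == 12L))
  truth <- tibble::tibble(genome_id = "g1", start = 100L, end = 208L,
                          period = 12L, copies = 9L, unit = unit,
                          category = "intergenic", div3 = TRUE)
  rec <- evaluate_recovery(truth, det)
  # each half covers only ~half the planted interval: no match either way
  expect_equal(rec$recall, 0)
  expect_equal(rec$precision, 0)
})

test_that("detector-estimated statistics on a small cohort sit near the
           configured generator values", {
  sim <- simulate_cohort(sim_config(n_genomes = 3L, genome_length = 2e5,
                                    n_groups = 0L,
                                    n_multicopy_subfams = 0L, seed = 9L))
  cl <- classify_regions(find_repeat_regions(sim$genomes), sim$annotations)
  rec <- evaluate_recovery(sim$truth$repeats, cl)
  expect_equal(rec$precision, 1)
  expect_equal(rec$recall, 1)
  s <- summarize_cohort(summarize_genomes(cl, sim$genomes))
  expect_equal(s$cohort$mean_density, 5, tolerance = 0.01)
  expect_equal(s$cohort$mean_unit_len, 25, tolerance = 0.25)
})
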