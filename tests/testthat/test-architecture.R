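test_that("a planted terminal inverted repeat is recovered exactly", {
  set.seed(31)
  s <- random_dna(1000)
  x <- strrep("A", 500)  # every position mismatches its own complement
  genome <- paste0(
    s, x,
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  )
  itr <- detect_itr(genome_tbl(genome))
  expect_equal(itr$itr_length, 1000L)
  expect_equal(itr$mismatch_count, 0L)
  expect_equal(itr$left_start, 0L)
  expect_equal(itr$right_end, nchar(genome))
  # reverse-complement invariant on the reported ITR
  left <- substr(genome, 1, itr$itr_length)
  right <- substr(genome, itr$right_start + 1, itr$right_end)
  rc_left <- chartr("ACGT", "TGCA",
                    paste(rev(strsplit(left, "")[[1]]), collapse = ""))
  expect_identical(right, rc_left)
})

test_that("random linear genomes report no ITR at min_len 20", {
  for (seed in c(5, 17, 23)) {
    set.seed(seed)
    g <- genome_tbl(random_dna(100000))
    expect_equal(detect_itr(g)$itr_length, 0L)
  }
})

test_that("ITR detection tolerates substitutions within the mismatch
           budget", {
  cfg <- sim_config(n_genomes = 1L, genome_length = 1e5,
                    itr_length = 1000L, itr_mismatch_rate = 0.02,
                    n_groups = 0L, n_multicopy_subfams = 0L, seed = 12L)
  sim <- simulate_cohort(cfg)
  itr <- detect_itr(sim$genomes, max_mismatch_frac = 0.05)
  expect_gte(itr$itr_length, 0.95 * 1000)
  expect_lte(itr$itr_length, 1000L)
  expect_lte(itr$mismatch_count, 0.05 * itr$itr_length)
})

test_that("circular genomes are rejected for ITR detection", {
  g <- genome_tbl("ACGTACGTACGT")
  g$topology <- "circular"
  expect_error(detect_itr(g), "linear")
})

test_that("normalized positions are midpoint over genome length", {
  g <- genome_tbl(strrep("A", 1000000))
  ann <- annotation_tbl("g1", c("a", "b"), c(200000L, 0L),
                        c(300000L, 1000000L))
  pos <- normalized_positions(ann, g)
  expect_equal(pos$position[pos$gene_id == "a"], 0.25)
  expect_equal(pos$position[pos$gene_id == "b"], 0.5)
  expect_true(all(pos$position >= 0 & pos$position <= 1))
})

test_that("position conservation computes group means, SDs and the
           conserved fraction", {
  pos <- tibble::tibble(
    genome_id = c("g1", "g2", "g3", "g1", "g2", "g3"),
    gene_id = sprintf("x%d", 1:6),
    position = c(0.70, 0.75, 0.80, 0.10, 0.45, 0.90),
    subfamily = c("tight", "tight", "tight", "loose", "loose", "loose")
  )
  pc <- position_conservation(pos)
  tight <- pc$groups[pc$groups$group_id == "tight", ]
  expect_equal(tight$mean_position, 0.75)
  expect_equal(tight$sd_position, 0.05)
  expect_true(tight$conserved)
  loose <- pc$groups[pc$groups$group_id == "loose", ]
  expect_false(loose$conserved)
  expect_equal(pc$conserved_fraction, 0.5)
})

test_that("multicopy genomes are excluded from a group with a warning", {
  pos <- tibble::tibble(
    genome_id = c("g1", "g1", "g2", "g3"),
    gene_id = sprintf("x%d", 1:4),
    position = c(0.2, 0.9, 0.50, 0.50),
    subfamily = "grp"
  )
  expect_warning(pc <- position_conservation(pos), "multicopy")
  g <- pc$groups
  expect_equal(g$n_genomes, 2L)    # g1 dropped, group survives
  expect_equal(g$mean_position, 0.5)
})

test_that("groups below min_genomes are dropped and the 7-plus counter
           uses the same SD threshold", {
  pos <- dplyr::bind_rows(
    tibble::tibble(genome_id = sprintf("g%d", 1:8),
                   gene_id = sprintf("a%d", 1:8),
                   position = 0.4 + seq(-0.035, 0.035, length.out = 8),
                   subfamily = "wide8"),
    tibble::tibble(genome_id = "g1", gene_id = "solo",
                   position = 0.2, subfamily = "singleton")
  )
  pc <- position_conservation(pos)
  expect_false("singleton" %in% pc$groups$group_id)
  expect_equal(pc$n_conserved_7plus, 1L)
})

test_that("conserved fraction responds monotonically to the SD threshold", {
  set.seed(77)
  pos <- dplyr::bind_rows(lapply(1:20, function(i) {
    sd <- stats::runif(1, 0.01, 0.3)
    tibble::tibble(
      genome_id = sprintf("g%d", 1:5),
      gene_id = sprintf("grp%02d_%d", i, 1:5),
      position = pmin(pmax(0.5 + stats::rnorm(5, 0, sd), 0), 1),
      subfamily = sprintf("grp%02d", i)
    )
  }))
  fr <- vapply(c(0.02, 0.1, 0.3),
               function(th) position_conservation(pos,
                                                  sd_threshold = th)$conserved_fraction,
               numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("subfamily matrix counts genes per subfamily and genome", {
  ann <- dplyr::bind_rows(
    annotation_tbl("g1", sprintf("a%d", 1:3), c(0L, 100L, 200L),
                   c(50L, 150L, 250L), subfamily = c("s1", "s1", "s2")),
    annotation_tbl("g2", sprintf("b%d", 1:2), c(0L, 100L),
                   c(50L, 150L), subfamily = c("s1", NA))
  )
  m <- subfamily_matrix(ann)
  expect_equal(m["s1", "g1"], 2L)
  expect_equal(m["s1", "g2"], 1L)
  expect_equal(m["s2", "g2"], 0L)
  expect_equal(sum(m), 4L)  # unlabeled genes excluded

  # totals invariant under genome order permutation
  m2 <- subfamily_matrix(ann[sample(nrow(ann)), ])
  expect_equal(sum(m2), sum(m))
  expect_equal(m2[rownames(m), colnames(m)], unclass(m)[, ],
               ignore_attr = TRUE)

  expect_equal(nrow(subfamily_matrix(annotation_tbl("g1", "x", 0L, 10L))),
               0L)
})

test_that("a 315-protein group across 17 genomes averages 18.5 copies", {
  set.seed(3)
  counts <- as.vector(stats::rmultinom(1, 315, rep(1, 17)))
  ann <- dplyr::bind_rows(lapply(1:17, function(i) {
    k <- counts[i]
    if (k == 0) return(NULL)
    annotation_tbl(sprintf("g%02d", i), sprintf("g%02d_p%d", i, seq_len(k)),
                   seq(0L, by = 100L, length.out = k),
                   seq(50L, by = 100L, length.out = k),
                   subfamily = "group1")
  }))
  m <- subfamily_matrix(ann)
  expect_equal(sum(m["group1", ]), 315L)
  expect_equal(sum(m["group1", ]) / 17, 18.5, tolerance = 0.01)
})

test_that("proximity clusters are single linkage on gene ordinals", {
  # genes with ordinals 5, 6, 9, 40 in a 50-gene genome
  starts <- seq(0L, by = 100L, length.out = 50L)
  ann <- annotation_tbl("g", sprintf("gene%02d", 1:50), starts,
                        starts + 80L)
  ann$subfamily[c(5, 6, 9, 40)] <- "fam"
  cl <- proximity_clusters(ann, "fam", max_index_gap = 3L)
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$size, c(3L, 1L))
  expect_equal(cl$ordinals[[1]], c(5L, 6L, 9L))
  expect_equal(cl$gene_ids[[2]], "gene40")

  # single gene forms a singleton cluster
  ann2 <- annotation_tbl("g", "only", 0L, 100L, subfamily = "fam")
  expect_equal(proximity_clusters(ann2, "fam")$size, 1L)

  # a consecutive run is always one cluster
  ann$subfamily <- NA_character_
  ann$subfamily[10:20] <- "run"
  expect_equal(nrow(proximity_clusters(ann, "run", max_index_gap = 1L)), 1L)
})
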