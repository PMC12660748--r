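#' Configuration for the synthetic-cohort simulator
#'
#' Defaults emulate the architecture of a cohort of linear megabase
#' extrachromosomal elements: 17 linear genomes of 0.5–1.1 Mbp terminated by
#' inverted repeats, gene intervals covering ~80% of each genome, planted
#' perfect tandem-repeat regions at ~5 per 100 kbp with unit lengths centred
#' near 25 bp (SD ~16, clipped to 9–200 bp) and ~5 complete copies per
#' region, 44% of regions inside genes, unit lengths divisible by 3 for 99%
#' of genic and 24% of intergenic regions, and single-copy ortholog groups
#' whose normalized positions are conserved across genomes up to a
#' controllable jitter.
#'
#' @param n_genomes Number of genomes.
#' @param genome_length Length range in bp (length-2 vector, or a scalar for
#'   fixed length).
#' @param gc_content Background GC fraction.
#' @param itr_length Planted terminal-inverted-repeat length in bp (0 for
#'   none).
#' @param itr_mismatch_rate Substitution rate applied to the right ITR copy.
#' @param gene_density Fraction of each genome covered by genes.
#' @param mean_gene_len Mean gene length in bp.
#' @param repeat_density Planted repeat regions per 100,000 bp.
#' @param unit_len_mean,unit_len_sd Mean and SD of the unit-length
#'   distribution (lognormal, moment-matched, then clipped to
#'   `unit_len_range`).
#' @param unit_len_range Clip bounds for unit lengths in bp.
#' @param copies_min Minimum complete copies per planted region.
#' @param copies_mean Mean complete copies per planted region
#'   (`copies = copies_min + Poisson(copies_mean - copies_min)`, then topped
#'   up so that `period * copies >= min_span`).
#' @param min_span Minimum planted region span in bp; keeps every planted
#'   region detectable under the default [repeat_params()] filters.
#' @param genic_fraction Probability a planted region is genic.
#' @param div3_genic,div3_intergenic Probability that a genic (resp.
#'   intergenic) planted unit length is divisible by 3.
#' @param n_groups Number of single-copy ortholog groups.
#' @param group_presence Probability a group is present in a genome.
#' @param group_jitter_sd Positional jitter SD of group genes (fraction of
#'   genome length); scalar or one value per group.
#' @param n_multicopy_subfams Number of multicopy subfamilies.
#' @param multicopy_mean Mean gene copies per (subfamily, genome).
#' @param seed Integer seed; every stage derives its own stream from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genomes = 17L,
                       genome_length = c(5e5, 1.1e6),
                       gc_content = 0.35,
                       itr_length = 1000L,
                       itr_mismatch_rate = 0,
                       gene_density = 0.8,
                       mean_gene_len = 1000L,
                       repeat_density = 5,
                       unit_len_mean = 25,
                       unit_len_sd = 16,
                       unit_len_range = c(9L, 200L),
                       copies_min = 3L,
                       copies_mean = 5,
                       min_span = 50L,
                       genic_fraction = 0.44,
                       div3_genic = 0.99,
                       div3_intergenic = 0.24,
                       n_groups = 120L,
                       group_presence = 0.8,
                       group_jitter_sd = 0.05,
                       n_multicopy_subfams = 4L,
                       multicopy_mean = 8,
                       seed = 1L) {
  if (length(genome_length) == 1L) genome_length <- rep(genome_length, 2L)
  fracs <- c(gc_content, gene_density, genic_fraction, div3_genic,
             div3_intergenic, group_presence, itr_mismatch_rate)
  stopifnot(
    all(fracs >= 0 & fracs <= 1),
    genome_length[1] <= genome_length[2], genome_length[1] > 0,
    repeat_density >= 0, copies_min >= 2L, copies_mean >= copies_min,
    unit_len_range[1] >= 1L, unit_len_range[1] <= unit_len_range[2],
    n_groups >= 0L, n_multicopy_subfams >= 0L,
    all(group_jitter_sd >= 0)
  )
  # feasibility: planted repeats + ITRs must fit comfortably
  min_len <- genome_length[1]
  planted_bp <- repeat_density * min_len / 1e5 *
    (unit_len_mean * copies_mean + 2)
  if (planted_bp + 2 * itr_length > 0.5 * min_len) {
    stop("infeasible packing: planted repeats (",
         round(planted_bp), " bp) plus ITRs (", 2 * itr_length,
         " bp) exceed half the smallest genome (", min_len, " bp)",
         call. = FALSE)
  }
  structure(
    list(
      n_genomes = as.integer(n_genomes),
      genome_length = as.numeric(genome_length),
      gc_content = gc_content,
      itr_length = as.integer(itr_length),
      itr_mismatch_rate = itr_mismatch_rate,
      gene_density = gene_density,
      mean_gene_len = as.integer(mean_gene_len),
      repeat_density = repeat_density,
      unit_len_mean = unit_len_mean,
      unit_len_sd = unit_len_sd,
      unit_len_range = as.integer(unit_len_range),
      copies_min = as.integer(copies_min),
      copies_mean = copies_mean,
      min_span = as.integer(min_span),
      genic_fraction = genic_fraction,
      div3_genic = div3_genic,
      div3_intergenic = div3_intergenic,
      n_groups = as.integer(n_groups),
      group_presence = group_presence,
      group_jitter_sd = group_jitter_sd,
      n_multicopy_subfams = as.integer(n_multicopy_subfams),
      multicopy_mean = multicopy_mean,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# stage-isolated seed derivation: each (stage, genome) pair gets its own
# stream so e.g. changing the ortholog-group settings never perturbs the
# sequences or the planted repeats
stage_seed <- function(seed, stage, genome = 0L) {
  as.integer((as.numeric(seed) * 7919 + stage * 104729 + genome * 514229) %%
               2147483647)
}

DNA_BASES <- c("A", "C", "G", "T")

base_probs <- function(gc) c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)

random_bases <- function(n, gc) {
  sample(DNA_BASES, n, replace = TRUE, prob = base_probs(gc))
}

revcomp_chr <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(
    x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE
  ))
}

# a unit is primitive iff it is not an exact repetition of a shorter string;
# only divisor periods can generate it
is_primitive_unit <- function(u) {
  n <- nchar(u)
  if (n == 1L) return(TRUE)
  for (d in seq_len(n %/% 2)) {
    if (n %% d == 0L &&
        identical(strrep(substr(u, 1L, d), n %/% d), u)) {
      return(FALSE)
    }
  }
  TRUE
}

#' Simulate a synthetic genome cohort with planted ground truth
#'
#' Generates linear genomes with i.i.d. background sequence at the configured
#' GC content, plants terminal inverted repeats, non-overlapping gene
#' intervals, perfect tandem-repeat regions (each flanked by deliberately
#' non-extending bases so maximality is exact, with primitive,
#' rejection-sampled units), single-copy ortholog groups with positional
#' jitter, and multicopy subfamilies laid out in proximity runs. The same
#' seed reproduces byte-identical output.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_cohort`: `genomes` (genome tibble),
#'   `annotations` (annotation tibble; ortholog-group and multicopy labels in
#'   `subfamily`), and `truth` — a list with `repeats` (planted regions with
#'   `category`/`div3`), `itr` (per-genome planted length), `groups`
#'   (per-group true position and jitter SD) and `group_members` (realised
#'   member positions).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config

  withr_seed <- function(s, code) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else {
      NULL
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(s)
    code
  }

  lens <- withr_seed(stage_seed(cf$seed, 1L), {
    round(stats::runif(cf$n_genomes, cf$genome_length[1],
                       cf$genome_length[2]))
  })
  gids <- sprintf("syn%02d", seq_len(cf$n_genomes))

  genomes <- vector("list", cf$n_genomes)
  annots <- vector("list", cf$n_genomes)
  repeats <- vector("list", cf$n_genomes)

  for (i in seq_len(cf$n_genomes)) {
    L <- lens[i]
    gid <- gids[i]

    seq_chr <- withr_seed(stage_seed(cf$seed, 2L, i), {
      random_bases(L, cf$gc_content)
    })

    genes <- withr_seed(stage_seed(cf$seed, 3L, i), {
      .plant_genes(L, cf, gid)
    })

    planted <- withr_seed(stage_seed(cf$seed, 4L, i), {
      .plant_repeats(seq_chr, L, genes, cf, gid)
    })
    seq_chr <- planted$seq_chr

    if (cf$itr_length > 0L) {
      seq_chr <- withr_seed(stage_seed(cf$seed, 5L, i), {
        .plant_itr(seq_chr, L, cf)
      })
    }

    genomes[[i]] <- tibble::tibble(
      genome_id = gid,
      sequence = paste(seq_chr, collapse = ""),
      length = as.integer(L),
      topology = "linear"
    )
    annots[[i]] <- genes
    repeats[[i]] <- planted$truth
  }

  genomes <- dplyr::bind_rows(genomes)
  annotations <- dplyr::bind_rows(annots)
  truth_repeats <- dplyr::bind_rows(repeats)

  grp <- withr_seed(stage_seed(cf$seed, 6L), {
    .assign_groups(annotations, genomes, cf)
  })
  annotations <- grp$annotations

  annotations <- withr_seed(stage_seed(cf$seed, 7L), {
    .assign_multicopy(annotations, cf)
  })

  structure(
    list(
      genomes = genomes,
      annotations = annotations,
      truth = list(
        repeats = truth_repeats,
        itr = tibble::tibble(genome_id = gids,
                             itr_length = cf$itr_length),
        groups = grp$groups,
        group_members = grp$members
      ),
      config = cf
    ),
    class = "sim_cohort"
  )
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$genomes), "genomes,",
      format(sum(x$genomes$length), big.mark = ","), "bp;",
      nrow(x$truth$repeats), "planted repeat regions;",
      nrow(x$truth$groups), "ortholog groups\n")
  invisible(x)
}

# tile [itr+margin, L-itr-margin) with alternating gene/gap intervals;
# coverage ~ gene_density via exponential gaps
.plant_genes <- function(L, cf, gid) {
  lo <- cf$itr_length
  hi <- L - cf$itr_length
  mean_gap <- cf$mean_gene_len * (1 - cf$gene_density) /
    max(cf$gene_density, 1e-6)
  starts <- integer()
  ends <- integer()
  pos <- lo
  while (TRUE) {
    gap <- 1L + stats::rpois(1L, max(mean_gap - 1, 0))
    glen <- max(150L, round(stats::rgamma(1L, shape = 4,
                                          rate = 4 / cf$mean_gene_len)))
    if (pos + gap + glen > hi) break
    starts <- c(starts, pos + gap)
    ends <- c(ends, pos + gap + glen)
    pos <- pos + gap + glen
  }
  n <- length(starts)
  tibble::tibble(
    genome_id = gid,
    gene_id = sprintf("%s_g%04d", gid, seq_len(n)),
    start = as.integer(starts),
    end = as.integer(ends),
    strand = sample(c("+", "-"), n, replace = TRUE),
    subfamily = NA_character_
  )
}

# draw a unit length from the clipped lognormal, snapped onto (or off) the
# multiples of 3 according to the planted category
.draw_unit_len <- function(cf, div3) {
  cv2 <- (cf$unit_len_sd / cf$unit_len_mean)^2
  sdlog <- sqrt(log(1 + cv2))
  meanlog <- log(cf$unit_len_mean) - sdlog^2 / 2
  len <- round(stats::rlnorm(1L, meanlog, sdlog))
  len <- min(max(len, cf$unit_len_range[1]), cf$unit_len_range[2])
  if (div3) {
    len <- max(3L * round(len / 3), cf$unit_len_range[1])
    if (len %% 3L != 0L) len <- len + (3L - len %% 3L)  # bumped by clip
  } else if (len %% 3L == 0L) {
    len <- if (len + 1L <= cf$unit_len_range[2]) len + 1L else len - 1L
  }
  as.integer(len)
}

.draw_unit <- function(len, gc) {
  for (tries in 1:50) {
    u <- paste(random_bases(len, gc), collapse = "")
    if (is_primitive_unit(u)) return(u)
  }
  stop("failed to draw a primitive unit of length ", len, call. = FALSE)
}

# plant tandem arrays into the background; flanking bases are redrawn to
# differ from the would-be periodic extension so each array is exactly
# maximal. Returns the modified sequence and the truth table.
.plant_repeats <- function(seq_chr, L, genes, cf, gid) {
  n_rep <- round(cf$repeat_density * L / 1e5)
  if (n_rep == 0L) {
    return(list(seq_chr = seq_chr, truth = NULL))
  }
  margin <- 8L
  lo <- cf$itr_length + 1L
  hi <- L - cf$itr_length

  gene_tbl <- genes[order(genes$start), ]
  gaps <- tibble::tibble(
    start = c(lo, gene_tbl$end),
    end = c(gene_tbl$start, hi)
  )
  gaps <- gaps[gaps$end - gaps$start > 0, ]

  occupied_s <- integer()
  occupied_e <- integer()
  overlaps_occupied <- function(s, e) {
    any(s < occupied_e & occupied_s < e)
  }
  resample1 <- function(x) x[sample.int(length(x), 1L)]  # safe for length 1

  rows <- vector("list", n_rep)
  for (k in seq_len(n_rep)) {
    genic <- stats::runif(1) < cf$genic_fraction
    div3 <- stats::runif(1) <
      if (genic) cf$div3_genic else cf$div3_intergenic
    placed <- FALSE
    for (tries in 1:200) {
      period <- .draw_unit_len(cf, div3)
      copies <- cf$copies_min +
        stats::rpois(1L, cf$copies_mean - cf$copies_min)
      # planted regions must satisfy the default inventory filters by
      # construction: top up copies so the span reaches min_span
      copies <- max(copies, as.integer(ceiling(cf$min_span / period)))
      alen <- period * copies
      if (genic) {
        ok <- gene_tbl$end - gene_tbl$start >= alen + 2L * margin
        if (!any(ok)) next
        g <- gene_tbl[resample1(which(ok)), ]
        s <- resample1(seq.int(g$start + margin, g$end - margin - alen))
      } else {
        ok <- gaps$end - gaps$start >= alen + 4L
        if (!any(ok)) next
        gp <- gaps[resample1(which(ok)), ]
        s <- resample1(seq.int(gp$start + 2L, gp$end - 2L - alen))
      }
      e <- s + alen
      if (overlaps_occupied(s - 2L, e + 2L)) next
      unit <- .draw_unit(period, cf$gc_content)
      ubase <- strsplit(unit, "")[[1]]
      seq_chr[seq.int(s + 1L, e)] <- rep(ubase, copies)
      # non-extending flanks: left must differ from unit's last base,
      # right from unit's first base
      seq_chr[s] <- sample(setdiff(DNA_BASES, ubase[period]), 1L)
      seq_chr[e + 1L] <- sample(setdiff(DNA_BASES, ubase[1L]), 1L)
      occupied_s <- c(occupied_s, s - 1L)
      occupied_e <- c(occupied_e, e + 1L)
      rows[[k]] <- tibble::tibble(
        genome_id = gid,
        start = as.integer(s), end = as.integer(e),
        period = period, copies = copies, unit = unit,
        category = if (genic) "genic" else "intergenic",
        div3 = period %% 3L == 0L
      )
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("infeasible packing: could not place planted repeat ", k,
           " of ", n_rep, " in genome ", gid,
           " (genic capacity exhausted)", call. = FALSE)
    }
  }
  list(seq_chr = seq_chr, truth = dplyr::bind_rows(rows))
}

# right terminus becomes the reverse complement of the left, optionally
# mutated; the base just inside each boundary is forced to mismatch so the
# planted length is exactly maximal
.plant_itr <- function(seq_chr, L, cf) {
  itr <- cf$itr_length
  left <- seq_chr[seq_len(itr)]
  right <- rev(chartr("ACGT", "TGCA", left))
  if (cf$itr_mismatch_rate > 0) {
    nmut <- stats::rbinom(1L, itr, cf$itr_mismatch_rate)
    if (nmut > 0L) {
      at <- sample.int(itr, nmut)
      right[at] <- vapply(right[at], function(b) {
        sample(setdiff(DNA_BASES, b), 1L)
      }, character(1), USE.NAMES = FALSE)
    }
  }
  seq_chr[seq.int(L - itr + 1L, L)] <- right
  # maximality: base itr+1 from the left must mismatch the complement of
  # base L-itr from the right
  partner <- chartr("ACGT", "TGCA", seq_chr[L - itr])
  if (seq_chr[itr + 1L] == partner) {
    seq_chr[itr + 1L] <- sample(setdiff(DNA_BASES, partner), 1L)
  }
  seq_chr
}

# ortholog groups: conserved normalized positions with per-group jitter;
# each present genome contributes its gene nearest the jittered target
.assign_groups <- function(annotations, genomes, cf) {
  if (cf$n_groups == 0L) {
    return(list(
      annotations = annotations,
      groups = tibble::tibble(group_id = character(), true_position = numeric(),
                              jitter_sd = numeric()),
      members = tibble::tibble(group_id = character(), genome_id = character(),
                               gene_id = character(), position = numeric())
    ))
  }
  sds <- rep_len(cf$group_jitter_sd, cf$n_groups)
  groups <- tibble::tibble(
    group_id = sprintf("og%04d", seq_len(cf$n_groups)),
    true_position = stats::runif(cf$n_groups, 0.05, 0.95),
    jitter_sd = sds
  )
  glen <- stats::setNames(as.numeric(genomes$length), genomes$genome_id)
  ann <- annotations
  ann$mid_frac <- (ann$start + ann$end) / 2 / glen[ann$genome_id]
  free <- is.na(ann$subfamily)

  members <- vector("list", cf$n_groups * nrow(genomes))
  mi <- 0L
  for (g in seq_len(cf$n_groups)) {
    for (gid in genomes$genome_id) {
      if (stats::runif(1) > cf$group_presence) next
      target <- min(max(groups$true_position[g] +
                          stats::rnorm(1, 0, groups$jitter_sd[g]),
                        0.01), 0.99)
      idx <- which(free & ann$genome_id == gid)
      if (length(idx) == 0L) next
      pick <- idx[which.min(abs(ann$mid_frac[idx] - target))]
      ann$subfamily[pick] <- groups$group_id[g]
      free[pick] <- FALSE
      mi <- mi + 1L
      members[[mi]] <- tibble::tibble(
        group_id = groups$group_id[g],
        genome_id = gid,
        gene_id = ann$gene_id[pick],
        position = ann$mid_frac[pick]
      )
    }
  }
  ann$mid_frac <- NULL
  list(
    annotations = ann,
    groups = groups,
    members = dplyr::bind_rows(members[seq_len(mi)])
  )
}

# multicopy subfamilies: per genome, a run of near-adjacent unlabeled genes
# (ordinal steps of 1-2) so members sit in genomic proximity
.assign_multicopy <- function(annotations, cf) {
  if (cf$n_multicopy_subfams == 0L) return(annotations)
  ann <- annotations
  for (s in seq_len(cf$n_multicopy_subfams)) {
    sf <- sprintf("subfam%03d", s)
    for (gid in unique(ann$genome_id)) {
      k <- stats::rpois(1L, cf$multicopy_mean - 1) + 1L
      idx <- which(ann$genome_id == gid & is.na(ann$subfamily))
      if (length(idx) < k) next
      idx <- idx[order(ann$start[idx])]
      anchor <- sample.int(max(length(idx) - 2L * k, 1L), 1L)
      steps <- cumsum(c(0L, sample(1:2, k - 1L, replace = TRUE)))
      pick <- idx[pmin(anchor + steps, length(idx))]
      pick <- unique(pick)
      ann$subfamily[pick] <- sf
    }
  }
  ann
}

#' Match detected features against planted truth
#'
#' For repeat regions, a detected region matches a planted one when their
#' intervals overlap reciprocally by at least `min_overlap` (fraction of each
#' interval) and the periods agree or are integer harmonics of one another.
#' Precision is matched/detected (reported as 1 with `no_detections = TRUE`
#' when nothing was detected), recall matched/planted.
#'
#' @param truth Planted repeat tibble (`truth$repeats` of a [simulate_cohort()]
#'   result).
#' @param detected Detected region tibble ([find_repeat_regions()] output).
#' @param min_overlap Reciprocal overlap fraction (default 0.9).
#' @return A list of class `recovery_report`: `precision`, `recall`,
#'   `matches` tibble (one row per detected region with its matched planted
#'   interval, if any), `no_detections` flag.
#' @export
evaluate_recovery <- function(truth, detected, min_overlap = 0.9) {
  if (nrow(detected) == 0L) {
    return(structure(
      list(precision = 1, recall = 0,
           matches = tibble::tibble(), no_detections = TRUE),
      class = "recovery_report"
    ))
  }
  harmonics <- function(p, q) p %% q == 0L | q %% p == 0L
  truth <- dplyr::mutate(truth, .tid = dplyr::row_number())
  det <- dplyr::mutate(detected, .did = dplyr::row_number())
  cand <- dplyr::inner_join(
    det[, c(".did", "genome_id", "start", "end", "period")],
    truth[, c(".tid", "genome_id", "start", "end", "period")],
    by = "genome_id", suffix = c("_d", "_t"),
    relationship = "many-to-many"
  ) |>
    dplyr::mutate(
      ov = pmax(0, pmin(.data$end_d, .data$end_t) -
                  pmax(.data$start_d, .data$start_t)),
      rec_d = .data$ov / (.data$end_d - .data$start_d),
      rec_t = .data$ov / (.data$end_t - .data$start_t)
    ) |>
    dplyr::filter(
      .data$rec_d >= min_overlap, .data$rec_t >= min_overlap,
      harmonics(.data$period_d, .data$period_t)
    )
  matched_det <- unique(cand$.did)
  matched_truth <- unique(cand$.tid)
  matches <- det |>
    dplyr::left_join(
      cand |>
        dplyr::group_by(.data$.did) |>
        dplyr::slice_max(.data$ov, n = 1L, with_ties = FALSE) |>
        dplyr::ungroup() |>
        dplyr::select(".did", ".tid", "start_t", "end_t", "period_t"),
      by = ".did"
    ) |>
    dplyr::mutate(matched = !is.na(.data$.tid)) |>
    dplyr::select(-".did", -".tid")
  structure(
    list(
      precision = length(matched_det) / nrow(det),
      recall = length(matched_truth) / nrow(truth),
      matches = matches,
      no_detections = FALSE
    ),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Recovery: precision %.3f, recall %.3f (%d detected)\n",
              x$precision, x$recall, nrow(x$matches)))
  if (x$no_detections) cat("  (no detections)\n")
  invisible(x)
}
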