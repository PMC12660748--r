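# tandemarch

Tandem-repeat inventory and genome-architecture analysis for cohorts of
linear genomes — built around the architecture of Borg extrachromosomal
elements of *Methanoperedens* archaea and the giant eukaryotic viruses they
resemble, and applicable to any set of linear replicons with gene
annotations.

## What it computes

Megabase-scale linear elements such as Borgs are peppered with **perfect
tandem repeats** (exact, contiguous repetitions of a DNA unit), are
terminated by **long inverted repeats**, carry **multicopy protein
subfamilies** often encoded in close proximity, and preserve a backbone of
single-copy genes at **conserved relative genomic positions**. This package
quantifies all four:

* **Repeat inventory.** Every maximal perfect tandem array is found at its
  *primitive period* p (the smallest unit length generating the array; a
  period-2k reading of a period-k repeat is suppressed). Arrays are merged
  into repeat regions and filtered by the inventory thresholds — span ≥ 50
  bp, ≥ 3 complete unit copies, unit ≥ 9 bp.
* **Classification.** A region is *genic* iff fully contained in a gene
  interval, and *div-by-3* iff 3 | p (an in-frame genic repeat yields
  amino-acid repeats). Cohort statistics report region density per 10⁵ bp,
  copies/region and unit length as across-genome mean ± sample SD, plus
  pooled integer-percentage splits.
* **Architecture.** Terminal-inverted-repeat detection (scored mismatch-
  tolerant extension from both termini); normalized gene positions
  (midpoint / genome length ∈ [0,1]) with per-group mean ± SD and the
  fraction of groups with SD ≤ 0.1; subfamily × genome copy-number
  matrices; single-linkage proximity clusters of multicopy genes on gene
  ordinals.
* **Synthetic cohorts.** A seeded generator plants genomes with ITRs,
  genes, primitive tandem repeats (44% genic, 99%/24% div-3, ~5 regions
  per 100 kbp, ~25 bp units) and jittered ortholog groups, with exact
  ground truth for recovery testing.

## Worked example

```r
library(tandemarch)

sim        <- simulate_cohort(sim_config(n_genomes = 3, seed = 7))
regions    <- find_repeat_regions(sim$genomes)          # detect + merge + filter
classified <- classify_regions(regions, sim$annotations)
summary    <- summarize_cohort(summarize_genomes(classified, sim$genomes))
summary
#> Cohort repeat summary (3 genomes, 2,564,159 bp)
#>   regions: 128 | density 4.98 +/- 0.04 per 100 kbp
#>   copies/region 5.2 +/- 0.3 | unit length 23.0 +/- 1.5 bp
#>   genic 39% (50) / intergenic 61% (78)

detect_itr(sim$genomes)[, c("genome_id", "itr_length", "mismatch_count")]
#> # A tibble: 3 × 3
#>   genome_id itr_length mismatch_count
#> 1 syn01           1000              0
#> 2 syn02           1000              0
#> 3 syn03           1000              0
```

The three simulated genomes (~2.6 Mbp total) carry 128 planted repeat
regions; the detector recovers a density of 4.98 regions per 100 kbp
(configured: 5), a mean unit length of 23.0 bp (configured: 25, SD 16 —
three genomes leave visible sampling noise), 39% of regions inside genes
(configured: 44%), and the planted 1000 bp terminal inverted repeats
exactly, with zero mismatches. `evaluate_recovery(sim$truth$repeats,
classified)` reports precision and recall 1.0 against the planted truth.

For real data, replace the simulation with

```r
genomes     <- read_genomes("cohort.fasta")
annotations <- read_annotations("genes.tsv", genomes)   # GFF3 also accepted
```

or run everything (including output tables and a run manifest) through
`run_pipeline("cohort.yaml", "results/")`.

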