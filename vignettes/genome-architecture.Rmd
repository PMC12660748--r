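---
title: "Tandem repeats and genome architecture of linear megabase elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tandem repeats and genome architecture of linear megabase elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tandemarch)
library(dplyr)
```

## The analyses

Borgs — linear, megabase-scale extrachromosomal elements of anaerobic
methane-oxidising *Methanoperedens* archaea — and the giant eukaryotic
viruses they resemble share a set of striking genome-architecture features:
long terminal inverted repeats (ITRs), pervasive perfect tandem-repeat
regions, multicopy protein subfamilies often encoded in close proximity, and
a conserved backbone of single-copy genes that sit at similar relative
positions across genomes. `tandemarch` implements the quantitative side of
those observations as a reproducible pipeline:

1. **Perfect tandem-repeat inventory** — detection of maximal perfect
   tandem arrays, canonicalised to their primitive period; assembly into
   repeat regions; filtering by the inventory thresholds (region span ≥ 50
   bp, ≥ 3 complete unit copies, unit ≥ 9 bp).
2. **Genic/intergenic classification** with the div-by-3 flag (a unit
   length divisible by three preserves reading frame, so an in-frame genic
   repeat generates amino-acid repeats).
3. **Cohort statistics** — per-genome region density per 100 kbp, copies
   per region, mean unit length; pooled two-way percentage splits; repeat
   position tracks.
4. **Architecture analyses** — ITR detection, normalized gene-position
   conservation, subfamily copy-number matrices, proximity clustering of
   multicopy genes.
5. **A synthetic-cohort generator** that plants all of these features with
   known ground truth, so every stage is testable without any download.

## Repeat model and canonicalisation

A *maximal perfect tandem array* is an interval consisting of at least two
exact copies of a unit (plus possibly an exact partial trailing copy) that
cannot be extended by one base on either side at the same period. Every
array is reported at its **primitive period**: a period-2k reading of a
period-k repeat is suppressed, so a homopolymer is a single period-1 array
and can never masquerade as a ≥ 9 bp unit. Internally the scanner sweeps
every period p up to `max_unit_len`, finds runs of lag-p matches, and keeps
a run only when the minimal period of the interval (via the KMP border
array) equals p. `N` matches nothing — not even itself — so arrays never
cross an ambiguous base and a region split by an `N` is reported as two
regions.

Complete copies are counted as `floor(span / period)`; the span still
includes an exact partial trailing copy. Filters (span ≥ 50, copies ≥ 3,
unit ≥ 9 under the defaults) are applied conjunctively after merging.

**Region assembly.** Arrays that overlap or abut (within `merge_gap`,
default 0) merge into one region spanning their union; the region inherits
unit, period and copy count from its longest-span constituent, ties going
to the smaller period and then the leftmost start. Only arrays whose period
meets the unit-length threshold take part: random DNA carries a period ≤ 8
micro-array every few bases, and letting that microsatellite dust chain
onto real loci would nudge essentially every region boundary and
occasionally flip a genic call at a gene edge. The thresholds thereby act
where a locus is defined, not merely as an after-the-fact filter; the
filtering step still applies all three criteria to whatever table it is
given.

A region is **genic** only when fully contained inside an annotated gene
interval; everything else, including regions straddling a gene boundary, is
intergenic. This mirrors a two-way published split whose genic criterion is
containment; the complement is everything else. Containment ignores strand.
When overlapping genes both contain a region, the shortest (most specific)
gene is recorded, ties leftmost — a determinism rule, not a biological
claim.

## Coordinates

All internal intervals are 0-based half-open, which makes lengths
subtractions and containment checks closed under composition. Every
external file — FASTA headers aside, GFF3 or the TSV annotation dialect on
the way in, all TSV tables on the way out — is 1-based inclusive. The
conversion is applied exactly once at each boundary and is round-trip
exact.

## ITR detection

For a linear genome the detector compares base *i* from the left terminus
with the complement of base *i* from the right terminus and scores each
extension length L as `matches − ((1 − f)/f) · mismatches`, with f the
mismatch tolerance (default 0.05). The reported ITR is the longest L
attaining the maximal score, provided L ≥ `min_len` (default 20 bp), the
score is positive and the realised mismatch fraction stays within f. A
plain cumulative-budget rule ("extend while mismatches ≤ f·L") was
rejected: inside a long perfect ITR it accrues budget that it then spends
walking ~ f/(0.75 − f) of the ITR length into random sequence, so planted
lengths would systematically overshoot. With the scored rule an overshoot
requires ~19 chance matches in a row (probability ≈ 4⁻¹⁹), and a planted
ITR is recovered exactly at 0% mismatch. Extension is capped at half the
genome so the two copies never overlap.

## Positional conservation

A gene's normalized position is its interval midpoint divided by genome
length — midpoints are robust to unequal gene lengths, and genomes are
taken in deposited orientation. Groups (ortholog labels or subfamilies)
restricted to single-copy occurrences in ≥ `min_genomes` genomes get a mean
and sample SD of position; a group is *positionally conserved* when its SD
is at most `sd_threshold` (default 0.1), and the same threshold defines the
count of conserved groups present in ≥ 7 genomes. Genomes carrying a group
in several copies are dropped from that group with a warning rather than
failing the run.

## The synthetic cohort

`simulate_cohort()` emulates the statistical structure of a 17-genome
cohort of linear elements. Defaults (all overridable) are the study
conditions:

| Parameter | Default | Meaning |
|---|---|---|
| `n_genomes` | 17 | cohort size |
| `genome_length` | 0.5–1.1 Mbp | drawn uniformly per genome |
| `gc_content` | 0.35 | i.i.d. background, AT-rich like the real elements |
| `itr_length` | 1000 bp | planted terminal inverted repeat |
| `gene_density` | 0.8 | fraction of genome covered by genes |
| `mean_gene_len` | 1000 bp | gamma-distributed gene lengths |
| `repeat_density` | 5 / 100 kbp | planted repeat regions |
| `unit_len_mean`, `unit_len_sd` | 25, 16 bp | lognormal, clipped to 9–200 bp |
| `copies_min`, `copies_mean` | 3, 5 | 3 + Poisson(2) copies |
| `genic_fraction` | 0.44 | planted inside genes |
| `div3_genic`, `div3_intergenic` | 0.99, 0.24 | unit length divisible by 3 |
| `group_jitter_sd` | 0.05 | positional jitter of ortholog groups |

The unit-length lognormal is moment-matched (`sdlog² = log(1 + (16/25)²)`,
`meanlog = log 25 − sdlog²/2`) and clipped, which leaves the realised mean
within a fraction of a base of 25 bp. Genic units are snapped to the
nearest multiple of 3 (intergenic off it) according to the div-3
probabilities; the snap moves a length by at most one base. Copy numbers
are topped up so that every planted region satisfies span ≥ 50 bp — the
generator guarantees its truth is detectable under the default filters.
Units are rejection-sampled to be primitive, and every planted feature gets
a deliberately non-matching flanking base (likewise one base just inside
each ITR boundary), so maximality — and hence exact coordinate recovery —
is well defined rather than probabilistic.

Each generation stage (genome lengths, background sequence, genes, repeats,
ITR, ortholog groups, multicopy subfamilies) draws from its own seed
derived from the master seed, so changing the group or subfamily settings
reproduces byte-identical sequences and planted repeats. Gene placement
necessarily feeds the genic repeat positions (containment is the planted
property), so altering the gene model does re-place repeats; the background
sequence itself is unaffected.

What the generator does **not** emulate: real coding sequence (background
is i.i.d.), repeat-unit families shared across loci, nested or approximate
repeats, replichore structure, and assembly artefacts. Green tests
therefore demonstrate algorithmic correctness on clean truth, not
robustness to the full messiness of environmental assemblies.

## Numerical conventions and edge cases

* Percentages are integer, rounded half-up, mirroring how the published
  tables print them; means/SDs display with one decimal, densities two.
* Across-genome spreads are sample SDs (n − 1); a single genome reports 0.
* A genome with no regions reports zero density and an `empty` flag.
* `evaluate_recovery()` matches a detected region to a planted one at ≥ 90%
  reciprocal overlap with equal or harmonic periods; an empty detection set
  reports precision 1 with a `no_detections` flag.
* Repeat-unit novelty compares units with match-count identity, maximised
  over all cyclic rotations of either orientation, normalised by the longer
  unit; the "shared" threshold (0.8) is this package's own default, since
  no quantitative threshold for "novel" is published.

## Worked-example scale

The acceptance script and test suite run everything at desk scale: the
closure analysis uses the default 17-genome cohort (~13.6 Mbp total,
roughly two minutes of scanning on one CPU), oracle cross-checks use 200
sequences of ≤ 3 kb, and jitter-recovery uses 12 genomes of 400 kbp. The
same functions run unchanged on real cohorts of deposited genomes; a
17-genome megabase cohort at `max_unit_len = 500` completes in minutes.

## A note on one published number

The complete ~4 Mbp *Methanoperedens* genome is reported with repeat
density "0.053 ± 0" per 100 kbp alongside 2 repeat regions and a
4,003,972 bp genome. Recomputing density as regions / genome length ×
100,000 gives 0.050. The package reports its own arithmetic (and displays
0.05); the 0.053 could reflect a different denominator or count upstream,
and is documented here rather than asserted.

## Limitations

* Only perfect (exact) tandem repeats are inventoried; mismatch-tolerant
  repeat models are out of scope, so diverged repeat copies fragment into
  shorter perfect arrays.
* The genic/intergenic rule is containment-only; partial overlaps are not
  apportioned.
* Ortholog groups are taken from labels, never inferred from sequence.
* ITR detection assumes the deposited sequence ends are the element's
  termini; trimmed or scaffolded assemblies will shorten or hide ITRs.
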