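---
title: "QTLome analysis with qtlome: models, thresholds and design choices"
author: "qtlome authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QTLome analysis with qtlome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Public QTL databases such as AnimalQTLdb accumulate hundreds of thousands
of quantitative trait locus annotations for livestock species. The raw
catalogues are noisy: the same association is deposited repeatedly across
studies and array versions, some records lack coordinates or carry
impossible positions, and confidence intervals range from single base
pairs (SNP-type records) to hundreds of megabases. Before any statement
about where QTL concentrate in a genome can be made, the catalogue has to
be curated into a set of unique, comparably-sized intervals; afterwards,
the interesting questions are distributional: does QTL density follow gene
density and chromosome size, which chromosomes and windows carry more QTL
than a neutral placement law predicts, and which genomic windows are
specifically enriched for particular phenotypic categories.

`qtlome` implements that whole chain — quality control and merging,
fixed-window density computation, correlation analysis with permutation
p-values, and three enrichment frameworks plus a resampling overlap test —
together with a synthetic QTLome generator so every stage can be validated
against planted ground truth without downloading anything.

## Coordinate conventions

Internally every interval is 0-based, half-open (`[start, end)`), so
lengths are always `end - start` and BED interoperability is direct. GFF
input and output convert at the boundary (1-based inclusive on disk), and
the conversion is an involution: exporting and re-importing records is the
identity. Midpoints are `floor((start + end) / 2)`.

## The quality-control cascade

`qc_cascade()` applies, in order:

1. **Anomaly filters** (`filter_anomalies()`). Records are removed — and
   counted under exactly one ledger reason, first matching rule wins — when
   they (a) lack coordinates, or have `start >= end` or a negative start;
   (b) lie on a chromosome absent from the assembly or extend past the
   chromosome end; (c) exceed `max_qtl_length` (default 10 Mbp). Filters
   never raise on record content: real catalogues contain these records,
   and the cascade's job is to count and quarantine them, not to crash.
2. **Duplicate removal** (`deduplicate()`). Records sharing chromosome,
   coordinates, trait name and study id are repeated annotations; the
   first occurrence is kept. Breed is deliberately not part of the key —
   it is missing from many records. A looser, position-only key is
   available (`key = "position"`) because "unique QTL" is used in both
   senses in database summaries; the stricter key is the default.
3. **Same-key merging** (`cluster_and_merge()`). Within each (chromosome,
   study, trait) group, single-linkage chaining joins records that overlap
   by at least 1 bp or are separated by less than `merge_gap` (500 kbp,
   strict: a gap of exactly 500 kbp does not merge). A cluster whose span
   is at most `merge_span_cap` (1 Mbp) collapses to one record covering
   the span. Longer clusters trigger the **densest-window fallback**
   (`densest_windows()`): 1 Mbp tiles anchored at the span start with a
   500 kbp step are scored by member midpoints, then selected greedily by
   descending score (ties: leftmost), skipping overlaps, until the
   selected length reaches 30% of the span. The tiling, step, midpoint
   scoring and greedy rule are this package's construction — only the
   1 Mbp window size and the 30% coverage floor are externally fixed — and
   they were chosen to make the result order-independent (coordinate
   tie-breaks, never input order) and reproducible.
4. **Size standardization** (`standardize_sizes()`). Records shorter than
   250 kbp are expanded and records longer than 1 Mbp trimmed to the band
   limit, centered on the midpoint. Intervals pushed past a chromosome
   boundary are shifted inward with length preserved; only a chromosome
   shorter than the standard length clamps the record.

**Fixed-point iteration.** Standardization can move two same-key records
back within merging distance (expanding two nearby SNPs to 250 kbp each
can shrink their gap below 500 kbp), and the fallback can emit adjacent
windows. A single merge-then-standardize pass is therefore not stable
under re-analysis. `qc_cascade()` iterates the merge and standardization
steps until the record set stops changing (capped at 25 iterations; in
practice two or three suffice), which makes the cascade idempotent: running
QC on its own output changes nothing, and the ledger's conservation
identity — input count equals output count plus every removal and merge
reduction — holds on every run.

## Windowing and density

`make_grid()` tiles each chromosome into fixed windows (0.25 / 1 / 2.5 /
5 Mbp are the standard scales); the final partial window is kept and
flagged. `count_features()` assigns each feature to exactly **one** window
— the window containing its midpoint — rather than to every window it
overlaps. The midpoint rule is what makes per-window counts sum to the
database total, which the hypergeometric trait test implicitly requires
(its population is the finite database), and it makes counts aggregate
exactly across nested scales. Per-window study and trait counts are counts
of *distinct* study ids and trait names among the window's QTL. Genome
coverage is the length of the interval union (via
`GenomicRanges::reduce()`) over the assembly length. Per-chromosome
density summaries use the conventional sample median (mean of central pair
for even window counts).

Partial windows shorter than half the window size distort density
comparisons, so enrichment functions skip them by default
(`min_window_fraction = 0.5`, configurable down to 0).

## Correlations and permutation p-values

All correlations are Pearson (`pearson_r()`); constant vectors raise an
undefined-correlation error and the affected unit is *excluded*, never
scored 0, so means over cells are not biased toward zero.
`permutation_pvalue()` permutes one vector with a seeded generator and
reports the two-sided "at least as extreme" p-value with the +1
correction, `p = (1 + #{|r_perm| >= |r_obs|}) / (n_perm + 1)` — bounded
below by `1/(n_perm + 1)`, reproducible bit-for-bit. Which vector is
permuted and the tail convention are this package's fixed choices; the +1
correction is standard permutation-test practice and guarantees `p > 0`.

Two scales are provided: `genome_level_correlations()` correlates
per-chromosome QTL counts with gene counts and chromosome lengths (with a
leave-out argument for outlier-chromosome analyses), and
`window_level_matrix()` builds the chromosome-by-scale matrix of
within-chromosome window-density correlations, excluding chromosomes with
fewer than 10 windows at a scale, with the per-scale mean of included
cells (`rbar()`). Under gene-proportional placement the mean correlation
rises with window size — coarser windows average away placement noise — a
pattern the synthetic generator reproduces and the test suite checks
qualitatively.

A single master seed drives everything; each test derives its own seed by
hashing its label (`derive_seed()`), so streams are decorrelated but the
whole analysis is reproducible from one integer.

## Enrichment tests

**Chromosome level** (`chromosome_enrichment()`): the observed QTL count
per chromosome against `Binom(n, p)` with `n` the genome-wide QTL count
and `p` the chromosome's fraction of the assembly; expectation `n * p`.
The test is the exact two-tailed binomial (`binomial_two_sided()`, the
`binom.test` convention: sum of all outcome probabilities not exceeding
the observed one, with the usual `1e-7` relative tolerance).

**Window level** (`window_enrichment()`): the same exact test per window
with `p` the window's share of all genes. Windows with zero genes are
skipped and reported — the null probability is literally a gene
proportion, and inventing a pseudo-count floor would change the null.

**Trait level** (`trait_window_enrichment()`): for each phenotypic label
(class, type or trait) and each window containing at least one QTL for
it, the upper-tail hypergeometric probability of drawing that many label
QTL into the window: `phyper(q - 1, m, N - m, k, lower.tail = FALSE)`
with `m` the window's QTL count, `N` the database total and `k` the
label's database count. The test is one-tailed upper — the question is
over-representation.

**Multiple testing**: Benjamini–Hochberg throughout
(`benjamini_hochberg()`, a validated wrapper over `p.adjust`). Family
boundaries are a genuine free choice; the default is one family per
chromosome set, per window set, and per *label* across windows for the
trait test (matching how per-trait Manhattan panels are read), with
`bh_family = "global"` pooling all trait tests instead.

**Numerical floor**: p-values that underflow double precision (deeply
enriched hotspots) are reported as the smallest positive double rather
than 0, keeping downstream `(0, 1]` contracts intact.

## Resampling overlap test

`permutation_overlap_test()` asks whether unique QTL — deduplicated and
recentred to 250 kbp around their midpoints (`prepare_unique_qtl()`) —
overlap a gene set of interest more than chance. The null is built either
by drawing same-size gene sets without replacement from the gene universe
(`random_genes`) or by placing length-matched segments uniformly on the
assembly with redraws at chromosome ends (`random_segments`). Enrichment
is one-tailed upper with the same +1 p-value convention, plus a z-score
against the null distribution. Because every query interval is 250 kbp,
matching segment lengths to the queries and using a fixed 250 kbp segment
length coincide.

## The synthetic QTLome generator

`sim_config()` / `simulate_qtlome()` emulate the statistical structure the
pipeline assumes: multi-chromosome genomes with log-normal lengths,
piecewise-constant gene density, a study table and a class > type > trait
hierarchy with log-normal size heterogeneity, QTL placed by a mixture of
uniform-by-length and gene-proportional components, hotspot windows whose
`lambda` multiplies the base intensity (implemented by rejection sampling,
so the planted intensity is exact), optional trait forcing inside hotspots,
SNP-type 1 bp records alongside log-uniform interval lengths, and injected
corruption — duplicates, missing coordinates, `start >= end` and negative
starts, off-chromosome and beyond-end positions, over-long records — at
configurable rates with exact planted counts. Clean records are forced
unique on the duplicate key so the QC ledger must recover the planted
counts *exactly*, not approximately.

Defaults describe a mid-sized livestock catalogue: 6 chromosomes around
80 Mbp, ~7 genes per Mbp, 60 studies, 4/10/40 classes/types/traits, 5,000
QTL with 60% SNP-type records, 15% duplicates and 5% anomalies — orders of
magnitude chosen to mirror real AnimalQTLdb species files while staying
desk-sized. What the generator does **not** emulate: linkage
disequilibrium (QTL positions are conditionally independent), breed
structure, flank-marker metadata, and the long-range autocorrelation of
real study designs. Passing tests therefore demonstrate correctness of the
statistical machinery under the stated placement laws, not that real
catalogues satisfy those laws.

## Validation design and problem sizes

The test suite validates every statistical kernel against an independent
oracle: exact tests against brute-force pmf enumeration (populations up to
200), merging against an O(n²) connected-components check (1,000 random
groups, including exact-gap non-merges), coverage against a per-base
bitmap, and counts against conservation identities at every scale.
Calibration uses 300 replicate genomes of 2,000 QTL over twenty 1 Mbp
windows with 100 bp genes — short genes make the gene-share null an exact
multinomial law, and expected counts near 100 put the exact binomial test
in the regime where its attained size is close to the nominal 5%. Because
the exact test is discrete and conservative, its rejection rate is
compared against its *analytic* attained size (rejection-region mass
computed from the pmf) rather than against 5% exactly, plus a hard upper
bound at the nominal level; a band centered exactly at 5% would reject any
correctly implemented exact test. Power checks plant `lambda = 5` window
hotspots and `lambda = 3` trait hotspots (with at least 50 forced trait
QTL) in genomes of 2,000 QTL and require recovery at BH 0.05 in at least
90% of 100 replicates. These sizes were fixed analytically before the
suite was run and are not tuned.

## Known limitations

* The densest-window fallback is one admissible construction; alternative
  tilings (e.g. sliding maximal windows) would select slightly different
  representatives for very long clusters.
* The gene-share null of the window test ignores gene length: a window's
  share is its count of gene *midpoints*. With genes much shorter than
  windows the distinction is negligible; for megabase-scale genes it is
  not.
* Attribute keys of the QTL GFF dialect vary between database exports;
  `qtl_attr_map()` must be checked against the file at hand (in
  particular, which attribute carries the study identifier — `PUBMED_ID`
  by default).
* Permutation nulls treat windows/genes as exchangeable; spatial
  autocorrelation between adjacent windows is not modelled.
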