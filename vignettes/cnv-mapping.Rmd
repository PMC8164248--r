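---
title: "Consensus CNV mapping and copy-number population differentiation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus CNV mapping and copy-number population differentiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvpop)
```

## Overview

`cnvpop` turns two breakpoint callers' structural-variant call sets into a
cohort CNV/CNVR map and a copy-number population-differentiation scan. The
pipeline has four model components: an evidence filter, a two-caller
consensus, interval merging into regions, and a variance-ratio
differentiation statistic on normalized read depth. This vignette explains
each component, its assumptions, the parameters that matter, and the
numerical choices; it also describes what the synthetic cohort generator
does and does not emulate, and therefore what a passing test suite shows.

## Coordinates

Internally every interval is 0-based half-open `[start, end)`, the BED
convention; conversion happens exactly once, at parse time. For symbolic
`<DEL>`/`<DUP>` alleles VCF places `POS` on the base before the event, so
the internal start equals `POS` and the event length is `END − POS`.
Half-open logic makes boundary behaviour unambiguous: two intervals that
merely touch share zero bases, do not count as overlapping for the
consensus intersection, and a gene touching a locus at its boundary is not
an annotation hit.

## Evidence filtering

`filter_params()` bundles the post-calling filter:

* `use_imprecise` (default `FALSE`): IMPRECISE-flagged records have
  unresolved breakpoints; keeping them inflates long duplications.
* `stringency`: the minimum summed PE + SR evidence. `medium` (t = 5) is
  the documented operating point; `low` (t = 3) and `stringent` (t = 8)
  are this package's extrapolations of the unstated neighbouring levels
  and can be overridden with `t_override`.
* `min_len` = 50 bp, `max_len` = 3 Mb (10 Mb as the documented
  alternative). An interval of exactly `min_len` is retained — "at least
  50 bp" is the conventional CNV definition — and the boundary is
  config-exposed because the strict reading ("longer than") differs by
  one base.
* `min_len_stage`: the lower cut-off can apply to raw caller records
  (`before_intersect`) or to consensus segments (`after_intersect`,
  default). The stage matters because intersection shortens intervals.
* `drop_hom_ref` (default `FALSE`): whether records genotyped 0/0 are
  dropped before intersection. Published pipelines are usually silent on
  this, so it is a switch rather than a behaviour.

## Two-caller consensus

For one sample, every pair of same-chromosome, same-type records (one per
caller) overlapping by ≥ 1 bp emits a consensus call covering the overlap
segment `[max(starts), min(ends))`. Emitting the segment rather than
either source record keeps the output symmetric in the caller labels and
reproduces a real phenomenon of such pipelines: a single long call in one
set intersecting k fragmented calls in the other yields k consensus calls,
so the combined set can exceed the smaller call set. Identical segments
arising from multiple overlapping pairs are collapsed — they are one locus
in one genome. Type matching (DEL with DEL, DUP with DUP) is an assumption
of this package; callers disagree about type rarely enough that the
alternative (type-free intersection) mainly admits noise.

## CNV regions

`merge_cnv()` pools calls over a scope (global, per population, or per
breed) and merges overlapping *and book-ended* intervals into maximal
regions, the semantics of `bedtools merge`, which this step deliberately
mirrors; a region's state is `loss` or `gain` when all member calls agree
and `both` otherwise, assigned at region level after merging. A sample is
a carrier of a region if any of its CNV overlaps the region by ≥ 1 bp, and
the region's frequency is carriers over cohort size; "present in a breed"
means at least one carrier in that breed, with no minimum-carrier rule
(real cohorts of this design contain single-sample breeds). The
catalogue-comparison report (`compare_cnvr_sets()`) returns both
directional coverage fractions, the intersection length, and the union
length of mutually overlapping region pairs, because a single "overlap"
number is ambiguous between those definitions.

## Read-depth normalization

The scan consumes per-locus read counts, normalized in three steps:

1. **RPKM** = 10⁹·RC/(TRC·S) corrects for region size S and library size
   TRC and is the only batch correction applied.
2. **GC correction**: per sample, with m the median RPKM over all loci
   and m_GC the median RPKM of the loci in the same GC bin, adjusted =
   RPKM·m/m_GC. The medians are medians *of the count signal* — overall
   and within the GC bin — following the event-wise-testing normalization
   this formula descends from. Bins are 1% GC wide with a minimum
   occupancy of 20 loci (sparser bins merge with their right neighbour;
   a sparse trailing group folds back into the previous one), which keeps
   the bin medians stable at the locus counts this package targets. A
   locus whose bin median is zero for some sample cannot be adjusted; it
   is flagged `unadjustable` and excluded downstream rather than silently
   dropped.
3. **Mappability**: division by the per-locus mappability fraction. No
   formula is standard here; plain division is this package's
   interpretation, and loci below a mappability floor (default 0.5) are
   flagged but kept.

The adjusted values are used on the linear scale as log-R-ratio proxies;
`log2_ratio = TRUE` switches to log2(adjusted / locus median) for users
who prefer a symmetric scale. The GC step is per-sample
scale-equivariant, and with a single GC bin it reduces exactly to RPKM —
both properties are tested.

## The V_ST statistic

For a locus with normalized values pooled across individuals,

V_ST = (V_T − V_S) / V_T,

with V_T the pooled sample variance and V_S the average within-population
sample variance. Sample variances use the n−1 denominator and V_S weights
populations by nᵢ−1; both choices are config-exposed (`weights =
"nminus1" | "n" | "equal"`) because the originating definition does not
pin them down. Degenerate cases are handled explicitly: populations with
fewer than two finite values are excluded from the comparison, and a
locus with V_T = 0 is non-informative (`NA`), not zero. Negative V_ST
values (within-population variance exceeding the pooled variance) are
reported as-is; clamping them to zero would distort the percentile
threshold.

The scan runs every pairwise population comparison plus one across all
populations. Within each comparison the threshold is the 99th percentile
(linear interpolation, R's default type-7 quantile) of that comparison's
finite V_ST values, and loci strictly above it are flagged. With N
distinct finite values this flags ⌈N/100⌉ loci — an outlier *budget*, not
a significance test; no multiple-testing correction is applied because
the rule is intentionally a fixed-fraction screen. The loci scanned are
the consensus-CNV footprint intervals (the rows of the read-count table);
a CNVR-level scan is a configuration away but coarser, since merging
blends differentiated and undifferentiated loci.

## The synthetic cohort

`sim_config()` defaults define the study conditions the tests run under:
five populations subdivided into 11 breeds (32 samples), 2000 CNV loci on
four 30-Mb chromosomes, 96.6% deletions, log-normal deletion lengths with
median 1.3 kb and mean ≈ 2.3 kb, heavier-tailed log-normal duplication
lengths with median ≈ 1.4 kb and mean ≈ 31.5 kb, truncated at 2.8 Mb to
match the observed CNV length range in goat-sized genomes. Carrier
probabilities are uniform on [0.05, 0.5] per locus; 20 planted loci
instead carry a uniform one-copy shift in one population. Caller noise is
modelled as independent detection dropout (p = 0.95 per caller),
Gaussian breakpoint jitter (sd 20 bp), Poisson PE/SR evidence (means
4.5 + 3.5, so a call passes the medium filter with probability ≈ 0.9), a
10% IMPRECISE rate, and one-sided false calls placed uniformly at random.
Read counts are negative binomial (size 50) with mean proportional to
copy number × region size × library size, multiplied by a smooth GC bias
exp(coef·(gc − 0.45)) and by mappability. Loci are placed without
overlap, longest first, so rare megabase duplications land while the
genome is sparse; an infeasible configuration raises a generation error
rather than silently overlapping loci.

What the generator does **not** emulate — and what passing tests
therefore do not establish about real data: caller-specific systematic
biases (fragmentation, length-dependent sensitivity, type confusion),
linkage between nearby loci, population structure beyond mean
carrier-frequency differences, segmental-duplication-rich regions where
mappability and GC interact, and any read-level artefacts (the generator
emits call sets and counts, not reads). The tests establish that the
*analysis* is correct and well-calibrated under its stated model, not
that the upstream callers are.

## Problem sizes

The test suite and the acceptance script run the full cohort (32 samples,
2000 loci, ≈ 17k records per caller), a 40-sample two-population recovery
experiment (2000 loci, 20 planted), and several 500-locus replicates;
these sizes give ≥ 5000 consensus calls for the distributional checks and
an exact 1%-of-2000 outlier budget for the recovery check, while keeping
a full run in tens of seconds on one CPU.

## Known limitations

* The intersection is evidence-agnostic once records pass the filter: a
  consensus call does not carry combined PE/SR evidence.
* `both`-state regions arise only when loss and gain calls overlap or
  touch; the default generator places loci disjointly, so its region maps
  are effectively two-state and the `both` logic is exercised by
  constructed cases in the tests.
* Mappability correction by division is an interpretation; users with a
  principled mappability model should pre-adjust their counts and pass
  mappability = 1.
* The V_ST percentile rule flags a fixed fraction of loci by design; on a
  cohort with no true differentiation it still flags 1%, which is why the
  permutation behaviour (planted signal collapsing under label shuffling)
  is part of the test suite.
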