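# cnvpop

Consensus copy-number-variant (CNV) maps and copy-number population
differentiation from two-caller structural-variant (SV) call sets.

## The problem

Whole-genome sequencing cohorts of livestock — the motivating case is a
multi-breed goat cohort sampled across several geographic populations — are
routinely screened for structural variants with breakpoint callers such as
LUMPY and Manta. Each caller has its own false-positive profile, so a
common design is to keep only the *consensus*: deletions and duplications
(≥ 50 bp) that both callers report at overlapping positions in the same
sample. The per-sample CNV are then merged across individuals into CNV
regions (CNVR), summarized by copy state (loss / gain / both), classified
as shared or private across breeds and populations, and scanned for
between-population differentiation.

`cnvpop` implements that post-calling analysis as a tested R package:

* **sv_io** — SV-flavoured VCF parsing (SVTYPE/END/PE/SR/IMPRECISE,
  genotypes), BED3+ and sample-map I/O, with a single 0-based half-open
  coordinate convention internally.
* **consensus** — evidence filters (precision, PE + SR stringency, length
  cut-offs) and the per-sample two-caller intersection. The consensus call
  is the *overlap segment*, so one long record intersecting k short records
  yields k calls.
* **cnvr** — region merging within populations and globally, per-state
  summaries, sharing/private analysis, and an overlap report between two
  CNVR catalogues.
* **depthnorm** — RPKM = 10⁹·RC/(TRC·S), followed by binned-median GC
  correction (adjusted = RPKM·m/m_GC) and mappability division, producing
  the log-R-ratio proxies for the scan.
* **vst** — the copy-number differentiation statistic
  V_ST = (V_T − V_S)/V_T, where V_T is the pooled-sample variance of the
  normalized signal at a locus and V_S the (n−1)-weighted mean
  within-population variance; computed for every population pair and
  across all populations, with loci above each comparison's
  99th-percentile V_ST flagged and annotated with overlapping genes.
* **synthetic_data** — a deterministic cohort generator (two noisy
  callers, copy-number-driven negative-binomial read counts with GC and
  mappability covariates, planted differentiated loci) with ground truth
  and precision/recall scoring.

## Worked example

The `analysis/` directory is a numbered workflow over the package. Stage 1
simulates a cohort of 32 samples in 11 breeds and 5 populations with 2000
CNV loci; stages 2–5 run the analysis:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_consensus.R
Rscript analysis/03_cnvr.R
Rscript analysis/04_vst.R
Rscript analysis/05_report.R
```

Stage 2 prints the record counts through the filter chain and the
consensus landscape:

```
     raw_a      raw_b filtered_a filtered_b  consensus        cnv
     17476      17455      14118      14186      10416      10299
consensus CNV: 10299 (97.3% losses); length mean 4531 bp, median 1249 bp
```

Reading: of ~17.5k records per caller, the precision and PE + SR ≥ 5
filters keep ~14k, the two-caller intersection produces 10,416 overlap
segments, and the 50 bp / 3 Mb length cut-offs leave 10,299 consensus CNV.
As in real short-read data, losses dominate (here 97.3%) and the median
CNV is ~1.2 kb. Stage 3 merges these into 1,901 global CNVR (17.5% present
in all five populations, 224 private to a single breed), stage 4 runs the
V_ST scan (across-all 99th-percentile threshold 0.421, 20 loci flagged),
and stage 5 scores the run against the simulated truth (precision 0.998,
recall 0.585 at the stringent operating point; 90% of the planted
differentiated loci recovered).

The same machinery runs on real data: point `run_config()` at directories
of per-sample caller VCFs, a sample map, and (optionally) a read-count
table, gene BED and external CNVR catalogue, then call `run_pipeline()`.

## Documentation

The methods vignette (`vignettes/cnv-mapping.Rmd`) describes the model,
the normalization chain, the simulator's assumptions and what the tests
do and do not establish about real data.
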