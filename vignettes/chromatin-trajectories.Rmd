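---
title: "Methods: temporal chromatin-accessibility trajectory analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal chromatin-accessibility trajectory analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromtraj)
```

## The analysis model

chromtraj analyses chromatin accessibility across a somatic-reprogramming
time course profiled by ATAC-seq in two conditions — reprogramming toward
naive and toward primed pluripotency — over seven stages: the starting
fibroblasts (`hiF-T`), intermediates at days 6, 8, 14, 20 and 24, and the
final iPSCs. The same machinery serves CUT&Tag-style binding-site analysis
of two transcription-factor isoforms.

The procedure has five steps:

1. **Region atlas.** Peak calls from all samples are pooled and merged with
   a 100-bp gap tolerance (`bedtools merge -d 100` semantics: two intervals
   merge when their half-open separation is at most the gap). The merged,
   sorted, non-overlapping set is the coordinate universe for everything
   downstream.
2. **Pseudo-input null and threshold calibration.** Background intervals
   are placed uniformly on the genome, length-matched and count-matched to
   the atlas and rejected if they touch it. The signal distribution over
   these intervals is an empirical null for "closed" chromatin; the
   open/closed threshold is its `1 - FPR` quantile (linear interpolation),
   so at most an `FPR` fraction of background exceeds it. The default FPR
   is 0.01. The study this pipeline models used a fixed threshold of 4.2
   (log2 units) for its own data; because that constant is data-set
   specific, chromtraj calibrates by default and accepts a fixed value
   (`pipeline_config(threshold = 4.2)`) to reproduce fixed behaviour.
3. **Trajectory classification.** Per-region per-stage signals (mean
   25-bp-bin coverage, scaled to counts-per-million and log2-transformed
   with a pseudocount of 1) are binarized — strictly above the threshold is
   open, at or below is closed — and each region's ordered call vector is
   classified: `PO` (open everywhere), `NEVER` (closed everywhere), `CO`
   (one closed-to-open switch, no reversion), `OC` (the converse), and
   `TRANSIENT` (everything else). Per-stage CO/OC counts are cumulative by
   switch stage; cross-condition agreement is summarised by interval-overlap
   Venn counts per class and by the joint histogram of switch stages for
   regions sharing a class.
4. **Transient-region clustering.** Transient trajectories are
   z-standardized per region within each condition (shape, not level),
   concatenated across conditions, and soft-clustered with fuzzy c-means
   (Euclidean distance, fuzzifier `m = 2`, `c = 10` clusters by default, in
   the style of the Mfuzz package). Cluster mean trajectories are labelled
   per condition as up / loss / transient / flat and combined into shared
   or condition-specific categories.
5. **Gene-level analyses.** Regions link to the nearest TSS within 10 kb.
   The candidate funnel intersects (i) genes near CO regions (optionally
   plus one transient cluster), (ii) genes upregulated at every stage
   (fold > 5 vs baseline, Welch-t p < 1e-4 on log2(FPKM+1), stage FPKM > 5),
   and (iii) a curated epigenetic-factor list. Binding-site target genes
   (TSS within 10 kb of a site, mean FPKM >= 1) are classified by the
   Pearson correlation sign between their per-stage mean log2(FPKM+1) and
   the factor's own expression series.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| merge gap (`gap_bp`) | 100 | bp | the published merge distance for pooling peak sets |
| target FPR (`fpr`) | 0.01 | fraction | published false-positive rate for open calls |
| signal log base | 2 | — | methods-text convention; base 10 selectable (the source figure legends use log10 in one place — the discrepancy is resolved toward the methods text) |
| pseudocount | 1 | CPM | keeps the transform defined at zero and scale-invariant under joint library/value rescaling |
| TSS window (`max_dist`) | 10000 | bp | published peak-to-gene annotation window |
| promoter window | −2000/+500 | bp around TSS, strand-aware | common promoter definition (the source delegates to annotation software without printing windows) |
| TTS window | ±500 | bp | same reasoning |
| clusters `c`, fuzzifier `m` | 10, 2.0 | — | 10 clusters mirror the published grouping; m = 2 is the fuzzy c-means convention |
| upregulation criteria | fold > 5, p < 1e-4, FPKM > 5 | — | published thresholds, applied at every non-baseline stage |
| DE criteria | fold > 2, BH q < 0.05 | — | published thresholds, re-implemented as Welch t + BH rather than a transcript-assembly package |
| target filter (`min_fpkm`) | 1 | FPKM | published low-expression exclusion |

## The synthetic world

`study_config()` states the simulated conditions once; tests and the
acceptance script use these defaults unchanged:

- 2,000 regions, 400 per class, on two synthetic chromosomes with 2–4 kb
  spacing; widths 200–800 bp.
- Log2 signal: open ~ N(6.0, 0.7), closed ~ N(2.0, 0.7). These give clean
  but not trivial separation: a 0.01-FPR threshold calibrates to roughly
  closed mean + 2.3 sd, so closed calls carry an expected 1% flip rate and
  open calls a ~3 per 10,000 flip rate, which is what bounds the planted
  class recovery (NEVER regions, with seven closed draws, are the
  weakest at ~0.99^7).
- Two replicates per condition and stage, matching the profiled design.
- Expression: per-gene baseline log2 FPKM ~ N(3, 1.2); linked genes add
  `coupling` (default 1.0) times the standardized planted region
  trajectory; replicate noise sd 0.25 log2.
- Forced-upregulated genes (funnel plants and two decoy groups) are set to
  baseline FPKM 2 and 40 at every later stage with replicate sd 1e-4. The
  tiny sd is deliberate: with two replicates the Welch degrees of freedom
  can approach 1, whose near-Cauchy tail makes p < 1e-4 unattainable unless
  induction is essentially deterministic. "Forced" therefore means
  satisfying all three criteria by construction.
- Funnel decoys fail exactly one criterion each: upregulated and near CO
  but not factor-listed; factor-listed and near CO but flat; factor-listed
  and upregulated but placed > 10 kb from every region.
- Binding: 400 alpha targets (80% positively correlated) and 100 beta
  targets (20%), one site within 10 kb of each target TSS, 10 shared sites
  in a gene-free zone, 20/5 low-FPKM plants, and 50 below-threshold decoy
  candidates per isoform. Planted correlations are linear responses with
  small noise, giving |r| near 1.

What the generator does **not** emulate: read-level noise, fragment-length
structure, GC or copy-number bias, peak-caller artefacts, replicate-level
signal variation within a stage, and correlated noise between neighbouring
regions. A green test therefore establishes the correctness of the
statistical machinery on its stated model, not robustness to upstream
artefacts.

## Numerical choices and edge cases

- Coordinates are 0-based half-open (BED) throughout; abutting intervals do
  not overlap, and a TSS exactly at an interval end is 1 bp away.
- A signal exactly at the threshold is closed ("above" is strict); a
  binding candidate exactly at the threshold is not a site.
- Quantile calibration uses type-7 (linear interpolation); with fewer than
  100 pseudo-input values calibration refuses to run.
- Mann-Whitney class statistics use the exact null for pooled n <= 20 and
  the tie-corrected normal approximation (no continuity correction) above.
- Welch tests on zero-variance pairs return p = 1 when means agree and
  p = 0 otherwise.
- Nearest-TSS ties break toward the lexicographically smaller gene id;
  fuzzy hard assignments break membership ties toward the lower cluster
  index; a region landing exactly on a centroid takes full membership.
- Fuzzy c-means starts from seeded random memberships and stops when the
  largest membership change falls below `tol` (1e-6) or after `max_iter`
  (500) iterations.
- Genes without exon structure contribute their body as intron in feature
  annotation; the feature of a region is decided by its midpoint with
  precedence promoter > 5'UTR > 3'UTR > exon > intron > TTS > intergenic.

## Open design decisions taken

- **Pseudo-input construction** samples coordinates (length-matched,
  count-matched, atlas-excluded) rather than permuting signal values; it is
  the least-assuming null given only peak coordinates and tracks.
- **Upregulated genes are computed per condition**; the published analysis
  does not state whether its count pooled conditions.
- **Which transient cluster joins the funnel** is a configuration key
  (`cluster$funnel_cluster`), defaulting to none: cluster indices are not
  stable identities across data sets, so hard-coding one would be
  meaningless outside the original data.
- **Correlation-sign analysis** uses all stages of one condition and
  Pearson on per-stage mean log2(FPKM+1); both are configurable because the
  published description fixes neither.
- **Cluster-category thresholds** (final-stage z >= 0.5 with Spearman rho
  >= 0.6 for "up", 0.5-z interior excess for "transient", z-span < 0.5 for
  "flat") operationalize a grouping that was originally made by inspecting
  figures; they are stated constants, not fitted values.
- A mention of a "day 2" stage in the source narrative is treated as a typo
  (day 2 is never sampled); the stage list is fully configurable and
  nothing assumes it.

## Known limitations

- Headline counts from the original study (e.g. 26,246 CO regions, 41
  candidates, 3,343/471 binding sites) depend on its deposited sequencing
  data and on alignment/peak-calling stages that are out of scope here;
  chromtraj reproduces the procedures, not those numbers.
- The fuzzy c-means objective is non-convex; different seeds can yield
  different local optima. Results are deterministic given the seed, and the
  planted-shape recovery test bounds the practical impact at the default
  settings.
- With two replicates the upregulation p-value criterion has essentially no
  power at biological noise levels; it acts as a consistency filter, and
  the fold and level criteria dominate. This mirrors the published design
  rather than improving on it.
- The per-stage signal model ignores replicate structure within ATAC
  stages (signals are stage-level); replicate-aware calling would need a
  different null.

## Worked example

```{r example, eval = FALSE}
library(chromtraj)
res <- run_pipeline(pipeline_config(seed = 1))
print(res$report)
```

The report prints the atlas size, calibrated threshold and its realised
pseudo-input exceedance, per-condition class counts, the funnel sizes, and
the binding Venn/target/correlation summaries; `run_pipeline(out_dir=)`
writes the same content as JSON and TSV.
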