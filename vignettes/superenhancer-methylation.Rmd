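---
title: "Discovering differentially methylated super-enhancers and their target genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering differentially methylated super-enhancers and their target genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semeth)
```

## The problem

Super-enhancers (SEs) are large (up to ~300 kb) clusters of enhancer elements
that drive the expression of cell-identity genes, with transcription start
sites (TSS) of their targets reachable in cis up to about 1 Mbp away through
chromatin loops. DNA methylation of an SE is expected to repress its targets:
maximal expression requires both an unmethylated promoter and an unmethylated
SE. Many tumour types lack the chromatin profiling needed to call SEs
directly, but often have genome-wide methylation (e.g. MBD-Seq) and RNA-Seq
for the same samples. `semeth` implements a screen built on that idea: start
from a candidate SE catalog (possibly borrowed from etiologically related
tissues), keep the SEs whose methylation differs between tumours and
controls, and keep the nearby genes whose expression is negatively
rank-correlated with that methylation. An independent cohort measured on a
450k-style methylation array can then be used to validate the surviving
SE-gene pairs.

## The procedure

All coordinates in the package are 0-based half-open (BED convention), and
all interval algebra reduces interval sets before measuring them, so
overlapping or touching peaks never double-count base pairs.

1. **SE methylation quantification.** For each sample, methylation arrives
   as MACS-style peak intervals. The methylation of an SE (or of a promoter,
   defined as TSS −1500/+500 bp, strand-relative) in a sample is the *net
   length in bp of the intersection* between the region and the sample's
   peaks — `region_methylation_matrix()`.
2. **Differential methylation.** Per SE, a two-sided Wilcoxon rank-sum test
   compares case and control net lengths; Benjamini–Hochberg FDR is applied
   across all SEs, and regions with $q < 0.05$ are classified
   hypermethylated or hypomethylated by comparing group means
   (`se_differential()`). A genome-wide variant tests 100 bp tiles with an
   exact Fisher test on the binary status "any peak overlap at all"
   (`scan_tiles()`); tiles methylated in no sample or in every sample carry
   no information for the 2×2 table and are excluded before the FDR
   correction so they do not dilute it.
3. **Target assignment.** Every gene whose TSS lies within 1 Mbp of a DM-SE
   is a candidate target (`find_targets()`). The eligibility distance is
   TSS-to-nearest-SE-edge (0 inside the SE); because descriptive distance
   conventions vary, the TSS-to-SE-midpoint distance is reported alongside
   in its own column.
4. **Correlation screen.** Per candidate pair, Kendall's $\tau_b$ between SE
   methylation and expression across shared samples; BH FDR across all
   candidate pairs jointly; a pair passes when $q < 0.05$ *and*
   $\tau_b < 0$. Positively correlated pairs are filtered out as artifacts
   regardless of significance, because the model under test is repression
   (`correlate_pairs()`). Promoter methylation is correlated with expression
   by the same machinery and reported alongside, with its own FDR, but plays
   no role in pass/fail (`correlate_promoters()`).
5. **Array validation.** In the validation cohort, probe betas
   ($\beta = M/(M+U)$) stand in for region methylation. For each passed
   pair, among the probes located inside the SE the one with the minimum
   (most negative) $\tau_b$ against the gene's expression is selected; the
   pair validates when that probe's unadjusted $p < 0.05$ and its
   $\tau_b < 0$ (`validate_pairs()`). Pairs whose SE contains no probe are
   "not assessable" rather than failed. Validation only annotates; it never
   changes discovery calls.

`run_pipeline()` chains the stages, logs the filtering funnel
(catalog → DM-SEs → candidate pairs → passed → validated), and writes
deterministic TSV outputs. A thin command-line wrapper
(`inst/scripts/semeth.R`) exposes each stage as a subcommand.

## Statistical conventions

* **Fisher (tiles).** Two-sided by the "probability at most observed" rule —
  the sum of probabilities of all tables with the observed margins whose
  hypergeometric probability does not exceed that of the observed table. A
  zero margin yields $p = 1$ (no information), not an error.
* **Wilcoxon (SEs).** Exact by enumeration when both groups are tie-free and
  $n_1 + n_2 \le 12$; otherwise the normal approximation with tie correction
  and continuity correction. Intersection-length data contain many ties
  (zeros), so the approximate branch is the common path. Against a fully
  enumerated permutation null the approximation is accurate to roughly
  0.02–0.04 at the cohort sizes involved; the test suite asserts exactly
  that, and the exact branch is checked against full labeling enumeration.
* **Kendall.** $\tau_b$ (tie-corrected), two-sided p from the tie-adjusted
  normal approximation with continuity correction. The tie correction
  matters for the same reason; pairs with a missing value in either vector
  are excluded pairwise, and fewer than 3 complete pairs or zero variance
  gives a missing statistic with $p = 1$. Because the p-values are
  approximate, borderline calls with $q \approx 0.05$ can differ from an
  exact-test analysis.
* **FDR.** BH step-up; missing p-values propagate missing q-values and do
  not count toward the number of tests. The correction is applied within
  each scan separately (tiles, SEs, SE-gene pairs, promoter pairs), because
  each answers a different question. For pairs, the default scope is one
  joint correction across all candidate pairs; a per-SE scope is available
  via `fdr_scope = "per_se"` for sensitivity analyses.
* **Overlap statistic.** `projection_overlap_stats()` asks whether query
  intervals (e.g. DM tiles) concentrate inside a reference set (e.g. the SE
  catalog): observed = number of query midpoints falling in the reference;
  expected = $n \cdot (\text{reference bp} / \text{genome bp})$; p from the
  upper binomial tail. The midpoint-projection binomial form was chosen
  because it is simple, exact under uniform placement, and calibrated
  (ratio → 1 for uniform queries); richer relative-distance statistics are
  out of scope.

## Key tunable parameters

| parameter | default | meaning |
|---|---|---|
| `window` | 1,000,000 bp | max TSS-to-SE-edge distance for candidate targets |
| `promoter_up` / `promoter_down` | 1500 / 500 bp | promoter window around the TSS, strand-relative |
| `tile_width` | 100 bp | genome tiling for the tile scan |
| `dm_alpha`, `pair_alpha` | 0.05 | FDR thresholds for DM calling and pair screening |
| `validation_p` | 0.05 | unadjusted p cutoff for probe validation |
| `fdr_scope` | `"joint"` | BH scope for pair correlations |

## The synthetic cohort generator

No suitable public cohort ships raw per-sample peak calls with matched
expression, so `simulate_cohort()` generates complete, ground-truthed inputs
and `truth_eval()` scores pipeline output against the planted truth. The
generator emulates the statistical structure the pipeline assumes:

* **Genome and catalog.** Four chromosomes of 120 Mbp with 200 SEs of
  5–20 kb placed on a regular grid (~2.4 Mbp spacing). Each SE's planted
  genes lie within ±0.8 Mbp of their SE, so the 1 Mbp cis windows of
  distinct SEs are disjoint. This isolation is deliberate: planted hyper-SEs
  share the tumour/normal group structure, so their methylation profiles are
  strongly correlated across samples, and if two DM-SEs shared a cis window
  each one's targets would genuinely correlate with the other SE too — a
  confound no correlation-based screen can resolve, which would make
  pair-level truth unidentifiable. With isolated neighbourhoods, pair-level
  sensitivity and false discovery are well-defined. The SE density
  (~0.4/Mbp) is of the same order as genome-wide SE catalogs.
* **Methylation.** Per SE and sample, a methylated fraction is drawn from a
  Beta distribution centred on the group mean — baseline $f_0 = 0.3$, and
  $f_0 \pm \delta$ with $\delta = 0.3$ for planted hyper/hypo SEs in cases
  (15% and 5% of SEs respectively) — with concentration 30 (per-sample sd
  ~0.08). Peaks are placed inside the SE as non-overlapping sub-intervals
  covering exactly the drawn fraction, so the realized coverage recomputed
  from the BED files matches the drawn target to within 1 bp / length.
  Background peaks outside SEs follow a seeded Poisson process (5 per Mbp),
  and a 10% subset of genes receives methylated promoters.
* **Expression.** Planted target genes follow
  $\max(0,\; a - b \cdot f + \varepsilon)$ with $a = 10$, $b = 8$,
  $\varepsilon \sim N(0, 1.3^2)$, calibrated so the expected Kendall
  correlation of a planted link is $\tau \approx -0.5$
  ($\rho = \sin(\pi\tau/2) \approx 0.71$, noise sd matched to
  $b \cdot \mathrm{sd}(f)$). Each SE also gets one positively linked
  "artifact" gene (slope $+b$) to exercise the sign filter and two decoy
  genes with independent noise.
* **Validation cohort.** 22 case / 6 control samples drawn from the same
  truth; 4 probes per SE at uniform positions; probe beta = the sample's SE
  fraction plus $N(0, 0.05)$ clipped to $[0,1]$.

What the generator does *not* emulate: CpG density and read-level coverage,
correlated methylation between neighbouring SEs beyond the group effect,
batch effects, clinical covariates, or heavy-tailed expression. Passing the
recovery tests therefore demonstrates that the statistical machinery is
correct and calibrated under the model's own assumptions — not that real
cohorts of this size will reach the same sensitivity.

## Problem sizes and numerical choices

The test suite runs the full discovery + validation pipeline on ten seeded
replicates of the reference conditions above (47/25 discovery samples,
200 SEs) and checks: DM-SE sensitivity ≥ 0.90 with empirical FDR ≤ 0.10 and
≥ 95% correct directions; recovery of ≥ 80% of planted links on called
DM-SEs with pair-level FDR ≤ 0.15; removal of 100% of positive artifact
links; and ≥ 80% validation of passed planted pairs. Oracle tests compare
the interval routines against per-base brute force on 1,000 random
instances, Fisher against full enumeration of every informative 2×2 table
with total ≤ 30, the exact Wilcoxon branch against full labeling
enumeration, $\tau_b$ against a pairwise-counting oracle, and BH against the
step-up definition; 2,000-replicate null simulations check type-I error.
Genome-wide tile scans in tests use small synthetic genomes (1–2 chromosomes
of a few Mbp), which is where the `run_tile_scan` stage is intended to be
exercised; tiling a mammalian genome at 100 bp produces ~30M tiles and is a
batch-scale computation.

Degenerate inputs are handled explicitly rather than erroring where the
pipeline must keep moving: cross-chromosome distances are `Inf` (the pair is
simply skipped), an SE constant across all samples gets $p = 1$ and
direction `none`, a significant SE with exactly tied means falls back to the
median difference and stays `none` if both tie (logged), the Jaccard index
of two empty sets is 0, and a pair whose SE contains no array probe is "not
assessable" (`NA`) rather than failed.

## Limitations

The screen is correlational: passing pairs are consistent with SE-mediated
repression but not proven causal, and strong tumour/normal differences in
any co-varying factor can produce significant correlations. Borrowed SE
catalogs inherit the tissue specificity of their sources. Validation
strength is limited by probe placement — an SE with no or few probes cannot
be assessed, mirroring the sparsity of array coverage inside large SEs.
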