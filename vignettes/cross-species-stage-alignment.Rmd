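---
title: "Aligning developmental stages across species with partial dynamic time warping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning developmental stages across species with partial dynamic time warping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardalign)
```

## The problem

Mouse embryos develop on a very different clock from human embryos, and the
offset is not a single constant: different cardiac lineages (atrial
cardiomyocytes, ventricular cardiomyocytes, endothelial cells) can sit at
different relative positions on the two time axes. Given single-cell
RNA-seq time courses from two species, `cardalign` estimates, per cell
type, which interval of the reference species' developmental time each
query-species stage corresponds to.

The procedure is:

1. **Pseudo-bulk construction.** Cells are grouped by (species, cell type,
   stage); within each group, log2(TPM + 1) expression is averaged and the
   mean is integerized as `round((mean + 1) * 10000)`. Pseudo-bulk
   profiles suppress cell-to-cell variability and put both species on a
   common per-stage footing. Species are joined on a strict 1:1 ortholog
   map.
2. **Dynamic-gene detection.** For each gene and species, expression is
   regressed on powers of tau = log2(gestational days) with a cubic
   polynomial. A gene is developmentally dynamic (a DDG) when its fit
   reaches R² ≥ 0.3 (in at least one species by default), after a
   per-species significance pre-filter (F-test p-values,
   Benjamini–Hochberg at 0.05).
3. **Trajectory fitting.** DDG profiles are standardized per gene (mean 0,
   SD 1) and refit as cubics, evaluated on a uniform 100-point grid over
   each species' observed tau span.
4. **Partial dynamic time warping.** The query species' curve family is
   matched onto a contiguous sub-window of the reference species' curves
   by a monotone dynamic program (steps (1,0), (0,1), (1,1)), open at both
   ends on the reference side, consuming the query completely, and
   minimizing the summed Euclidean distance across genes. Age order is
   preserved by construction.
5. **Stage correspondence.** Each query stage maps through the warping
   path to an interval of reference grid points, reported in log2 days,
   days and weeks. Grid resolution is the precision of these intervals.

The package also provides a hypergeometric overlap test for comparing gene
sets (e.g. cell-type DDGs against bulk-tissue DDGs), a linear-model
differential-expression screen with the conventional |log2FC| ≥ 0.5 and
adjusted p ≤ 0.01 thresholds, and a two-species synthetic-data generator
with a known time warp that exercises every stage of the pipeline.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_features_*` | 0 | QC: keep cells with more than this many detected genes. For the real embryonic heart datasets, 1000 (human) and 600 (mouse) are the conventional values; synthetic data needs no cell QC. |
| `r2_min` | 0.3 | minimum cubic-fit R² for a gene to count as dynamic |
| `scope` | either | species combination rule for DDGs (`either`/`both`) |
| `alpha` | 0.05 | BH-adjusted F-test cutoff of the significance pre-filter |
| `degree` | 3 | polynomial degree for detection and curve fitting |
| `grid_size` | 100 | grid points per species for DTW (per-species, uniform in tau) |
| `dtw_mode` | partial | open-begin/open-end on the reference; `full` anchors both ends |
| `distance` | euclidean | local cost across genes; `correlation` available |
| `mean_space` | log | pseudo-bulk averaging on log2 values; `linear` de-logs first |

Times are always gestational days; human weeks enter as `weeks * 7`
(`weeks_to_days()`), mouse embryonic days as-is, and tau = log2(days) is
the fitting and warping axis throughout.

## Why the significance pre-filter is on by default

An R² threshold alone cannot control false selections: R² is scale-free,
so a truly flat gene with *any* independent stage-level noise has
R² ~ Beta(3/2, (n − 4)/2) under the null — with eight stages, about two
thirds of flat genes exceed 0.3 regardless of how small the noise is. The
two-step screen used for polynomial time-course regression therefore
selects significant fits first and applies the goodness-of-fit rule
second; `detect_ddgs()` mirrors this with a per-species BH-adjusted F-test
at `alpha = 0.05` ahead of the R² rule. Setting
`significance_filter = FALSE` recovers the bare R² rule.

## Compositional centering

TPM is a within-cell relative measure: when dynamic genes rise, every
other gene's TPM falls, so pseudo-bulk profiles carry a shared per-stage
offset that can carry flat genes over the significance threshold.
`detect_ddgs()` removes it in two passes: first a per-sample median over
all genes, then — once a provisional DDG set exists — the per-sample mean
over the non-selected (control) genes. The median alone is not enough
because the cross-sectional skewness of the gene population varies with
stage, leaving a stage-varying gap between mean and median; the
control-gene mean removes the shared component exactly. The same centering
feeds the trajectory fits. This assumes a majority of genes are not
dynamic; if most of the transcriptome moves, the centering (like any
global normalization) is biased and `sample_center = FALSE` with external
normalization is the better choice.

## Joint cross-species standardization

Standardizing each species separately (per gene, over its own stages)
looks natural but breaks subsequence alignment: the query species is
observed over a *window* of the reference span, so per-species scaling
gives each gene a different affine distortion in each species, and the
minimum-cost window no longer sits at the true correspondence — on
noiseless synthetic data the recovered stages drift by tens of grid steps.
`run_pipeline()` therefore standardizes each gene once, over the union of
both species' samples, so both curve families live on a common scale; with
that choice the true warp is the exact zero-cost alignment in the
noiseless case. The cost is that genuine cross-species scale differences
for a gene are retained rather than normalized away; with hundreds of
DDGs these act as zero-mean perturbations of the cost surface rather than
a systematic bias.

## Numerical choices

- **Rounding** in the pseudo-bulk transform is half-away-from-zero
  (`round_half_up()`), fixing cross-platform tie behavior.
- **DTW tie-breaks** prefer the diagonal step, then query-only (0,1), then
  reference-only (1,0); a tied open end takes the smallest reference
  index. Ties are measure-zero for continuous costs but the rule makes
  paths deterministic.
- **Path cost is a sum**, not a per-step average: only within-comparison
  minimization matters, and for windows no longer than the query grid the
  step count is constant anyway.
- **Degenerate inputs**: constant genes get R² = 0, p = 1 by convention in
  fits, are excluded (with a warning) from standardization, and are
  flagged with reason "zero variance" by the sample-outlier check.
  Zero-residual genes in the DE screen get p = 1 when the fold change is
  also zero and the machine floor otherwise.
- **VST** for PCA input is median-of-ratios size factors followed by
  log2(count/sf + 1) — a fully specified variance-stabilizing transform;
  it intentionally does not replicate dispersion-based VST
  implementations bit-exactly.
- **Outlier flagging** combines the k-MAD rule (k = 3 on mean
  inter-sample correlation) with a 0.01 absolute floor so numerically
  identical cohorts are never flagged; flags are advisory.
- `fit_curve_grid()` refuses to extrapolate beyond the observed tau span
  unless asked; stage times outside the query grid are a range error.

## What the generator emulates — and what it does not

`sim_config()` defines two species sampled at discrete stages
(human-like: days 35–119, i.e. weeks 5–17; mouse-like: E9.5–E13.5). A
configurable fraction of genes (default 30% of 1000) follows cubic log2
expression programs of amplitude 0.8–1.6 on the reference tau axis; the
query species expresses the same programs through the monotone affine
warp tau_ref = a + b·tau_query (default a = 0.8, b = 1.4, whose image
sits inside the reference span). Each cell draws per-gene Gaussian
expression noise (SD 0.2 in log2 units) around its stage program and
Poisson (or negative-binomial) counts at a 20,000-count library, then
counts become TPM with unit effective lengths. The default 200 cells per
stage matches the order of cells per stage and lineage that embryonic
heart atlases provide after subsetting.

Passing tests on this generator shows the machinery is correct under its
assumptions — shared programs up to a smooth monotone warp, independent
cells, no batch structure. Real data add gene–gene correlation, batch and
dissection effects, unequal cell quality, imperfect orthology and genuine
cross-species program divergence; none of these are emulated, so
benchmark accuracy here is an upper bound, not a promise about any
particular dataset.

## Problem sizes

The shipped tests and the acceptance script run the default benchmark
(1000 genes × about 2600 cells across both species), 200 random
DTW-oracle instances on grids up to 6×6, and a full enumeration sweep of
hypergeometric configurations up to a 12-gene universe; the whole suite
completes in well under a minute on one CPU.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)
sim <- simulate_species_pair(cfg)
res <- run_pipeline(
  ref = log_transform(sim$ref$matrix), ref_cells = sim$ref$cells,
  query = log_transform(sim$query$matrix), query_cells = sim$query$cells,
  orthologs = sim$orthologs, cell_type = "CMs-A")
res$correspondence
truth_eval(res$correspondence, sim$truth)
autoplot(res$correspondence)
```

## Known limitations

- One query species against one reference; no joint alignment of three or
  more species.
- No confidence intervals on the warp; correspondence precision is grid
  resolution.
- The DE screen is a normal-theory linear model on log-normalized
  pseudo-bulk, suited to threshold mechanics and overlap statistics, not a
  replacement for count-based inference when per-cell counts are the
  object of study.
- DDG detection needs at least degree + 2 distinct stages per species
  (five, for cubics); with exactly five, the mouse-side F-test has a
  single residual degree of freedom and contributes little to selection.
- Placing in vitro (e.g. stem-cell-derived) samples on the embryonic axis
  requires user-supplied pseudo-times; the package does not infer them.
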