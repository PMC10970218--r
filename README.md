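# cardalign

Cross-species alignment of developmental stages from single-cell
transcriptome time courses.

Mouse and human embryos run the same developmental programs on different
clocks, and the offset differs between cardiac lineages: the question
"which human gestational week corresponds to mouse E11.5 for atrial
cardiomyocytes?" has a different answer than for ventricular
cardiomyocytes or endothelial cells. `cardalign` answers it from
single-cell RNA-seq time courses of the two species, per cell type, and is
aimed at developmental and comparative transcriptomics work where mouse
findings must be placed on the human time axis.

## Method

For each species, cells are aggregated into pseudo-bulk samples per
(species, cell type, stage): the group mean of log2(TPM + 1) is
integerized as `round((mean + 1) * 10000)`, and species are joined on 1:1
orthologs. With τ = log2(gestational days), each gene is fit by ordinary
least squares to

  y(τ) = β₀ + β₁ τ + β₂ τ² + β₃ τ³,

and genes are called developmentally dynamic (DDGs) when R² ≥ 0.3, after
a per-species Benjamini–Hochberg F-test pre-filter (α = 0.05). DDG
profiles are standardized per gene (mean 0, SD 1, jointly across both
species' samples), refit as cubics, and evaluated on a uniform 100-point
τ grid per species. The query species' curve family Q(·) is then aligned
onto the reference family R(·) by **partial (subsequence) dynamic time
warping**: a monotone dynamic program over local costs

  d(i, j) = ‖R(τᵢ) − Q(tⱼ)‖₂  (across genes)

with steps (1,0), (0,1), (1,1), open begin/end on the reference and the
query fully consumed, minimizing the summed cost. The optimal path maps
each query stage to an interval of reference time, reported in log2 days,
days and weeks. Supporting statistics include hypergeometric gene-set
overlap tests, a linear-model differential-expression screen
(|log2FC| ≥ 0.5, adjusted p ≤ 0.01), and a synthetic two-species
generator with a known affine warp τ_ref = a + b·τ_query for validation.

## Worked example

Simulate a two-species benchmark (8 human-like stages at days 35–119,
5 mouse-like stages E9.5–E13.5, 1000 genes of which 300 dynamic, warp
τ_ref = 0.8 + 1.4 τ_query) and run the full pipeline:

```r
library(cardalign)

cfg <- sim_config(seed = 1)
sim <- simulate_species_pair(cfg)
res <- run_pipeline(
  ref = log_transform(sim$ref$matrix),   ref_cells   = sim$ref$cells,
  query = log_transform(sim$query$matrix), query_cells = sim$query$cells,
  orthologs = sim$orthologs, cell_type = "CMs-A")

res$ddgs
#> <ddg_set> CMs-A: 315 of 1000 genes dynamic (R^2 >= 0.30, scope either)

dplyr::select(tibble::as_tibble(res$correspondence),
              query_days, ref_days_lo, ref_days_hi, ref_weeks_lo, ref_weeks_hi)
#> # A tibble: 5 × 5
#>   query_days ref_days_lo ref_days_hi ref_weeks_lo ref_weeks_hi
#>        <dbl>       <dbl>       <dbl>        <dbl>        <dbl>
#> 1        9.5        41.1        41.1         5.87         5.87
#> 2       10.5        47.1        47.1         6.73         6.73
#> 3       11.5        53.3        53.3         7.61         7.61
#> 4       12.5        59.6        59.6         8.51         8.51
#> 5       13.5        65.7        65.7         9.39         9.39
```

Each row maps one query stage (in days) to its matched reference interval:
the simulated E9.5 stage lands at reference day ~41 (week 5.9), E13.5 at
day ~66 (week 9.4). Because the generator knows the true warp, recovery
can be scored exactly:

```r
truth_eval(res$correspondence, sim$truth)
#> # A tibble: 5 × 5
#>   query_days true_ref_tau est_ref_tau abs_error_tau grid_steps_off
#>        <dbl>        <dbl>       <dbl>         <dbl>          <dbl>
#> 1        9.5         5.35        5.36       0.0140               1
#> 2       10.5         5.55        5.56       0.00805              0
#> 3       11.5         5.73        5.74       0.00264              0
#> 4       12.5         5.90        5.90       0.00527              0
#> 5       13.5         6.06        6.04       0.0180               1
```

Every stage is recovered within one grid step (grid spacing ≈ 0.018 in
log2 days). `autoplot()` methods exist for correspondences, alignment
paths, fitted trajectories, PCA results and DE tables; `tidy()`/`glance()`
turn every result type into tibbles.

For real data, `read_expression_matrix()` (MTX or dense TSV/CSV),
`read_cell_table()` and `read_ortholog_map()` ingest the standard formats,
`qc_filter()` applies the detected-gene threshold (conventionally 1000 for
human cells, 600 for mouse), and a thin command-line wrapper lives at
`inst/scripts/cardalign.R`. The methods vignette
(`vignettes/cross-species-stage-alignment.Rmd`) documents the model,
parameter choices and limitations.

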