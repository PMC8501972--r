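# rf3h

Quantification pipeline for **RNA fluorescence three-hybrid (rF3H)** imaging
assays, with a synthetic microscopy generator that makes every stage testable
without real data.

## The assay and the statistic

In an rF3H experiment, an EGFP-tagged *RNA trap* (e.g. MCP–EGFP–LacI)
anchors a tagged test RNA at a defined nuclear structure — a lacO repeat
array (one bright spot), chromocenters or Cajal bodies (many puncta), or the
nuclear lamina (a rim). If an mCherry-tagged candidate protein binds that
RNA, red fluorescence accumulates at the structure. Binding is quantified
per cell as the **relative fluorescence** at the anchor:

```
            Red_anchor − Red_nucleus
  ratio  =  ────────────────────────────
            Green_anchor − Green_nucleus
```

where each term is the mean gray value over the anchor region or the whole
nucleus in the red (protein) or green (trap) channel. Differencing against
the nucleus-wide means makes the ratio invariant to additive offsets and
normalizes cell-to-cell expression variation; dividing by the green excess
removes dependence on how much trap accumulated. Each experiment's per-cell
ratios are then divided by the arithmetic mean ratio of a no-RNA control
group, so the control reads exactly 1 and specific binding reads as fold
enrichment. Groups are compared with a two-sided pooled-variance Student's
t-test and annotated `*` p < 0.05, `**` p < 0.01, `***` p < 0.001.

The pipeline stages are: nucleus segmentation from the nuclear-stain
channel (Gaussian smoothing → Otsu → hole filling → labelling → area and
border filters), anchor detection in the green channel
(Laplacian-of-Gaussian blob detection for spots and puncta, morphological
band for the rim), per-cell measurement, QC (undetectable anchor, weak
trap, aberrant nucleus area), control normalization, and group statistics.

## Worked example

Simulate the lacO single-spot experiment design (pp7 RNA vs PCP protein;
23 control and 24 specific cells, 2-fold binding gain) and run the full
pipeline on the synthetic images:

```r
library(rf3h)

cfg <- figure_preset("F1_pp7_PCP")
sim <- simulate_experiment(cfg, seed = 7)
res <- analyze_simulation(sim)
res
#> <rf3h_results> 47 cells (47 kept, 0 rejected), control '-RNA'
#> # A tibble: 2 × 5
#>   condition is_control     n  mean    sd
#>   <chr>     <lgl>      <int> <dbl> <dbl>
#> 1 +ms2-pp7  FALSE         24  2.14 0.734
#> 2 -RNA      TRUE          23  1    0.376
res$stats
#> # A tibble: 1 × 10
#>   group_a  group_b mean_a mean_b   n_a   n_b t_statistic    df     p_value stars
#>   <chr>    <chr>    <dbl>  <dbl> <int> <int>       <dbl> <dbl>       <dbl> <chr>
#> 1 +ms2-pp7 -RNA      2.14      1    24    23        6.67    45     3.13e-8 ***
```

The control group's normalized mean is exactly 1 by construction; the
specific condition recovers the configured 2-fold enrichment up to
Monte-Carlo error (2.14 ± 0.73 SD across 24 cells here), and the
comparison is highly significant. `plot_enrichment(res)` (or
`autoplot(res)`) draws the standard scatter with mean ± SD bars and stars.

The same analysis runs file-based: `rf3h_simulate_dataset()` writes
multi-page TIFFs, a YAML manifest and a ground-truth CSV;
`rf3h_analyze()` consumes the manifest and writes `cells.csv`,
`groups.csv`, `stats.csv` and a run log. A thin command-line wrapper lives
at `inst/cli/rf3h.R`:

```sh
Rscript inst/cli/rf3h.R simulate --preset F1_pp7_PCP --seed 7 --out data/
Rscript inst/cli/rf3h.R analyze --config data/manifest.yaml --out results/ --plots
```

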