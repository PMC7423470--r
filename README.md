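# fpdist

Does an alien plant that is phylogenetically and functionally *distinct*
from its resident community escape competition? `fpdist` implements the
complete inference chain for answering that question with a competitor
removal experiment, for ecologists working at the interface of community
phylogenetics and plant demography:

- **Demographic models** per species × treatment: stage-structured matrix
  population models (MPMs) and midpoint-rule integral projection models
  (IPMs), with the population growth rate λ as the dominant eigenvalue and
  individual-level bootstrap uncertainty.
- **Effect sizes**: the demographic benefit of competitor removal as the
  offset log response ratio
  `effect = ln((λ_CR + 0.5) / (λ_C + 0.5))`,
  where λ_CR and λ_C are the growth rates with competitors removed and in
  control plots.
- **Distinctiveness** of each focal species at two spatial grains (plot
  community vs regional pool) on square-root cophenetic distances: MPD,
  NND, abundance-weighted variants, with richness rarefaction (k = 11) at
  the small grain. Trees are assembled with congeneric placement of
  missing species and pruning.
- **Trait distances and signal**: mixed-type Gower distances (continuous,
  circular flowering month, binary, categorical traits), a correlation
  screen, Blomberg's K, the Fritz–Purvis D statistic and Mantel tests.
- **Functional–phylogenetic weighting**: `FPD = sqrt(a·PD² + (1−a)·FD²)`
  swept over a ∈ {0, 0.025, …, 1}, refitting the regression of effect size
  on distinctiveness + z-scored competitor biomass at each grid point and
  tracking the adjusted R².
- **A synthetic-data generator** with known ground truth (planted
  distinctiveness–competition coupling), so every stage of the chain is
  testable without field data.

## Worked example

Simulate a 14-species removal experiment with a strong planted coupling
(the least distinct species benefits most from competitor removal), run
the full pipeline, and look at the headline regression:

```r
library(fpdist)

cfg <- pipeline_config(
  scenario = list(treatment_effect_slope = 0.4, seed = 2),
  n_boot = 200, sweep_metric = "MPD", seed = 2)
res <- run_pipeline(cfg)

subset(res$regressions, metric == "MPD")
#>  grain metric       parameter   observed       lower       upper
#>  small    MPD distinctiveness -0.1270071 -0.15873798 -0.09839779
#>  small    MPD          adj_r2  0.6030871  0.34181901  0.73641290
#>  large    MPD distinctiveness  0.1765524 -0.04246369  0.40822365
#>  large    MPD          adj_r2 -0.1543371 -0.18020278 -0.03377839

attr(res$sweep, "best_a"); attr(res$sweep, "best_adj_r2")
#> [1] 1
#> [1] 0.3962703
```

The small-grain MPD coefficient is negative with a 95% bootstrap CI
excluding zero: in this run, species with close relatives in their plots
gained the most from removing competitors, and rarefied plot-level
distinctiveness plus biomass explains ~60% of the variance in the removal
effect. The large-grain coefficient's CI covers zero: co-occurrence at
the regional grain carries no signal, by construction (single runs can
still show spurious grain-level signal with 14 species; the test suite
checks the rates across 50 replicate experiments). The sweep puts its
arg-max at `a = 1` — phylogeny-only weighting — as expected for a
generator that plants a purely phylogenetic coupling; the traits-only
model (`a = 0`) explains nothing here (adjusted R² −0.18).

`res$ground_truth` holds the generating λs and the planted effects;
`make_report(res, dir)` writes coefficient histograms and the adjusted-R²
versus `a` curve.

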