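# estuaryRF

Barrier-aware random-forest mapping of sediment contamination hotspots in
estuaries.

## The problem

Concentrations of sediment-bound contaminants (the reference case is
triclosan, TCS, in ng/g dry sediment) are measured at a few dozen points,
mostly clustered in sub-estuaries and near suspected sources. Managers need
a full-estuary picture of where contamination is likely high. `estuaryRF`
implements a decision-support pipeline for exactly this situation:

1. **Effective distance** (`cost_surfaces()`, `accumulate_cost()`): the
   estuary is rasterized (15 m cells by default) and the accumulated
   least-cost distance "as the fish swims" is computed from every wastewater
   treatment plant (WWTP) and combined sewer overflow (CSO) outfall, with
   land as an impenetrable barrier (Dijkstra on the water-cell adjacency
   graph; 8- or 16-connected moves).
2. **Features** (`assemble_design()`): each sample gets sediment covariates
   (TOC, sand, mud, depth), raw min/max/mean CSO distances, discharge-
   weighted WWTP proximity scores
   `s_j = (1 + norm(1/d_j)) (1 + norm(V_j)) ∈ [1, 4]`, and planar
   coordinates — 12 predictors.
3. **Random forest** (`fit_forest()`): regression of `log(tcs)` with
   out-of-bag (OOB) validation,
   `MSE_oob = (1/n) Σ (y_i − ȳ_i^OOB)²`, percent variance explained
   `100 (1 − MSE_oob/σ²(y))`, permutation importance (% increase in OOB
   MSE), mtry tuning and partial dependence.
4. **Variable selection** (`var_select()`): three steps — keep positive
   mean importance over 25 seeded forests; smallest nested prefix within
   one SE of the minimal OOB error; greedy correlation-pruning pass —
   yielding a parsimonious prediction model.
5. **Hotspot classes** (`classify_hotspots()`): log-scale predictions are
   discretized at quantiles into low/medium/high under scheme A (terciles),
   B (25/50/25) or C (12.5/75/12.5).

A synthetic-estuary generator (`generate_estuary()`, `generate_fields()`,
`generate_samples()`, `synthetic_training_table()`) produces branched water
domains, shoreline outfalls, autocorrelated sediment fields and
concentration samples with known generative structure, so the entire
pipeline is testable offline. `run_pipeline()` orchestrates everything from
a config list or YAML file; `inst/cli/estuaryRF.R` is a thin command-line
front end.

## Worked example

```r
library(estuaryRF)

fix <- synthetic_training_table(seed = 1)   # synthetic 58-sample estuary
fix$grid
#> estuary_grid: 120 x 80 cells of 15 m (2364 water, 7236 land)

dm <- design_matrix(fix$design)
model <- fit_forest(dm$x, dm$y, forest_config(ntree = 4000, mtry = 9, seed = 1))
model
#> forest_model: 4000 trees, mtry 9, nodesize 1, n = 58, P = 12
#>   OOB MSE 0.6856, % variance explained 48.4

head(permutation_importance(model), 4)
#>   variable raw_inc_mse pct_inc_mse
#> 1      mud   0.5154234   75.181946
#> 2      toc   0.3811924   55.602423
#> 3     sand   0.3797812   55.396580
#> 4 wwtp_avg   0.0325982    4.754919

sel <- var_select(dm$x, dm$y, forest_config(ntree = 1000, mtry = NULL, seed = 1),
                  n_forests = 10, n_rep = 5, ntree = 1000)
sel
#> Three-step variable selection
#>   ranked:         toc, mud, sand, cso_min, wwtp_avg, cso_avg, easting, ...
#>   interpretation: toc, mud, sand, cso_min, wwtp_avg, cso_avg, easting
#>   prediction:     toc, mud, cso_min

pm <- fit_forest(dm$x[sel$prediction_set], dm$y,
                 forest_config(ntree = 4000, mtry = 1, seed = 1))
pm
#> forest_model: 4000 trees, mtry 1, nodesize 1, n = 58, P = 3
#>   OOB MSE 0.6250, % variance explained 53.0

cl <- classify_hotspots(predict(pm, dm$x[sel$prediction_set]), "A")
class_summary(cl)
#>    class count  fraction   min_ngg    max_ngg
#> 1    low    19 0.3275862  1.275386   5.182965
#> 2 medium    20 0.3448276  5.242914  11.666387
#> 3   high    19 0.3275862 12.055092 127.830017
```

Reading the output: the OOB-validated forest explains about half of the
log-concentration variance on this synthetic realization; selection prunes
the 12 predictors to a TOC / grain-size / CSO-distance triple (sand and mud
are exact complements in the generator, so either label can represent grain
size); the tercile scheme splits the 58 predictions into three classes of
~19 points whose back-transformed ranges (e.g. high ≈ 12–128 ng/g) are what
a monitoring program would map.

The same run end-to-end, with artifacts on disk:

```r
run_pipeline(list(seed = 1, simulate = list(), forest = list(mtry = 9)),
             out_dir = "run1")
```

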