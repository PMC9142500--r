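# mixedclust

Feature-type-distributed clustering for mixed-type epidemiological
survey data.

## The problem

Survey tables about chronic disease — the motivating case is detecting
sub-populations among type-2 diabetes patients in a national health
survey — mix three kinds of variables: continuous measurements (age,
BMI, haemoglobin, time to the drinking-water source), ordinal responses
(food-intake frequencies, wealth quintile, education level, binary
comorbidity indicators) and nominal responses (sex, religion, caste,
residence, cooking fuel, water source). Embedding all columns jointly
under one Euclidean metric lets the wide-range continuous columns
dominate every distance: the clustering then reflects a handful of
continuous features and ignores the categorical majority of the table.

`mixedclust` clusters each feature type separately under a
type-appropriate metric and integrates the results:

1. split the table into continuous / ordinal / nominal blocks
   (declared by a `feature_schema`; a packaged 36-feature survey schema
   ships with the package);
2. per block, compute pairwise distances — Euclidean for continuous,
   Canberra `sum |x_i - y_i| / (|x_i| + |y_i|)` for ordinal rank codes,
   normalized Hamming (mean mismatch) for nominal codes — build a
   smooth kNN graph (`n_neighbors = 30`, per-point bandwidths
   calibrated by bisection to `log2(k)`), symmetrize it with the fuzzy
   union `w + w' - ww'`, and embed it with a deterministic spectral
   engine (a stochastic-optimizer engine can be plugged in through the
   same contract);
3. integrate 2 continuous + 2 ordinal + 1 maximum-variance nominal
   coordinate into an `n x 5` representation;
4. extract dense sub-populations with DBSCAN (`eps = 1`,
   `min_points = 200`, or `min_frac = 0.02` to scale with n); clusters
   holding at least 10% of the population are *significant*;
5. characterize clusters the way epidemiological baseline tables are
   written: mean ± SEM for continuous features, count (percent) per
   level for categorical ones.

A synthetic survey generator with planted cluster structure
(`default_nfhs_like_config()`), a naive single-metric baseline
(`naive_baseline()`) and a feature-type bias diagnostic
(`bias_diagnostic()`, eta-squared / Cramér's V per feature) make every
stage testable without access to the survey microdata.

## Worked example

```r
library(mixedclust)

sim <- generate_mixed_data(
  default_nfhs_like_config(n = 1200, k = 4, separation = 1, seed = 7))
res <- run_pipeline(sim$dataset, min_frac = 0.02, seed = 7)
res
#> <pipeline_result>
#> <cluster_labels> n = 1200, 4 cluster(s), 15 noise point(s)
#> sizes: 1:380 2:335 3:305 4:165
#> significant (>= 10%): 1, 2, 3, 4
mclust::adjustedRandIndex(as.integer(res$labels), sim$labels)
#> [1] 0.976

tab <- render_summary(res$summary)
tab[c("Cluster size (N)", "age", "bmi", "time_to_water_source",
      "refrigerator: Yes", "residence: Rural", "fish_freq: Never",
      "wealth_index: Richest"), ]
#>                       Cluster 1      Cluster 2      Cluster 3      Cluster 4
#> Cluster size (N)      380            335            305            165
#> age                   40.95 ± 0.39   37.77 ± 0.38   40.02 ± 0.42   39.68 ± 0.6
#> bmi                   27.02 ± 0.22   24.1 ± 0.25    25.99 ± 0.26   23.83 ± 0.37
#> time_to_water_source  0.3518 ± 0.073 0.3189 ± 0.095 0.2888 ± 0.089 18.72 ± 0.35
#> refrigerator: Yes     377 (99.21)    3 (0.90)       236 (77.38)    49 (29.70)
#> residence: Rural      56 (14.74)     287 (85.67)    144 (47.21)    158 (95.76)
#> fish_freq: Never      6 (1.58)       14 (4.18)      297 (97.38)    8 (4.85)
#> wealth_index: Richest 305 (80.26)    4 (1.19)       165 (54.10)    1 (0.61)
```

The four planted archetypes are recovered as the four significant
clusters (15 rows flagged as outliers; adjusted Rand index 0.976
against the planted partition): an older, obese, urban, affluent
cluster 1 (refrigerator ownership 99%, richest wealth quintile 80%); a
younger, non-obese, rural, poor cluster 2; an obese, strictly
vegetarian cluster 3 (97% never eat fish); and a younger, poorest
cluster 4 living far from its water source (mean 18.7 minutes versus
under 0.4 elsewhere). Each cell reads as in a baseline
characteristics table: `mean ± SEM` for continuous rows,
`count (percent of cluster)` for categorical rows.

A command-line interface over the same functions is installed at
`inst/cli/mixedclust.R`
(`simulate | embed | integrate | cluster | characterize | run |
baseline`), e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/mixedclust.R", package="mixedclust"))')" \
  simulate --n 1200 --k 4 --seed 7 --out survey.csv
```

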