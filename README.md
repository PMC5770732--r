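# hpmica

Resting-state fMRI connectivity analysis as a single, tested R pipeline:
**hierarchical partner-matched ICA (HPM-ICA)** to find reproducible
functional networks across subjects, **Granger causality indices (GCIs)** —
including relay-mediated paths — for directed (effective) connectivity,
**covariate-adjusted group statistics** with Monte-Carlo cluster-extent
correction, and **MLDA / Gaussian-kernel SVM classification** of combined
functional + effective connectivity features under leave-one-out
cross-validation. A synthetic cohort generator plants known networks and
causal structure so every stage can be verified against ground truth
without any data download.

It is aimed at researchers who want the full method chain — of the kind
used in clinical resting-state studies comparing a patient group with
controls — in one reproducible, scriptable package.

## The methods in brief

* **Spatial ICA per subject.** The time-by-voxel matrix is modelled as
  mixing × sources; sources (spatial maps) are estimated by fixed-point
  negentropy-maximizing ICA (logcosh contrast, PCA whitening, symmetric
  decorrelation, multiple restarts).
* **Hierarchical partner matching.** Components are matched across subjects
  by absolute spatial correlation (first level), cluster representatives
  are matched across ICA model orders (second level), and for each group of
  clusters the one with the highest Cronbach's alpha,
  α = k/(k−1) · (1 − Σᵢ varᵢ / var(sum)), is kept — one reproducible map
  per network.
* **Group statistics.** Per-voxel OLS of subject maps on group + age + sex;
  the group t-map is thresholded at a voxel p and a minimum cluster extent
  k calibrated by Monte-Carlo simulation of smoothed null volumes;
  comparisons can be restricted to RSN masks from one-sample t-maps;
  severity scores are correlated with per-subject cluster means.
* **Granger causality.** GCI(x→y) = ln(σ²_reduced / σ²_full) from
  autoregressions of y without/with x's lags (df-corrected residual
  variances); the mediated index max(0, GCI(x→y) − GCI(x→y | relay))
  quantifies influence routed through a relay node.
* **Classification.** Per-fold t-test feature selection (p < 0.05) and
  per-fold standardization inside LOOCV; maximum-uncertainty LDA (pooled
  covariance eigenvalues below their mean raised to the mean) and a
  Gaussian-kernel SVM (width σ = 0.5); metrics reported as accuracy,
  sensitivity, specificity plus fold-averaged feature weights.

See `vignettes/hpmica-methods.Rmd` for the full model descriptions,
parameter rationale, and known limitations.

## Worked example

```r
library(hpmica)

cfg <- pipeline_config(cohort = cohort_config(seed = 7), seed = 7)
res <- run_pipeline(cfg)
res
#> <pipeline_result>
#>   stages: simulate, preprocess, ica, groupstats, granger, classify
#>   MLDA accuracy 95.8% | kSVM accuracy 95.8%

res$classify$mlda
#> <MLDA LOOCV | accuracy 95.8% | sensitivity 100.0% | specificity 91.7%>
```

The default synthetic cohort has 12 subjects per group on a 16 × 16 × 8
grid (150 volumes, TR 2 s, 6 networks), with group A carrying raised map
amplitudes in networks 1–3 and two weakened directed couplings. The
pipeline recovers six reproducible clusters (Cronbach's alpha ≥ 0.995,
mean spatial correlation with the planted sources 0.97) and the Granger
stage finds the planted weakened edge:

```r
res$granger$report[which.min(res$granger$report$p), c("source", "target", "t", "p")]
#>   source target        t            p
#> 1     C1     C2 -7.09846 4.047401e-07
```

i.e. the directed influence C2 → C1 is markedly weaker in group A
(mean ± SD 0.009 ± 0.009 versus 0.117 ± 0.052 in group B) — the coupling
the generator weakened. The LOOCV metrics above say 23 of the 24 subjects
are classified correctly from the combined feature set, and the
fold-averaged MLDA weights rank exactly the planted connections highest:

```r
head(res$classify$weights[order(-abs(res$classify$weights$mean_weight)), ], 3)
#>      feature mean_weight selection_frequency
#> 1  GC:C1->C2   -2.444099               1.000
#> 17 GC:C4->C2   -2.357317               1.000
#> 3  GC:C1->C4    1.317150               1.000
```

Every stage is also callable on its own (`generate_cohort()`,
`decompose_subject()`, `match_components()`, `hpm_ica()`,
`fit_group_glm()`, `mc_cluster_extent()`, `gci_pairwise()`,
`gci_mediated()`, `loocv()`, …), and `inst/cli/hpmica-pipeline.R` provides
a thin command-line wrapper with `simulate` / `ica` / `groupstats` /
`granger` / `classify` / `all` subcommands.

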