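# methdet

Simulation and analysis of methylation-sensitive restriction enzyme
microarrays for relapse prognosis.

## The problem

Promoter CpG-island methylation silences tumour-suppressor genes and
carries prognostic information. One way to read it out of archival (FFPE)
tumour DNA is a two-colour restriction-digest microarray: each sample is
split, one aliquot is digested with a methylation-sensitive enzyme (Hin6I,
blocked by CpG methylation) and the other is mock-digested; both are
amplified, labelled (digested → Cy3 "test", mock → Cy5 "control") and
competitively hybridized to a small CpG-island probe array. Methylated
(digestion-protected) templates keep their test-channel signal, so the
per-spot ratio `R = control / test` falls as methylation rises.

`methdet` implements the full analysis chain for this assay family —
56 gene probes on three identical 8×8 subarrays, each subarray carrying 3
positive controls, 2 hybridization controls and 3 empty background spots —
together with a calibrated synthetic-cohort generator so every stage can be
exercised and validated without access to patient data. The default
simulated cohort mirrors a breast-cancer case series of 123 patients (19
metastatic relapses, 15.4%), with a matched 19 vs 19 option.

## The pipeline

1. **Simulation** (`cohort_config()`, `generate_cohort()`): latent per-gene
   log2 ratios are drawn per sample from group means separated by
   `direction × log2(FC)` with configured within-group spreads, then
   rendered into spot intensities (template × protected fraction,
   lognormal spot noise, additive background, dropout) and written as
   GenePix-style tab-delimited files (`write_cohort()`).
2. **Array processing** (`preprocess_sample()`, `build_matrix()`,
   `categorize_calls()`): empty-spot background subtraction; spots must
   reach 2× the mean hybridization-control signal in *both* channels to be
   informative; genes need ≥ 2 informative replicate spots, else missing;
   gene value = mean of spot ratios; `M = log2(R)` is normalized per sample
   by a lowess fit against control-channel intensity, anchored on the
   positive-control spots (expected log-ratio 0); genes missing in > 25%
   of samples are dropped; binary methylated/unmethylated calls at a
   2-fold threshold.
3. **Differential screen** (`differential_table()`, `apply_cutoffs()`):
   per-gene two-sample t-test on the log2 scale;
   `FC = 2^|Δmean|`; survivors have `FC ≥ 1.5` and `p < 0.05`.
4. **Classifier selection** (`cross_validate_models()`): six model
   families (PLS discriminant, kNN, logistic, LDA, CART tree, forward
   stepwise logistic) compared by mean out-of-fold AUC over 5-fold,
   10-run stratified cross-validation.
5. **Panel selection** (`rank_and_select_panel()`): NIPALS PLS-DA with VIP
   (variable importance in projection) scores averaged over CV fits;
   genes with mean VIP > 1 form the prognostic panel.
6. **Accuracy** (`evaluate_panel()`, `evaluate_single_genes()`):
   sensitivity, specificity, PPV, NPV and rank-based (Mann–Whitney) AUC,
   reported side by side for whole-data resubstitution and
   cross-validation to make the optimism of "whole-model fit" explicit.
7. **Clustering** (`cluster_and_concordance()`): median-centred,
   pairwise-complete euclidean distances, centroid linkage; top-split
   branch versus outcome concordance; newick export.
8. **Power** (`welch_power()`, `panel_power()`): noncentral-t power with
   Welch–Satterthwaite degrees of freedom,
   `δ = Δmean / sqrt(s₁²/n₁ + s₂²/n₂)`, for the per-sample panel average
   and per gene against an 80% adequacy threshold.

`run_pipeline(pipeline_config(...))` chains all stages reproducibly from a
single seed; `inst/cli/methdet.R` wraps `simulate`, `run-all` and `power`
as shell subcommands. Results are tibbles with `tidy()`/`glance()` methods
and `autoplot()`/`plot_*()` graphics.

## Worked example

```r
library(methdet)

cfg <- pipeline_config(
  cohort = cohort_config(
    n_relapse = 19, n_control = 19,
    effects = default_effect_table(sd_relapse = 0.5, sd_control = 0.5),
    null_sd = 0.5
  ),
  seed = 7
)
report <- run_pipeline(cfg)
print(report)
#> <run_report>
#> # A tibble: 6 × 2
#>   stage           count
#>   <chr>           <int>
#> 1 samples            38
#> 2 spots            7296
#> 3 genes_on_layout    56
#> 4 genes_retained     56
#> 5 candidates         19
#> 6 panel               8
#>
#> best model family: pls
#> selected panel: MSH2, DAPK1, BRCA1, PRKCDBP, FABP3, ICAM1, PGR, DNAJC15
#> panel (resubstitution): sens 1.00 spec 1.00 ppv 1.00 npv 1.00 auc 1.000
#> panel (cross-validated): sens 1.00 spec 1.00 auc 1.000
#> panel power: 1.0000
```

Reading this: of 56 probes, all survived the missingness filter; 19 genes
passed the `FC ≥ 1.5`, `p < 0.05` screen (21 were planted at the published
fold changes with within-group sd 0.5); PLS beat the other five families on
cross-validated AUC; eight genes had mean VIP > 1; at these planted effect
sizes the panel separates the groups perfectly under both evaluation modes,
and the panel-average power is 1.

The published panel-level power inputs reproduce directly:

```r
welch_power(2.112189, 1.16809, 0.708074, n_relapse = 19, n_control = 19)
#>  mean_diff sd_relapse sd_control n_relapse n_control alpha noncentrality
#>    2.11219    1.16809   0.708074        19        19  0.05       6.74026
#>        df critical_t    power
#>   29.6547    2.04327 0.999997
```

which rounds to the reported power of 1 for the 7-gene panel average.

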