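# m5Cpattern

Tumor subtyping from the expression of 5-methylcytosine (m5C) RNA-modification
regulators, for bulk transcriptomics cohorts with survival annotation.

Writers (NSUN family, DNMTs), readers (ALYREF) and erasers (TET2) of m5C vary
coherently across tumors, and that variation stratifies patients. This package
implements the full analysis as a reusable, tested pipeline:

1. **Modification patterns** — Monti-style consensus clustering (resampled
   k-means, average-linkage consensus labels, PAC-based selection of k) of a
   user-supplied regulator panel.
2. **Pattern-associated genes** — empirical-Bayes moderated t (one-vs-rest,
   gene-level FDR control), and a second consensus-clustering pass on those
   genes into *gene-clusters*.
3. **The m5C score** — univariate Cox screening (Wald p < 0.01) of the
   pattern-associated genes, then PCA of the retained panel; the per-sample
   score is the PC1 + PC2 coordinate sum,
   `score_s = Σ_i (PC1_i + PC2_i) · z_is`.
4. **Survival dichotomization** — the maximally selected log-rank statistic
   over all admissible cutoffs (`minprop` 0.1) splits samples into high/low
   score groups; Kaplan–Meier/log-rank and per-gene Cox machinery included.
5. **TME quantification** — rank-based single-sample (ssGSEA-style) gene-set
   scores, a stromal + immune composite, and CIBERSORT-style linear ν-SVR
   cell-fraction deconvolution against a marker signature matrix.
6. **Diagnostic classifier** — genes with |Spearman ρ| > 0.4 against the
   score feed a linear SVM (score-group or tumor/normal labels), evaluated by
   confusion matrix and rank-formula AUC.

A synthetic-cohort generator (`simulate_cohort()`, `simulate_mixtures()`)
with exported ground truth — latent clusters, latent prognostic score, true
mixing fractions — backs every stage with parameter-recovery tests.

## Worked example

A full run on a simulated cohort (2000 genes, 200 tumor + 40 normal samples,
3 latent patterns, log-hazard 0.7 per score SD):

```r
library(m5Cpattern)
res <- run_pipeline(sim = sim_config(seed = 11), reps = 250, seed = 11)
print(res)
#> m5C-pattern pipeline run
#>   patterns: k = 3 (PAC-selected)
#>   phenotype DEGs: 71; Cox-screened signature genes: 44
#>   score cutoff 5.419; high/low log-rank p = 8.49e-17
#>   diagnostic features: 33; score-group accuracy 1.000
```

The three simulated patterns are recovered (PAC is exactly 0 at k = 3):

```r
glance(res$consensus_regulators)
#> # A tibble: 4 × 5
#>       k   pac cdf_area  reps subsample_fraction
#>   <int> <dbl>    <dbl> <int>              <dbl>
#> 1     2 0.680    0.451   250                0.8
#> 2     3 0        0.661   250                0.8
#> 3     4 0.235    0.725   250                0.8
#> 4     5 0.293    0.772   250                0.8
```

71 pattern-associated genes survive the gene-level FDR screen; 44 of them are
prognostic at Cox p < 0.01 and form the PCA signature. The maximal log-rank
cutoff splits 55 high- from 145 low-score samples and the groups differ
sharply in survival (log-rank p ≈ 8e-17, expected: the generator ties hazard
to the latent score that the fitted score tracks at |r| ≈ 0.82):

```r
res$cutpoint
#> # A tibble: 1 × 5
#>   cutoff statistic n_high n_low minprop
#>    <dbl>     <dbl>  <int> <int>   <dbl>
#> 1   5.42      8.32     55   145     0.1
```

The 33 score-correlated feature genes reproduce the score grouping perfectly
on the training cohort, and a 5-fold cross-validated tumor/normal classifier
on the same features reaches accuracy 1.0 at the simulated 2-SD tumor shift:

```r
res$eval_score
#> # A tibble: 1 × 9
#>   accuracy sensitivity specificity   auc    tp    fp    tn    fn     n
#>      <dbl>       <dbl>       <dbl> <dbl> <int> <int> <int> <int> <int>
#> 1        1           1           1     1    55     0   145     0   200
res$cv_tissue$accuracy
#> [1] 1
```

Each stage is also exposed directly — `consensus_cluster()`, `select_k()`,
`moderated_t_test()`, `phenotype_degs()`, `select_signature_genes()`,
`fit_score_model()`, `compute_m5c_score()`, `max_rank_cutpoint()`,
`ssgsea_score()`, `estimate_scores()`, `deconvolve_nusvr()`,
`train_classifier()`, `evaluate_classifier()` — with tibble outputs,
`tidy()`/`glance()` methods and `autoplot()` diagnostics. See
`vignettes/m5c-pattern-methods.Rmd` for the models, parameter defaults and
the generator's assumptions.

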