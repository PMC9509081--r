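# pcllike

Transcriptomic classification of plasma cell leukemia-like multiple
myeloma.

Primary plasma cell leukemia (pPCL) is an aggressive form of multiple
myeloma defined clinically by a circulating tumor cell (CTC) level of at
least 20%. A subset of newly diagnosed myeloma (NDMM) tumors never crosses
that clinical cutoff yet carries a bone-marrow transcriptome that closely
resembles pPCL — and a correspondingly poor prognosis. `pcllike` is an R
package for statisticians and computational biologists working with bulk
tumor transcriptomes: it builds, calibrates, applies and evaluates a
*PCL-like score* that quantifies this resemblance, and ships a
synthetic-cohort generator with known ground truth so the entire pipeline
is testable without patient data.

## The method

Genes are ranked by a per-gene linear model on the log-odds scale,

    x_g = a_g + b_g * logit(CTC) + c_g * logit(burden) + e_g,

where `b_g` is the expression change per log-odds unit of CTC level,
independent of tumor burden (bone-marrow plasmacytosis), with
Benjamini–Hochberg FDR control across genes. The number of classifier
genes is chosen by leave-one-out cross-validation (per-fold re-ranking,
held-out AUC for pPCL vs NDMM, smallest size at the maximum). The PCL-like
score of a sample is the equal-weight signed mean of training-standardized
expression over the selected genes,

    S = (1/k) * sum_g sign(b_g) * z_g,      z_g = (x_g - mu_g) / sigma_g,

and the decision threshold is the minimal score among discovery-set pPCL
tumors, so discovery sensitivity is 100% by construction; a sample is
called PCL-like when `S >= threshold` (inclusive). A packaged 54-gene
model with the published threshold 3.55 is included (its gene identities
are a clearly-labelled synthetic stand-in; see the vignette). Downstream,
the package evaluates the score by CTC prediction with a sequential ANOVA
variance decomposition, Wilcoxon/Fisher group comparisons with
sigmoid-scaled odds-ratio co-occurrence, Kaplan–Meier/log-rank curves,
study-stratified Cox models (Breslow ties) and DerSimonian–Laird
random-effects meta-analysis of hazard ratios.

## Worked example

```r
library(pcllike)

cfg    <- sim_config(seed = 11)             # 110 samples x 2,000 genes
cohort <- simulate_cohort(cfg)
fit    <- pcl_classifier(cohort$expression, cohort$annotation,
                         fdr_cutoff = 0.05, size_grid = c(10, 25, 54, 100))
fit
#> PCL-like classifier (built): 100 genes, threshold 0.8071
#>   signs: +50 / -50; rule: score >= threshold => PCL-like
#>   LOOCV-selected size k* = 100
#>   built from 110-sample discovery set (9 pPCL, 101 NDMM), 2000 genes tested
```

The LOOCV curve (`summary(fit)`, `plot(fit)`) shows the held-out AUC per
candidate size — here 0.992 at 10 genes rising to 0.999 at 100 — and the
threshold 0.807 is the lowest score among the nine discovery pPCL tumors.
Scoring an independently simulated validation cohort:

```r
vcfg      <- cfg
vcfg$seed <- 1100L
val       <- simulate_cohort(vcfg, sample_prefix = "V")
scores    <- predict(fit, val$expression)
table(scores$call, val$annotation$disease_label)
#>                NDMM pPCL
#>   not-PCL-like   96    3
#>   PCL-like        0   11
```

Eleven of fourteen validation pPCL tumors are recognized from their
bone-marrow transcriptome alone. How much of the CTC level the score
explains, with tumor burden entered second:

```r
det <- val$annotation$ctc_detectable
predict_ctc(scores$pcl_score[det],
            logit(val$annotation$burden_fraction[det]),
            logit(val$annotation$ctc_fraction[det]))
#> CTC prediction from PCL-like score + tumor burden (n = 110)
#>   variance explained: score 97.6%, burden 0.0%, residual 2.4%
#>   adjusted R^2 (observed vs predicted): 0.976
```

Prognostic value across eight simulated study cohorts (true PFS hazard
ratio 1.85 for PCL-like disease):

```r
studies <- simulate_multistudy(sim_config(n_genes = 10, n_signal_genes = 0,
                                          n_confounded_genes = 0, seed = 11),
                               n_studies = 8, per_study_n = 250)
pfs <- do.call(rbind, lapply(studies, `[[`, "survival"))
pfs <- pfs[pfs$endpoint == "PFS", ]
cox_fit(pfs, covariates = "pcl_like", strata = "study_id")
#> Stratified Cox model (Breslow ties): 2000 subjects, 1439 events
#>          term               hr  p_value
#>  pcl_likeTRUE 1.95 (1.66-2.29) 4.81e-16
meta_cox_by_study(pfs)
#> Random-effects meta-analysis (DerSimonian-Laird), k = 8 studies
#>   pooled HR 1.99 (95% CI 1.63-2.43), tau^2 = 0.0281, Q = 10.56
```

The packaged 54-gene model is loaded with `load_packaged_model()` and
applied to a new cohort with
`predict(model, expr, ref_expr = reference_expr)`, where the reference
cohort supplies the standardization statistics.

See `vignette("pcl-like-classifier")` for the full model description,
generator assumptions, statistical conventions and limitations.

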