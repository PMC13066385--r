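# deconvMM

Compartment-resolved expression analysis and metachronous-metastasis risk
modeling for clear cell renal cell carcinoma (ccRCC)-style cohort studies.

About a third of ccRCC patients with an apparently localized primary tumor
later relapse with *metachronous* metastasis (MM, diagnosed more than 100
days after surgery). Identifying primary tumors at risk — against
*indolent* (IN) and *synchronous metastatic* (SM) comparators — requires
separating expression changes of the cancer cells from those of the
stromal/immune compartment, because bulk tumor RNA mixes both. deconvMM
implements that analysis chain end to end, with a synthetic-cohort
generator providing ground truth for every stage:

* **Two-compartment deconvolution.** Per gene and cohort, bulk log2
  expression `b_i` is regressed on tumor purity,
  `b_i ≈ p_i·e_c + (1−p_i)·e_s`, yielding cancer (`e_c`) and stroma
  (`e_s`) expression with nonnegativity enforced by an exact active set.
  Purity comes from a multi-method consensus (per-sample median, at least
  two methods required).
* **Compartment-specific DE score.**
  `DE = log2( |e_c2/e_c1| / |e_s2/e_s1| )` contrasts the relative change
  between cohorts across compartments (positive = cancer-dominant).
  Significance via a label-permutation null that re-runs the
  deconvolution at every shuffle (add-one empirical p, default 50,000
  permutations, exhaustive enumeration on tiny cohorts,
  Benjamini–Hochberg q-values).
* **Genomic association stages.** Per-gene two-sided Fisher exact tests on
  mutation carriers, SEG→gene copy-number mapping with locus-level
  Wilcoxon tests, copy-number/expression Pearson dosage correlation, and
  one-sided Fisher pathway enrichment against a background universe.
* **GPR reaction scoring.** A parser/evaluator for gene–protein–reaction
  boolean rules scoring metabolic reactions from compartment expression by
  the OR→max / AND→min substitution.
* **Cox risk model.** Feature screening by univariate Cox, a multivariate
  gene-signature model benchmarked by event-stratified 5-fold
  cross-validation repeated 100 times (AUC, c-index, AIC, likelihood-ratio
  p, specificity at a target sensitivity), nested cross-validation with
  LASSO feature selection, and score-tertile Kaplan–Meier stratification
  with a log-rank test.

## Worked example

Simulate a cohort with 10% of genes carrying a planted 2-fold
cancer-compartment change between IN and MM, deconvolute, and test:

```r
library(deconvMM)

cfg <- simulation_config(n_in = 40, n_mm = 40, n_sm = 2, n_genes = 300,
                         noise_sd = 0.2, frac_cancer_de = 0.1,
                         cna_region = NULL, seed = 42)
cohort <- simulate_cohort(cfg)

expr_log <- prepare_expression(cohort$expression, min_median = 2)
purity   <- setNames(cohort$annotation$purity, cohort$annotation$sample)
labels   <- setNames(cohort$annotation$group,  cohort$annotation$sample)

de <- permutation_de_test(expr_log, purity, labels, c("IN", "MM"),
                          n_perm = 1000, seed = 42)
head(de[order(de$p_empirical), c("gene", "de_score", "cancer_log2fc",
                                 "stroma_log2fc", "p_empirical", "q_bh",
                                 "direction")], 5)
#>   gene   de_score cancer_log2fc stroma_log2fc p_empirical      q_bh direction
#>  g0058 -0.3407335   -0.19952017     0.7554796 0.000999001 0.1498501    stroma
#>  g0279 -0.1628390   -0.25026932     0.3513057 0.000999001 0.1498501    stroma
#>  g0012  0.7481968    1.15753706    -0.1906539 0.001998002 0.1498501    cancer
#>  g0025 -0.2525984   -0.24889059     0.6850908 0.001998002 0.1498501    stroma
#>  g0006 -0.4052418   -0.07172182     0.9042644 0.002997003 0.1498501    stroma
```

Each row gives the compartment-resolved fold-changes (group 2 minus
group 1 on the log2 scale), the DE score contrasting them, and the
permutation p with its BH q. `direction` reads the score's sign: `cancer`
for changes concentrated in the cancer compartment.

Benchmark a 5-gene Cox signature on a cohort with a planted hazard
(each gene at hazard ratio 1.8 per SD, 94 usable IN/MM patients):

```r
genes <- sprintf("g%04d", 1:5)
cfg2 <- simulation_config(n_in = 53, n_mm = 41, n_sm = 2, n_genes = 100,
                          noise_sd = 0.2, cna_region = NULL,
                          frac_cancer_de = 0, frac_stroma_de = 0,
                          planted_betas = setNames(rep(log(1.8), 5), genes),
                          seed = 7)
ch2  <- simulate_cohort(cfg2)
ann  <- ch2$annotation[ch2$annotation$group %in% c("IN", "MM"), ]
el2  <- prepare_expression(ch2$expression, min_median = 0)
tab  <- build_feature_table(as.data.frame(t(unclass(el2)[genes, ann$sample])),
                            ann)
cv <- repeated_cv_evaluate(tab, genes, k = 5, repeats = 20,
                           target_sensitivity = 0.878, seed = 7)
cv
#> Cross-validation report (20 repeats x 5 folds)
#>                       metric     mean       sd
#> 1                        auc 7.53e-01 0.021138
#> 2                    c_index 7.75e-01 0.029337
#> 3                        aic 1.15e+02 0.388361
#> 4                      lrt_p 7.17e-04 0.000427
#> 5                sensitivity 9.09e-01 0.000000
#> 6 specificity_at_sensitivity 3.79e-01 0.061562
```

The out-of-fold AUC (event vs censored discrimination of the linear
predictor, averaged over folds and repeats) is 0.75 here; the operating
point holding sensitivity at or above 87.8% retains 38% specificity.
`nested_cv_lasso()` adds per-feature selection frequencies, and
`tertile_logrank()` stratifies patients by score tertiles with a log-rank
test and a number-at-risk table.

A pipeline driver (`run_pipeline()`, YAML-configurable, with a manifest of
seeds and output checksums) and a thin command-line wrapper
(`inst/scripts/deconvmm.R`) chain the simulate → deconvolute → DE stages;
see the vignette for the model details and design choices.

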