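# twinbile

Twin-cohort heritability and gut-microbiome prediction of metabolite
phenotypes.

## What this package is for

Serum and stool metabolites — bile acids in particular — sit at the
crossroads of host genetics and the gut microbiome: primary bile acids are
host-synthesised, secondary ones are microbial transformation products, and
both associate with post-prandial lipaemia and metabolic health. Twin
cohorts make it possible to split the variance of each metabolite into
additive-genetic (A), common-environment (C) and unique-environment (E)
parts, and paired metagenomes make it possible to ask how much of the
"environment" is the microbiome. `twinbile` implements that full analysis
chain for researchers working with twin-registry metabolomics and shotgun
metagenomic profiles:

- **Preprocessing** — the metabolite QC chain: drop metabolites with >20%
  missingness, scale each (metabolite, instrument-batch) cell to a median
  of one, impute missing values with the metabolite's global observed
  minimum (detection-limit censoring), then rank-based inverse normal
  transform (Blom offset).
- **Heritability** — maximum-likelihood twin variance decomposition
  (saturated, ACE, AE, CE, E). Pairs contribute bivariate-normal terms with
  covariance `a² + c²` (MZ) or `a²/2 + c²` (DZ); singletons contribute
  univariate terms. AIC selects the model; profile-likelihood intervals
  cover each variance share; heritability is the a² share.
- **Prediction** — random-forest regressors (Spearman ρ) and outer-quartile
  classifiers (AUC) of each metabolite from species relative abundances
  under twin-aware 5-fold cross-validation: whenever a sample is in a test
  fold, its co-twin is removed from that fold's training set, so
  family-shared variance cannot leak into performance estimates.
- **Association** — covariate-adjusted partial Spearman species screens
  with Benjamini–Hochberg FDR, two-cohort concordance gating (discovery
  q < 0.05, validation p < 0.05, same sign), post-prandial peak/delta
  linear models, DerSimonian–Laird random-effects meta-analysis, paired
  t-tests for intervention change, complete-linkage clustering of species
  association profiles.
- **Synthetic data** — generators for twin cohorts with known ACE
  architecture, compositional microbiomes (optionally family-correlated)
  with planted species→metabolite couplings, instrument-batch scale/censor
  structure, and post-prandial trajectories with a planted slope. Every
  generator returns its ground truth, so the whole chain is testable by
  parameter recovery without access-controlled cohort data.

## Worked example

Simulate the full cohort design (654 MZ pairs, 380 DZ pairs, 471
singletons) with a metabolite whose true heritability is 0.60, fit all twin
models, select by AIC and attach profile-likelihood intervals:

```r
library(twinbile)

design <- cohort_design(n_mz_pairs = 654, n_dz_pairs = 380, n_singletons = 471)
cohort <- simulate_twin_cohort(design, list(isoUDCA = ace_spec(a2 = 0.6, c2 = 0)),
                               seed = 7)
fits <- lapply(c("saturated", "ACE", "AE", "CE", "E"),
               function(m) fit_twin_model(cohort, "isoUDCA", m))
best <- confidence_intervals(cohort, select_model(fits))
print(best)
#> twin AE fit for 'isoUDCA' (654 MZ, 380 DZ pairs, 471 singletons)
#>   a2 = 0.610 [0.564, 0.651]  c2 = 0.000 [0.000, 0.000]  e2 = 0.390 [0.349, 0.436]
#>   loglik = -3353.522, k = 3, AIC = 6713.043
```

AIC picked the AE model (the generating model: c² = 0) and the heritability
estimate 0.610 [0.564, 0.651] covers the planted 0.60; the remaining 39% is
unique environment.

Predict a microbiome-coupled metabolite from species relative abundances
under twin-aware cross-validation, then screen individual species:

```r
mb <- simulate_microbiome(500, 100, prevalence_profile = 0.6, seed = 8,
                          family = cohort$family_id[1:500], family_icc = 0.3)
rownames(mb) <- cohort$sample_id[1:500]
cm <- couple_metabolite(mb, causal_species = 1:4,
                        effect_sizes = c(0.7, -0.6, 0.6, 0.5),
                        noise_sd = 1.1, seed = 9)
cm$r2   # ground-truth variance explained: 0.54

perf <- predict_from_microbiome(mb, cm$trait,
                                cohort[1:500, c("sample_id", "family_id")],
                                ntree = 300, seed = 10)
print(perf)
#> random-forest prediction (500 samples, 100 species, 5-fold, twin-aware)
#>   Spearman rho: mean 0.564 [0.479, 0.648]
#>   AUC:          mean 0.848 [0.784, 0.912]

scr <- species_screen(mb, cm$trait, cohort[1:500, c("age", "bmi", "sex")])
head(scr[order(scr$q), ], 3)
#>   feature    rho        p        q direction   n
#>    sp_001  0.399 2.08e-20 2.08e-18         1 500
#>    sp_003  0.319 3.38e-13 1.69e-11         1 500
#>    sp_002 -0.219 8.23e-07 2.74e-05        -1 500
```

The cross-validated ρ of 0.56 tracks the planted R² of 0.54, the AUC of
0.85 shows the outer quartiles are well separated, and the screen ranks the
planted causal species first with the correct signs.

`run_pipeline(pipeline_config(seed = 1, out_dir = "run"))` executes the
whole chain — simulate, preprocess, heritability, prediction, association —
and writes the result tables plus a YAML run report; identical configs
produce byte-identical tables.

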