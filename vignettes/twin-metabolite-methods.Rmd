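---
title: "Methods: twin heritability and microbiome prediction of metabolite phenotypes"
author: "twinbile authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: twin heritability and microbiome prediction of metabolite phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinbile)
```

# Scope

`twinbile` implements the statistical chain used to dissect host-genetic and
gut-microbial contributions to serum and stool metabolite phenotypes —
bile acids being the motivating panel — in twin cohorts:

1. metabolite QC and normalisation (missingness filter, per-batch median
   scaling, minimum-value imputation, rank-based inverse normal transform);
2. ACE twin variance decomposition by maximum likelihood with AIC model
   selection and profile-likelihood confidence intervals;
3. twin-aware cross-validated random-forest prediction of each metabolite
   from species relative abundances (Spearman rho for regressors, AUC for
   quartile classifiers);
4. association statistics: covariate-adjusted partial Spearman screens with
   Benjamini–Hochberg control, two-cohort concordance gating, post-prandial
   peak/delta linear models, DerSimonian–Laird random-effects meta-analysis,
   paired t-tests for intervention change, and complete-linkage clustering
   of species association profiles.

Cohort-scale human data of this kind is access-controlled, so the package
ships a synthetic-data generator with known ground truth; every stage is
validated by parameter recovery on simulated cohorts rather than by
re-analysis of participant data. Upstream steps (LC-MS peak calling,
taxonomic profiling, dietary index construction) are out of scope: the
package starts from delivered abundance tables.

# The synthetic twin cohort

`simulate_twin_cohort()` draws each trait from the classical additive
model. For individual $j$,

$$y_j = \mu + \sigma\,(a\,G_j + c\,C_j + e\,U_j), \qquad
a = \sqrt{a^2},\ c = \sqrt{c^2},\ e = \sqrt{e^2},$$

where $G$ is identical within MZ pairs and correlated $0.5$ within DZ pairs
(the standard additive-genetic expectation), $C$ is identical within any
pair, and $U$ is independent. The implied intraclass correlations are
$r_{MZ} = a^2 + c^2$ and $r_{DZ} = a^2/2 + c^2$, which the test suite
verifies empirically at $10^4$ pairs.

Defaults encode the study design the package targets: 654 MZ pairs, 380 DZ
pairs and 471 singletons (2,539 individuals). Covariates are kept simple on
purpose — age uniform on 30–75 years shared within a pair, BMI normal
(mean 26, SD 4 kg/m²) per individual, sex Bernoulli with a 0.85
female fraction reflecting a female-skewed twin registry — because their
only job is to let covariate adjustment be tested.

`simulate_microbiome()` draws zero-inflated log-normal abundances (species
presence Bernoulli at its prevalence; present values log-normal with a
species-specific location drawn once, SD 1.5, within-species log-SD 1) and
closes each sample to sum to one. This reproduces the two features that
matter for the downstream machinery: heavy right tails and a prevalence
structure. When a `family` vector is supplied, co-family members share a
fraction `family_icc` of the log-abundance variance and, with the same
probability, a single presence/absence draw — real twins have correlated
gut microbiomes, and without this feature family-level information leakage
in cross-validation (which the twin-aware folds exist to prevent) could not
be demonstrated at all.

What the generator does *not* emulate: read-count noise, taxonomic
misassignment, longitudinal dynamics, and realistic inter-species
correlation beyond the compositional closure and family effects. Passing
recovery tests therefore show the statistics behave correctly under the
stated model, not that any real cohort satisfies that model.

`couple_metabolite()` plants the microbiome signal as a linear combination
of standardised $\log(1+x)$ abundances of chosen causal species plus
Gaussian noise, and reports the realised $R^2$ so prediction stages can be
scored against it. `apply_batch_structure()` multiplies samples by their
instrument-batch scale and then left-censors the lowest `censor_quantile`
fraction of each metabolite — detection-limit censoring, not
missing-at-random, because minimum-value imputation is only a sensible
repair under censoring. `simulate_postprandial()` builds analyte
trajectories from a fasting baseline and a gamma-like pulse whose amplitude
is `amplitude_base + beta*trait + covariates + noise`, truncated at zero;
with the default base of 5 and noise SD 1 the truncation is almost never
active, so the planted slope is recoverable by OLS on the peak.

All generators are pure functions of (parameters, seed). A single master
seed fans out to per-operation sub-streams via `substream()`, a hash of the
operation label, so adding a stage never perturbs another stage's draws.

# Metabolite preprocessing

The QC chain is order-fixed — filter → scale → impute → transform — and the
`metabolite_matrix` stage tag enforces it.

* **Missingness filter**: metabolites missing in *strictly more than* 20%
  of samples are dropped. The threshold is strict because the rule it
  implements is worded "more than"; a metabolite at exactly 20% survives.
* **Batch median scaling**: each (metabolite, batch) cell is divided by the
  within-batch median of its *observed* values, giving every batch — and
  hence the metabolite — a median of one. A batch with no observed values
  for a metabolite, or a zero median, is an error rather than a silent NaN.
  The operation is idempotent.
* **Minimum imputation**: each missing entry is replaced by the
  metabolite's minimum observed value across *all* batches of the scaled
  data (the global minimum, not the batch minimum).
* **Inverse normal transform**: $\Phi^{-1}\!\big((r_i - 3/8)/(n + 1/4)\big)$
  on average ranks — the Blom offset. The offset is configurable; 3/8 is
  the conventional default and nothing downstream is sensitive to the
  choice. Average ranks keep the transform well-defined on the tied values
  that minimum imputation necessarily creates.

Normalisation is per cohort: when two cohorts are analysed, each is
processed separately, matching the package's treatment of cohorts as
separate screens everywhere else.

# Twin variance decomposition

For the non-saturated models (ACE, AE, CE, E) a pair contributes a
bivariate-normal likelihood term with common mean $\mu$ and variance
$\sigma^2_T = a^2\!+\!c^2\!+\!e^2$ and covariance $a^2\!+\!c^2$ (MZ) or
$a^2/2+c^2$ (DZ); singletons contribute univariate terms and so inform only
$\mu$ and $\sigma^2_T$. The saturated model frees mean, variance and
within-pair correlation per zygosity group and serves as the AIC ceiling.

Numerical choices:

* The likelihood depends on the data only through per-group sufficient
  statistics ($n$, $\sum(x_1\!+\!x_2)$, $\sum(x_1^2\!+\!x_2^2)$,
  $\sum x_1 x_2$), so each evaluation is O(1) and a full five-model fit on
  2,539 individuals takes milliseconds. This is what makes the replicated
  recovery tests cheap.
* Optimisation is over unconstrained path coefficients $(a, c, e)$, squared
  on output — components are non-negative by construction and boundary
  estimates (e.g. $\hat c^2 = 0$) are reached smoothly, with no constrained
  optimiser needed. The sign ambiguity is irrelevant because only squares
  are reported.
* BFGS with a moment-based start (Falconer estimates from the observed
  $r_{MZ}$, $r_{DZ}$) plus five deterministic jittered restarts; restarts
  consume no RNG so fits never perturb simulation streams.
* Ties in AIC selection break toward fewer parameters, then the fixed
  order ACE, AE, CE, E.

Confidence intervals invert the likelihood-ratio statistic: the interval
for a share is the set of values whose profile log-likelihood is within
$\chi^2_{1,0.95}/2$ of the maximum, found by root-finding on a
reparameterised profile (total variance log-scale, remaining shares on a
logit split). Estimates on a boundary yield one-sided intervals flagged
with a `boundary` attribute. A delta-method interval (finite-difference
Hessian on the path-coefficient scale) is available as a cross-check; the
two agree away from boundaries but the profile interval is the default
because variance shares near 0 or 1 make the Wald approximation poor.

Traits are assumed already inverse-normalised; no further covariate
adjustment is applied inside the twin model.

# Twin-aware random-forest prediction

Species first pass a near-zero-variance screen (drop when the most-common /
second-most-common frequency ratio exceeds 19 *and* the distinct-value
fraction is below 10%, or when variance is exactly zero — the conventional
screening default). Features enter untransformed as relative abundances.

Folds are drawn at the individual level and then purged: for each test
fold, any co-family member of a test sample is removed from that fold's
training set. This mirrors the procedure "remove a twin from training when
their co-twin is in test" literally, rather than blocking whole families
into folds. The regressor uses all samples (`mtry = ⌊p/3⌋`, `ntree = 1000`
by default); the classifier dichotomises the response at the outer
quartiles (ties at a boundary go to the outer class, the middle half is
excluded *before* fold construction so fold sizes stay balanced) and uses
`mtry = ⌊√p⌋`. AUC is the Mann–Whitney rank statistic with midrank credit;
per-fold values are summarised by the cross-fold mean and the t-interval
$\bar m \pm t_{0.975,\,m-1}\, s/\sqrt m$.

Forests are grown with `ranger` (single-threaded, seeded) — the same
algorithm and hyperparameters as the classical `randomForest`
implementation, chosen for speed and per-fold seed control. Each
metabolite in a panel gets its own derived fold seed.

The leakage property this design guards against is demonstrated in the test
suite: with a trait that is 100% family-shared and a family-correlated but
causally unrelated microbiome, naive 5-fold CV reports a mean Spearman rho
around 0.3 while twin-aware CV stays at zero.

# Association statistics

* **Partial Spearman**: rank-transform both variables (average ranks),
  residualise each on an intercept + covariates by least squares, Pearson
  correlation of residuals; $p$ from the t transform with
  $df = n - 2 - (\#\text{covariates})$. With no covariates this *is*
  Spearman's rho. The construction is invariant to strictly monotone
  transforms of either variable. A constant covariate (sex in a single-sex
  cohort) is dropped with a message.
* **FDR**: Benjamini–Hochberg step-up via `p.adjust`, applied per screen
  (per biofluid × cohort), validated against a brute-force oracle.
* **Concordance gate**: discovery $q < 0.05$, validation $p < 0.05$, same
  sign — features missing from the validation screen are excluded and
  reported, not silently passed.
* **Post-prandial summaries**: baseline is the value at time 0; the peak is
  the maximum over $(0, \text{window}]$, *excluding* the fasting sample — a
  post-prandial peak should not be the fasting value, so delta can be
  negative for a declining trajectory. Windows of 6 h (triglycerides,
  inflammation markers) and 2 h (glucose, insulin) are the conventional
  choices.
* **Meta-analysis**: DerSimonian–Laird, the standard reading of "random
  effects inverse variance": $\tau^2 = \max\{0, (Q - (k-1)) / (\sum w_i -
  \sum w_i^2 / \sum w_i)\}$, pooled weights $1/(se_i^2 + \tau^2)$, Wald
  interval; no Knapp–Hartung correction. With $\tau^2 = 0$ it reduces
  exactly to fixed-effect pooling, and the implementation is cross-checked
  against `metafor::rma(method = "DL")`.
* **Paired t-tests** for before/after intervention change, with an explicit
  error on zero difference variance.
* **Clustering** of species association profiles: complete linkage on
  Euclidean row distances via `hclust`; leaf order is the deterministic
  order of the standard agglomeration.

# Problem sizes in the shipped checks

The replicated checks run at sizes chosen to give stable Monte-Carlo
estimates at interactive cost: heritability recovery at the full design
(654 + 380 pairs + 471 singletons) over 50 replicates; Falconer consistency
at $10^4 + 10^4$ pairs over a six-point $(a^2, c^2)$ grid; the CV-leakage
contrast at $n = 400$, 200 species, `ntree = 200` over 50 replicates;
prediction recovery at $n = 800$, 150 species with planted $R^2 \approx
0.5$; FDR control over 500-species global-null screens. Forest sizes in
the replicated simulations use `ntree` of 100–200 — forest performance
metrics are flat in `ntree` well below the production default of 1000, and
the contrast under study is between fold schemes, not absolute accuracy.

# Known limitations

* The DZ genetic correlation is fixed at 0.5: no assortative mating, no
  dominance (ADE), no sex-limitation or bivariate models.
* Correlation screens apply no mixed-effects correction for twin
  relatedness; relatedness is handled where it matters most here — in the
  cross-validation design.
* The generator's missingness is purely left-censored; if real data were
  missing at random, minimum imputation would bias low values.
* Profile intervals assume a unimodal profile likelihood; at extreme
  boundary fits they degrade to one-sided intervals rather than failing.
* `run_pipeline()` analyses a single simulated cohort split into two
  pseudo-cohorts for the discovery/validation and meta-analysis stages;
  applying the package to real paired cohorts means running the screens per
  cohort and feeding `replicate_concordance()` / `meta_random_effects()`
  directly.
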