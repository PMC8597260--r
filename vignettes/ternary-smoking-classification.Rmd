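---
title: "Methods: two-stage ternary smoking-status classification from DNA methylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage ternary smoking-status classification from DNA methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ternmeth)
```

## The problem and the model

Smoking leaves a strong, reproducible imprint on blood DNA methylation.
At some CpG sites the shift persists for decades after cessation
("persistent" sites); at others methylation returns to never-smoker levels
within a few years of quitting ("reverting" sites). Former smokers
therefore form an intermediate cluster that overlaps both neighbours,
which is exactly why a single binary classifier cannot resolve three
classes — and why a *pair* of binary classifiers can:

1. a **persistent-site score** separates *ever* (current + former) from
   *never* smokers, because ever smokers remain shifted there;
2. a **reverting-site score** separates *current* from *former* smokers,
   because former smokers have drifted back at those sites.

A score is linear in the methylation fractions,
$s_i = b_0 + \sum_j b_j \,\beta_{ji}$, applied to beta values on the
0–1 scale (not M-values, and not percentages — a published weight set
calibrated on a 0–100 scale would need its weights divided by 100 before
use with this package). `train_ternary()` fits one threshold per stage on
development data and freezes both; `apply_ternary()` / `predict()` use the
stored thresholds only. Stage 2 is **trained** on self-reported ever
smokers (the cleanest available current/former contrast) but **applied**
to stage-1-predicted ever smokers; this asymmetry is deliberate — at
application time self-report is exactly what the classifier is supposed to
replace.

## Thresholds and orientation

Candidate thresholds are the midpoints between consecutive distinct sorted
scores, plus $\pm\infty$ sentinels; the optimal threshold minimises the
Euclidean distance $\sqrt{(1-\mathrm{sens})^2 + (1-\mathrm{spec})^2}$ to
the ROC (0, 1) corner. Ties in the minimal distance go to the smallest
threshold, making training fully deterministic. With `direction = "auto"`
the orientation (case above or below threshold) is resolved at training by
whichever gives AUC ≥ 0.5 and is stored in the rule — necessary because
smoking *lowers* methylation at sites like cg05575921, so a raw AHRR-style
score places cases below the threshold. A score exactly equal to a
threshold is assigned to the control class; since thresholds are midpoints
of observed scores, exact ties essentially never occur on continuous data,
but the convention is fixed and unit-tested so behaviour at the boundary
is never platform-dependent.

Degenerate inputs fail loudly: single-class labels are refused, and a
score vector with all values equal (an uninformative score whose ROC has
only the two trivial operating points) raises an error rather than
returning an arbitrary cut.

## AUC, DeLong variance and paired comparison

AUC is the Mann–Whitney concordance — ties count one half — computed by
midranks, so heavy ties (common when a score is a single beta value) are
handled exactly. Variances use DeLong structural components; the 95% CI is
the normal approximation on the AUC scale truncated to [0, 1] (a
deliberate, documented choice: bootstrap CIs are out of scope). The paired
`delong_test()` orients each score case-high by its own direction before
comparing, so a score that discriminates "downwards" is not penalised for
its sign. When both scores are identical the variance of the difference is
zero and the test returns $z = 0$, $p = 1$ rather than 0/0. The test suite
cross-checks AUC, variance, CI, threshold and the paired test against an
independent ROC implementation, and verifies the p-value distribution is
uniform under the null and that the CI covers a known binormal AUC at
≈95%.

## The evaluation battery

`confusion_summary()` mirrors the standard development/validation
reporting for classifiers of this kind: accuracy with an exact
Clopper–Pearson binomial CI; the no-information rate (largest observed
class proportion) with a one-sided exact binomial test of accuracy
exceeding it; unweighted Cohen's kappa
$(p_o - p_e)/(1 - p_e)$ with $p_e$ from the row×column marginal products;
and one-vs-rest sensitivity, specificity, PPV and NPV per class. The NIR
is always computed from the labels actually supplied, never taken from an
external table. When both sides contain a single identical class,
$p_e = 1$ and kappa is undefined; it is reported as 0 with a warning.
Per-class metrics with empty denominators are `NA`, not 0. All of these
agree with caret's `confusionMatrix` in the cross-check tests.

## Riley criteria: how many CpGs may a score contain?

For a binary outcome developed on $n$ samples with outcome proportion
$\varphi$ and anticipated apparent $R^2$, `max_parameters()` evaluates the
three published criteria. With
$\ln L_0 = n(\varphi\ln\varphi + (1-\varphi)\ln(1-\varphi))$ and
$\max R^2_{cs} = 1 - e^{2\ln L_0/n}$, the parameter bounds are
$p \le n(S-1)\ln(1 - R^2_{cs}/S)$ with $S = 0.9$ (shrinkage criterion)
and with $S = R^2_{cs}/(R^2_{cs} + \delta \cdot \max R^2_{cs})$,
$\delta = 0.05$ (optimism criterion, the ≤5% Nagelkerke-optimism bound
mapped to the Cox–Snell scale on which the criteria operate). Criterion 3
($n \ge z^2 \varphi(1-\varphi)/\mathrm{margin}^2$) constrains $n$, not
$p$, and is reported as a feasibility flag. Bounds are floored, which is
conservative. As the anticipated signal vanishes the shrinkage bound — and
with it $p_{\max}$ — goes to zero; the optimism bound tends to the
positive limit $n\ln\!\big(1/(1-\delta\max R^2_{cs})\big)$, a property of
the published formula itself.

One input convention matters in practice. The widely used sample-size
software for these criteria takes its `rsquared` argument on the
**Cox–Snell** scale, and published analyses frequently feed a Nagelkerke
estimate straight into it. `riley_spec()` therefore exposes `r2_scale`:
`"nagelkerke"` (the default; converted via
$R^2_{cs} = R^2_N \cdot \max R^2_{cs}$, the statistically faithful reading
of a Nagelkerke input) and `"cox_snell"` (use the value as is, reproducing
that software's behaviour). For the compositions shipped in the acceptance
script ($n = 1063$, $\varphi = 0.66$ and $n = 698$, $\varphi = 0.52$, with
apparent $R^2 = 0.609$) the two scales give caps of 52/36 and 61/42
respectively; both are computed and reported, with all intermediates, so
the reader can audit which convention a given cap reflects.

## LASSO score derivation

`lasso_select()` delegates the penalised path and cross-validation to
glmnet: binomial deviance loss (the package's reading of "minimum mean
cross-validated error" — deviance is glmnet's own default for logistic
CV), a 100-value log-spaced λ path from the empty-model λ downwards,
5 folds by default, and λ at the minimum mean CV deviance. Fold assignment
is class-stratified and fully determined by the spec's seed, so a rerun is
bit-identical. Predictors are **not** standardised by default: the
exported weights must apply directly to raw beta fractions so that a score
model file is self-contained. A `standardize = TRUE` flag exists; either
way glmnet reports coefficients back on the raw scale, and a round-trip
test asserts the exported `score_model` reproduces the fitted linear
predictor to 1e−8. When a parameter cap (typically a Riley bound) is
exceeded at λ-min, the smallest λ whose selection respects the cap is used
instead and the substitution is flagged in the diagnostics rather than
silently applied.

## The synthetic generator: what it emulates, and what it does not

`generate_methylation()` draws, per CpG, a never-smoker mean from
`baseline_range` and applies the behaviour-class shifts described above;
individual values are logit-normal around the class mean
(`noise_sd` on the logit scale), which keeps every beta strictly inside
(0, 1) with a single dispersion knob — a standard way to model methylation
heterogeneity, chosen here as a modelling decision, not an empirical
claim. Defaults: 50 persistent + 50 reverting + 50 partial + 350 null
CpGs; 200 samples per class; effects of −0.15 beta shift (negative:
smoking-associated hypomethylation, so orientation handling is genuinely
exercised); `former_fraction_partial = 0.5` placing former smokers halfway
at partially-reverted sites; `noise_sd = 0.5`; baselines in (0.3, 0.8) so
shifted means stay safely inside (0, 1). Configurations whose shifted
means would leave (0, 1) are rejected at construction. Under these
defaults a 50-CpG oracle score separates its target contrast almost
perfectly (AUC > 0.9 is the tested property); single CpGs overlap
substantially, as on real arrays.

Because baseline methylation is a property of a CpG, not of a cohort, a
validation cohort must share its CpG universe with the development cohort:
passing `truth = dev$truth` reuses the ids, behaviours and true class
means and draws only new samples. Generating two cohorts independently
instead simulates applying a classifier to a *different array with
different biology* — a structural mismatch no real external validation
has — and is the main way to misuse the generator.

The generator deliberately omits: probe-type and batch artefacts,
cell-composition mixtures, age/sex confounding, per-sample
time-since-cessation dynamics (former-smoker heterogeneity is the single
interpolation parameter), and any correlation between CpGs beyond their
shared class structure. Passing tests on synthetic data therefore
demonstrates the *machinery* — threshold fitting, frozen application,
calibrated inference, recovery of informative sites — not performance on
real 450K cohorts, which depends on normalisation and confounding this
package does not model.

## Presets and problem sizes

`synthetic_presets()` ships `paperlike-dev` (1063 samples:
364/334/365 current/former/never) and `paperlike-val` (717 samples:
260/263/194), the compositions used by the end-to-end tests and the
acceptance script, plus `weak-former` (`former_fraction_partial = 0.9`)
emulating recently-quit cohorts. The test suite sizes its simulations to
be informative yet quick: 1000-instance exact-oracle sweeps for thresholds
and AUC, 2000 replicates for p-value uniformity, 1000 for CI coverage, a
20,000-rep bootstrap for the paired-test cross-check, and cohorts of a few
hundred samples elsewhere; the full suite runs in well under a minute.

## Known limitations

* Real-data performance claims are out of scope: no normalisation, no
  cell-type adjustment, no GEO ingestion — inputs are plain beta matrices.
* Hard class assignments only; no probabilistic (soft) ternary output.
* DeLong CIs can be anti-conservative for AUCs very near 1 with small
  samples; bootstrap CIs are intentionally not provided.
* Mean imputation of missing betas (`missing_policy = "mean_impute"`) is
  available but off by default, because silent imputation changes
  classifications; the default is to fail on missing values at model CpGs.
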