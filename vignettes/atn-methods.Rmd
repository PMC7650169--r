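---
title: "Classifying ATN biomarker status and predicting it from risk factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying ATN biomarker status and predicting it from risk factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atnpredict)
```

## The problem

In cognitively healthy older adults, Alzheimer's disease can be present as
a purely biological state long before symptoms. The A/T/N framework
classifies individuals by three binary biomarkers — **A**myloid (CSF
Aβ42), **T**au (CSF phosphorylated tau) and **N**eurodegeneration (here,
medial temporal atrophy on MRI) — independent of clinical presentation.
`atnpredict` implements a complete, testable pipeline for this setting:
deriving the biomarker cut-offs, assigning the five ATN groups, computing
vascular composite risk scores, and quantifying how well constitutional,
cognitive and vascular risk factors predict biomarker group membership.

Because individual-level data from multi-site prevention cohorts are
access-controlled, the package ships a synthetic-cohort generator that
emulates the relevant structure, so every stage is exercisable and
testable without restricted data.

## Biomarker dichotomisation

### CSF cut-offs by Gaussian mixture modelling

CSF analyte distributions in mixed normal/pathological populations are
bimodal. `fit_two_component_mixture()` fits
$w_1\,N(\mu_1,\sigma_1^2) + w_2\,N(\mu_2,\sigma_2^2)$ by EM:

* initialisation by a quantile split (the first start splits at the
  median; further starts perturb the split point to random quantiles),
* `n_starts = 10` restarts, keeping the best final log-likelihood,
* convergence when the relative log-likelihood change falls below
  `tol = 1e-8` (at most 500 iterations by default),
* component SDs floored at $10^{-6}$ of the overall SD so the likelihood
  stays bounded.

Two dichotomisation rules are supported. `intersection_cutoff()` returns
the point between the component means where the weighted component
densities are equal, solved in closed form (a quadratic in $x$, linear
when the SDs coincide) and verified numerically; with extreme weight
imbalance no such point exists between the means and the function says so,
pointing to the alternative. `mean_sd_cutoff()` implements that
alternative: component mean moved $k$ SDs toward the other component. The
number of SDs is not standardised in the field; the default `k_sd = 2` is
common practice and configurable. Fits whose components are not genuinely
separated (closer than one pooled SD, or one carrying under 5% of the
mass) are flagged by `components_separated()` and should not be used for
intersection cut-offs.

The package also ships the published fixed rules — Aβ42 < 1025 pg/ml ⇒
A+, p-Tau > 24 pg/ml ⇒ T+ — as `default_cutoff()` objects so
classification can run without refitting. All comparisons are strict;
ties at a threshold are negative.

### Neurodegeneration

N-status uses the Scheltens medial-temporal-atrophy visual rating (0–4 in
half points, left/right averaged) with age-banded thresholds: N+ when the
score is strictly above 1 (age < 65), 1.5 (65–74) or 2 (75+). The source
wording leaves exactly-75 unassigned between its two oldest bands; this
package places 75 in the oldest band so coverage is contiguous, and
documents that choice rather than asserting it as the original authors'
intent.

## Group assignment and the analytic sample

`assign_group()` maps the eight complete flag patterns to five groups:
normal AD biomarkers (A−T−N−), Alzheimer's pathologic change (A+T−N−),
Alzheimer's disease (A+T+N±), concomitant AD and non-AD pathologic change
(A+T−N+), and non-AD pathologic change (A−T+N± or A−T−N+, the SNAP-like
profiles). Any missing flag makes the participant unclassifiable.

`apply_exclusions()` builds the analytic sample in three ordered stages —
clinical dementia/MCI diagnosis, then CDR global ≥ 0.5, then incomplete
ATN profile — attributing each excluded participant to the first stage
that catches them, which makes the cascade arithmetic exactly auditable:
stage counts plus the analytic n always sum to the input n.

## Composite risk scores

CAIDE and the sex-specific Framingham general-cardiovascular and stroke
point systems are table-driven: each lives in a plain-text CSV under
`inst/extdata/scoring_tables/` mapping fields to points through half-open
`[low, high)` bands or flag values, optionally conditioned on another
flag (the Framingham CVD systolic-BP bands differ by antihypertensive
treatment). Tables are validated at load: bands must partition
`[0, Inf)`, flags must cover both values. Two self-report adaptations
replace lipid measurements: CAIDE's cholesterol component contributes a
flat 2 points for self-reported hypercholesterolaemia, and the Framingham
CVD table awards the sex-specific diabetes points for it.

Transcription choices worth knowing about: the source tables use
inclusive wording ("≤ 140", "> 53"), mapped here to half-open intervals
at the printed boundary (documented per table; no downstream result in
this package depends on a boundary case); the Framingham CVD source
legitimately assigns *negative* points to low untreated systolic BP, so
the loader permits negative integers; the women's treated-BP interaction
in the stroke source is collapsed to a flat 2-point treatment term for
both sexes; and left ventricular hypertrophy — rarely available in
research cohorts of this kind — defaults to absent. A missing input for
any other component makes the score `incomplete` rather than guessing.
Scores enter models as cohort-wide z-scores (`standardize_scores()`,
sample SD) computed over complete results only.

## The association and prediction battery

* `fit_pathology_logistic()` — age- and sex-adjusted binary logistic
  models of A+/T+/N+ on one exposure; Wald 95% CIs and p-values
  (likelihood-ratio alternatives were considered; Wald matches the
  log-symmetric intervals conventional in this literature). Complete
  separation is reported as non-estimable, not an error.
* `fit_multinomial()` — multinomial logit over the five groups with the
  normal group as reference, age/sex and optionally 21 fixed study-site
  effects; exponentiated contrasts are relative risk ratios.
* `interaction_scan()` — adds one exposure-by-moderator product term
  (APOE4, age or sex as moderator) and tests it per contrast.
* `compare_groups()` — five-group omnibus comparisons: one-way ANOVA with
  all ten pairwise t-tests Bonferroni-multiplied and capped at 1 for
  continuous variables; 2×5 chi-square with *adjusted standardised*
  residuals $R_{gc} = (O-E)/\sqrt{E(1-n_{g\cdot}/N)(1-n_{\cdot c}/N)}$
  for binary ones, flagging $|R|>2$. The adjusted (margin-corrected)
  variance form is used, matching how such residuals are conventionally
  reported; expected cells below 1 attach a small-cell warning.
* `bonferroni_threshold()` — family-wise alpha divided by the family
  size. Published footnotes in this literature sometimes print "0.5/m"
  families; both 0.5 and 0.05 work as the alpha argument and the
  arithmetic is the caller's choice.
* `fit_and_auc()` / `roc_battery()` / `compare_to_basic()` — the nested
  prediction models: model 1 (age, sex, APOE4; plus age×APOE4 and
  sex×MMSE product terms for the Alzheimer's-pathologic-change contrast),
  models 2–5 adding family history, BMI, WML volume and MMSE in turn,
  model 6 with all of them, models 7a–c adding each z-scored composite.
  AUC is the in-sample (apparent) rank/Mann–Whitney statistic with
  mid-rank ties and a DeLong 95% CI; no cross-validation or optimism
  correction, by design. Model comparison is the likelihood-ratio
  chi-square with both models refit on the extended model's complete-case
  rows — the only nested chi-square consistent with maximum-likelihood
  logistic fits; whether to refit the basic model on the common subsample
  is genuinely open, and refitting is this package's documented choice.

Per-model complete-case (listwise) deletion is used throughout, so each
model's n reflects its own covariates' missingness.

## What the synthetic cohort does and does not emulate

`generate_cohort()` is calibrated, by default, to the study conditions the
package is designed around: 1500 over-50s across 21 sites; an exclusion
cascade of 82 (dementia/MCI), 171 (CDR ≥ 0.5) and 237 (incomplete ATN)
leaving 1010 analytic participants; and per-flag combination counts
(567/211/58+9/31/84+7+43) consistent with every published margin — 309
A+, 158 T+, 90 N+ and group sizes 567/211/67/31/134. The A+T+ split
across N± and the non-AD split across its three combinations are not
published; the defaults are one consistent choice and are configurable.

Covariates are drawn *independently within group* from group-specific
marginals (means/SDs for continuous variables, prevalences for flags);
published tables constrain only these marginals, and the within-group
independence is a stated simplification, not a claim about real data.
WML volume is strongly right-skewed (SD ≫ mean) and is drawn from a
log-normal matched to the configured arithmetic mean and SD. CSF values
are placed on the requested side of the active cut-off at a half-normal
margin (scales 150 pg/ml for Aβ42, 5 pg/ml for p-Tau), guaranteeing the
classification round-trip while keeping realistic overlap; note this
makes the marginal CSF density peak *at* the cut-off, so configs that
exercise the mixture-refit route should set a positive margin offset to
obtain genuine bimodality. Scheltens scores are sampled on the correct
side of the age-specific threshold with weight decaying away from it.
Ages are truncated at 50 (the recruitment floor) and MMSE is rounded and
clamped to 0–30.

Consequences for interpretation: passing tests demonstrate that the
*procedures* are correct under known generating conditions (exact cascade
arithmetic, exact group recovery, calibrated effect-size recovery), not
that real cohort data share the generator's independence structure. In
particular, apparent AUCs computed on independently-drawn covariates can
differ from those in real data, where covariates correlate; the
acceptance checks therefore use generous neighbourhoods for AUC targets.

`generate_from_model()` is the companion for effect-recovery studies:
covariates from stated base distributions, outcomes from a specified
binary or multinomial logistic model (binary runs through the
two-category multinomial path, so the two coincide exactly on matched
seeds), with optional product terms and a no-effect site factor.
`calibrate_logit_intercept()` pins the intercept to a target prevalence.

All generation uses R's default Mersenne-Twister generator; a single
config seed makes runs byte-identical.

## Numerical choices and problem sizes

EM tolerance 1e-8 (relative log-likelihood), 10 restarts, max 500
iterations; intersection roots verified to a relative density difference
below 1e-8; z-scores use the sample (n−1) SD; multinomial fits use
`nnet::multinom` with `reltol = 1e-10` (tightened to 1e-16 where
equivalence with binary logistic is asserted); Wald CIs use ±1.96, the
DeLong CI uses the exact 97.5% normal quantile. Effect-recovery
simulations use n = 100,000 (keeping Monte-Carlo error well inside the
5–10% recovery tolerances); mixture recovery uses n = 5,000 per analyte;
AUC summaries average 20 replicates of a 525-vs-64 two-group design;
property suites use 50–200 replicates at a few hundred observations each.

## Known limitations

* The scoring-table transcriptions are auditable but band-edge choices at
  inclusive/exclusive boundaries are this package's own mapping.
* No imputation: missing biomarkers make a participant unclassifiable and
  missing score components make the composite incomplete.
* Only two-component Gaussian mixtures; no bootstrap CIs for cut-offs.
* In-sample AUC only; no external validation or recalibration.
* The generator does not simulate longitudinal follow-up, attrition,
  assay drift, or realistic between-covariate correlation (an optional
  per-group correlation hook is deliberately left out until there is a
  defensible joint target to calibrate to).
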