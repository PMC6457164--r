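---
title: "Methods: two-phase diagnostic accuracy for antenatal screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-phase diagnostic accuracy for antenatal screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(twophasedx)
```

# The design and its estimators

A two-phase validation study screens a whole clinical population with a cheap
index instrument and administers the expensive gold standard to all
screen-positives but only a random 1:k sample of screen-negatives. The
package's estimation layer assumes:

* the phase-two sample is drawn by a known stratified mechanism (here,
  independent Bernoulli 1/k selection of screen-negatives, all positives
  invited), with consent acting as further thinning;
* design weights are computed from **realized** interviewed counts,
  `w_h = N_h / n_h`, not from nominal sampling fractions. Consent
  non-response is thereby absorbed into the weight. This reproduces printed
  weights of real studies exactly (e.g. 906/287 and 9057/258), at the cost
  that the estimand is strictly the consenting population: the weighting
  corrects the *design* imbalance, not consent selectivity. With consent
  independent of disease the two coincide in expectation;
* diagnoses are input labels; the package models nothing about the
  diagnostic interview itself.

Weighted cells of the 2×2 table are sums of per-record weights, and all
accuracy measures derive from them, so Bayes consistency
(PPV from Se, Sp and prevalence) holds exactly by construction — the unit
tests assert it to 1e-12. Division by an empty *disease* margin is a typed
error; an empty *test* margin (possible at extreme cut-offs) yields `NA`
predictive values with a flag rather than an error, so that cut-point tables
can include the degenerate rows Se = 1/Sp = 0 and Se = 0/Sp = 1.

Confidence intervals use a percentile bootstrap, resampling records with
replacement **within screening stratum** with stratum sizes fixed, each
record carrying its weight. Defaults: B = 1000, 95% level. Percentile
intervals were chosen as the simplest defensible interval for weighted
ratio estimators; their small-sample coverage is checked by simulation
(300 replicate studies; the suite accepts 90–99% coverage for a nominal
95% interval).

# Covariate-adjusted ROC regression

For an ordinal score the package fits

$$ROC_Z(t) = \Phi(\alpha_0 + \alpha_1 \Phi^{-1}(t) + \beta^\top Z)$$

by the parametric distribution-free placement-value method: the placement
value of a case score is the weighted proportion of controls scoring at or
above it; binary indicators $1[pv_i \le t]$ over a grid of false-positive
rates are regressed on $\Phi^{-1}(t)$ and the case covariates with a probit
link and case design weights. The model assumes covariates shift the ROC
curve only — the control distribution is used unadjusted, which is the
appropriate assumption when controls are homogeneous with respect to the
covariates' effect on the score.

Numerical choices:

* **t grid**: 0.01–0.99 in steps of 0.01 (99 points). Finer grids change
  estimates negligibly for a 31-point ordinal score.
* **Ties**: score ties between a case and controls contribute half weight
  (mid-rank). Ordinal 0–30 scores guarantee ties; mid-ranks keep the
  identity between the trapezoid AUC and the weighted concordance
  probability exact (asserted to 1e-10 against an exhaustive-pairs oracle).
* **Inference**: each case contributes one row per grid point, so rows are
  strongly dependent within case; the covariance is a sandwich clustered on
  the case, computed in closed form from the probit scores and cross-checked
  in the tests against `sandwich::vcovCL` on an identical `glm` fit.
  Per-covariate Wald χ² statistics test the full contrast block of a
  categorical covariate jointly.
* The fitted `alpha1` should be positive; a non-positive estimate is flagged
  on the fit rather than silently accepted.

A known property, documented rather than hidden: the cluster-robust Wald
test is **liberal in small samples**. In null simulations its size is about
8% at 250 cases per group and reaches the nominal 5% (within 3–7%) at about
500 cases per group; the calibration check in the suite therefore runs at
500 cases/controls over 400 null replicates. Parameter recovery is verified
on data simulated from the binormal model itself (continuous latent scores,
1000 cases and controls, 100 replicates, mean absolute bias below 0.05 for
$\alpha_0, \alpha_1, \beta$); with discretised 0–30 scores the true ROC of
the *observed* score is a step function that only approximates the latent
binormal curve, so exact parameter recovery is a property of the latent
scale, not of the coarsened score.

# Missing data

Two mechanisms are handled, mirroring what happens in practice:

* **Item-level** questionnaire missingness: single-round predictive mean
  matching. For each item, a linear regression on the mean of the record's
  other observed items plus age is fitted on complete donors; each missing
  cell is filled from one of the `donor_k = 5` donors nearest in predicted
  mean, drawn uniformly, ties broken by record order. Records with more
  than 30% of items missing are never imputed; they are excluded from
  score-based analyses. A single round (no chained iterations, no multiple
  imputation) is deliberate: with ≤3 of 10 items missing the gain from
  iteration is negligible and single imputation keeps downstream weighting
  simple.
* **Module-level** gold-standard missingness: a logistic response model of
  module completion on the (post-imputation) questionnaire total, ethnicity
  and employment. Analysis weights are `design_weight / p̂(respond)` for
  module-observed records; module-missing records are excluded from that
  module's analyses. Response probabilities below 0.02 are floored there
  (weight capped) to bound variance inflation — standard IPW practice.
  When no module is missing the model degenerates to probabilities of
  exactly 1 and the analysis weights equal the design weights.

Quasi-separation is a real hazard in small samples (a sparse ethnicity
category with no missing modules); `fit_response_model()` raises an error
suggesting category collapsing, and the pipeline's `fit_response_model_safe()`
falls back to progressively simpler predictor sets, logging the reduction.

The IPW correction is validated by a bias-reduction experiment: under
missingness at random in the questionnaire total strong enough that module
response falls from ~0.92 at score 0 to ~0.08 at score 25 (8000 screened,
200 replicates), the IPW estimate of the cut-off-13 sensitivity is closer to
the truth than the complete-case estimate in at least 80% of replicates.
Under weaker missingness the two estimators differ by less than the
sampling noise and the comparison is uninformative — which is itself the
expected behaviour, not a failure of the correction.

# The synthetic cohort generator

The generator is first-class, tested code: it defines the conditions under
which every estimator is validated. Defaults emulate the structure of a
large inner-city antenatal screening population:

| parameter | default | rationale |
|---|---|---|
| `n_screen` | 9963 | screened population with a recorded screen result |
| prevalence | depression 0.11, anxiety 0.15, any 0.27 | weighted population estimates typical of early pregnancy |
| screen Se/Sp | 0.41 / 0.945 | the two-item screen as asked in routine care; yields ~9% positivity |
| `mu1`, `sigma1` | 1.78, 1 | binormal AUC Φ(1.78/√2) ≈ 0.89 for the score vs depression |
| score map | round(5.5 + 4.5·latent), clamped to 0–30 | see calibration note below |
| consent | 0.34 | observed participation among invitees in comparable studies |
| item missingness | 0.005 MCAR per item | of the order of a few records per hundred with 1–3 items missing |
| module missingness | logistic, intercept 3.5, slope −0.05 per score point | ~4% missing modules, worse at high scores |

**Calibration note.** The score discretisation is calibrated so that the
cut-off 12/13 has sensitivity ≈ 0.59 and specificity ≈ 0.94 against
depression and the binormal AUC is ≈ 0.89 — the operating characteristics a
validation study in this setting reports. An alternative would be to
calibrate the *control* score distribution to the interviewed sample's
printed median of 7 (IQR 4–13); but that sample is verification-biased
(half screen-positive, case-enriched), so its quantiles overstate control
scores, and matching them contradicts the printed Se/Sp/AUC. With the
chosen map the *stratified interviewed sample's* median and IQR come out
close to those printed values, which is the consistent reading.

Items are produced by sampling `total` of the 30 unit slots (3 per item)
without replacement — uniform over item vectors with the given total and
0–3 caps — so items sum exactly to the discretised latent total.

Two screen answers are generated so that the *either*-rule has the
configured Se/Sp; among positives, the probability of endorsing both
questions is 0.61 for cases and 0.35 for non-cases, making the
*both*-rule markedly less sensitive and more specific, and the help
question is endorsed by 20% of screen-positive cases and 18% of
screen-positive non-cases, making the *help*-rule sensitivity an order of
magnitude below the either-rule — the qualitative pattern such studies
report. These are structural defaults, not published values.

What the generator does **not** emulate: dependence between disorders
beyond an independent residual category lifting "any disorder" to its
configured prevalence; consent selectivity (consent is independent of
everything); item-level psychometrics (no factor structure, items are
exchangeable given the total); seasonal or enrolment-order structure; and
interviewer effects. Passing tests therefore demonstrate correctness of the
estimators under the stated sampling and missingness mechanisms — not that
real questionnaire data follow a binormal latent model.

# Design and power calculations

`expected_yield()` is closed-form: P(screen+) = πSe + (1−π)(1−Sp), expected
interviews n_h = n_screen · P(stratum) · consent · fraction_h, and expected
diseased interviewees by Bayes. When a protocol states planned whole-number
interview targets, those can be supplied directly (`n_interview_pos/neg`)
and take precedence — a protocol's printed percentages are typically rounded
from its planned counts, and the two can differ by a woman or two in the
expected case count (185.4 from planned 400+200 vs 183.9 from the rounded
fractions 0.54/0.06 at the default design).

`simulate_ci_width()` draws whole screened populations at the design
parameters, applies the design, marks index-test results at the assumed
Se/Sp, and reports mean stratified-bootstrap CI widths with Monte-Carlo
standard errors (defaults: 200 replicates × B = 500). `simulate_power()`
implements the conservative cases-only reading of a sensitivity comparison:
the number of index-test positives among n cases is drawn at the true
sensitivity and tested against the comparator value by the exact two-sided
binomial test; the rejection region is precomputed once per n. The
two-sample chi-square comparison is available as
`test_spec = "two_sample_independent"`.

The suite also compares the simulated Se CI width against a two-stratum
delta-method approximation (agreement within 0.05), and checks that widths
shrink when the screened population is quadrupled.

# Problem sizes used in the validation suite

Chosen to make every stochastic assertion a 3-Monte-Carlo-SE (or stated
band) check of its estimand: marginal calibration of the generator at
50 000 screened; design-unbiasedness over 200 replicate samples from a
fixed population of 6000 (consent 1, so that only design randomness is in
play); bootstrap-vs-binomial closed form at n = 200, B = 5000; ROC-GLM
recovery at 1000 + 1000 × 100 replicates; Wald size at 500 + 500 × 400
replicates; IPW bias reduction at 8000 screened × 200 replicates; PMM
properties over 100 random fixtures; power at 5000 simulation replicates.

# Known limitations

* The sandwich Wald test is liberal below ~500 cases; a stratified bootstrap
  of the ROC-GLM fit would be the remedy and is deliberately not the default
  (runtime).
* Percentile bootstrap intervals can undercover for extreme weighted
  proportions (few effective cases in a stratum).
* The IPW response model conditions on the post-imputation questionnaire
  total; imputation uncertainty is not propagated into the weights.
* `any disorder` is generated as a union of independent components; real
  comorbidity is positively dependent, so component-wise prevalences
  conditional on "any" are not emulated.
* The 1:k selection is independent Bernoulli, not systematic every-kth;
  both are "random selection", and Bernoulli keeps records exchangeable.
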