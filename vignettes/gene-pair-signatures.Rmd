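---
title: "Gene-pair prognostic signatures: model, estimators and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-pair prognostic signatures: model, estimators and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairsig)
```

## The model

A sample's feature vector is built from within-sample comparisons of gene
pairs: for an oriented pair (A|B) the indicator is 1 when gene A is
expressed above gene B in that sample, 0 otherwise (ties score 0). Because
only the within-sample ordering matters, the encoding is invariant to any
strictly increasing per-sample transformation of the expression values.
This is the property that lets a signature trained on RNA-seq score a
microarray cohort without normalization, and it is the property the test
suite pins down hardest (bit-identical risk scores under per-sample
affine, power and rank-quantile distortions).

The prognostic model is a Cox proportional-hazards model on a small set of
pair indicators. The risk score of sample *s* is

$$\mathrm{score}(s) \;=\; \sum_i \beta_i \, \mathbf{1}\{x_{A_i s} > x_{B_i s}\},$$

with the $\beta_i$ being multivariate Cox coefficients. Since each
indicator is 0 or 1, every score lies between the sum of the negative
coefficients and the sum of the positive ones — a bound asserted as a
property test.

## The construction funnel

1. **Variability screen** — keep genes with across-sample median absolute
   deviation above 0.5. The *raw* MAD (`median |x - median x|`, no 1.4826
   consistency constant) is the default: the threshold is quoted against
   an unstated estimator upstream, and the raw form is the conservative
   reading. Both the constant and the threshold are arguments of
   `mad_filter()`.
2. **Availability** — drop genes absent from any validation cohort
   (`intersect_available_genes()`), so the signature can be scored
   everywhere it will be evaluated.
3. **Pairing** — all unordered pairs, each once, oriented by the supplied
   gene-list order (`build_pair_matrix()`). The published signature's pair
   orientations are not lexicographic, so the original enumeration order
   is unrecoverable; list order is the reproducible stand-in.
4. **Prevalence filter** — keep pairs whose indicator prevalence lies in
   [0.20, 0.80] *inclusive*. "Less than 20% or more than 80% excluded"
   reads as strict exclusion outside the closed interval; the boundary
   cases (exactly 20%, exactly 80%) are kept and unit-tested.
5. **Univariate screen** — one single-covariate Cox model per pair, keep
   Wald p < 0.05, no multiplicity adjustment (deliberately: the screen is
   a funnel stage, not an inference). Non-converged fits count as p = 1
   rather than aborting.
6. **LASSO-Cox stability selection** — an L1-penalized Cox model over a
   log-spaced lambda path; the penalty is chosen by 10-fold
   cross-validated partial-likelihood deviance at its minimum, folds are
   re-randomized across repetitions (default 1000), and a pair enters the
   signature when selected in more than half the repetitions. "1000
   iterations" upstream is ambiguous between path iterations and CV
   repetitions; the repeated-CV/stability reading avoids the known fold
   sensitivity of a single `cv.glmnet` call and is exposed as
   `n_repetitions` / `stability_threshold`. Lambda-at-minimum (not 1-SE)
   is the default because the stability vote already provides the
   parsimony pressure.
7. **Refit** — unpenalized multivariate Cox on the selected pairs gives
   the signature coefficients (penalized coefficients are biased toward
   zero and are not what a risk formula should carry).

Every stage logs its count; a stage that empties its output aborts with a
stage-named error (CLI exit code 3).

## Survival machinery

`cox_fit()` maximizes the Breslow log partial likelihood by Newton
iterations with step-halving; the trace is exposed and tested to be
non-decreasing. Breslow tie handling is used everywhere — including the
glmnet-backed penalized path — so penalized and unpenalized fits share one
objective. Standard errors come from the observed information; the score
test at $\beta = 0$ is returned because, for a single binary covariate on
tie-free data, it coincides exactly with the log-rank statistic (asserted
to 1e-6). With tied event times the two differ by the hypergeometric
$(n-d)/(n-1)$ factor, which is why the identity tests generate tie-free
data. Fits that fail to converge or drift beyond |β| > 15 (numerical
separation) are flagged; a flagged fit is never silently used.

`km_estimate()` is the product-limit estimator; `logrank_test()` the
Mantel–Haenszel chi-square with hypergeometric variance.

## Time-dependent ROC and the cutoff

`time_dependent_roc()` implements the Kaplan–Meier cumulative/dynamic
estimator: at horizon *t* (365/730/1095 days for 1/2/3 years), cases are
subjects with an event by *t*, controls are subjects surviving past *t*,
and censored-before-*t* subjects contribute through KM weighting:

$$\mathrm{sens}(c) = \frac{\{1 - S(t \mid x > c)\}\,P(x > c)}{1 - S(t)},
\qquad
\mathrm{spec}(c) = \frac{S(t \mid x \le c)\,P(x \le c)}{S(t)}.$$

The nearest-neighbor smoothed variant used by some tools is deliberately
not replicated; on identical data AUCs may differ from other software in
the second decimal. On uncensored data the estimator collapses exactly to
the binary ROC of the event-by-horizon label (asserted to 1e-12 against an
independent rank-sum oracle). The AUC integrates trapezoids *in threshold
order*, which keeps the sweep exact even where KM weighting makes the
curve locally non-monotone; sensitivity/specificity values within 1e-9 of
0 or 1 are snapped to the exact endpoint (true values are at least 1/n
away) so floating-point dust cannot reorder tied corners.

`youden_cutoff()` maximizes J = sensitivity + specificity − 1 over the
attained score values; ties break toward the smallest threshold (the most
inclusive high-risk group). `stratify()` assigns `high` to scores
*strictly above* the cutoff: the Youden threshold is itself an attained
score, and the boundary patient belongs with the group whose survival
estimate generated the threshold. One training-derived cutoff is applied
to all cohorts by default (`train_transfer`); per-cohort re-optimization
is available (`per_cohort`) since the upstream description is ambiguous on
this point.

A note on an estimator asymmetry: reversing the score's sign maps AUC to
1 − AUC exactly only without censoring. At attained thresholds the
reversed sweep evaluates subgroups {x < c} where the original evaluated
{x ≤ c}; under KM weighting these differ by one subject. The tests assert
the identity exactly on uncensored data and within 0.02 under censoring.

## Association statistics

Chi-square tests of risk group against clinicopathologic categories use
the Pearson statistic without continuity correction (tables are generally
larger than 2×2, and the hand-formula examples are exact without it).
Rank-sum comparisons of the risk score across the standard binary splits
(stage I–II vs III–IV, T1–2 vs T3–4, N0–1 vs N2–3, M0 vs M1) use the exact
Wilcoxon distribution for small tie-free samples and the tie-corrected
normal approximation otherwise — the exact branch is what makes the
3-vs-3 permutation oracle (p = 2/20) hold. Correlations are Pearson
(t approximation) or Spearman (large-sample, tie-corrected). TMB is
mutations divided by 38 Mb of exome: the unit (mutations/Mb) is standard,
the denominator is not stated upstream, and 38 Mb is the conventional
whole-exome size; it is an argument of `tmb()`.

## The synthetic cohort: what it emulates, what it does not

`generate_cohort()` produces the data structure the analysis assumes:

* **Expression** — per-gene normal on the log2 scale, location ~ U[2,10],
  spread ~ U[0.3,1.5], plus a per-sample location shift
  (`noise_spread`, default 0.2) mimicking library-size variation while
  preserving within-sample order. A simple model, chosen so the MAD filter
  is meaningful; no distributional claim about real cohorts is intended.
* **Planted pairs** — the indicator is realized *by construction*: a
  latent Bernoulli(1/2) picks the sign of a strictly positive log2 offset
  (mean `pair_shift` = 1, a two-fold flip) separating gene A from gene B.
  Truth is therefore controlled, recomputable and exact, rather than
  emergent. Genes in planted pairs draw their spread from U[0.9,1.5] — above
  the MAD>0.5 cut — so that recovery experiments measure the Cox/LASSO
  machinery rather than random eliminations by the variability screen;
  this floor was fixed at design time, before any acceptance measurement.
* **Survival** — Weibull proportional hazards (shape 1.2, scale 1800 days:
  median ≈ 3.6 years at zero linear predictor, a plausible NSCLC figure),
  sampled by inverse transform with linear predictor Σβ·I. Censoring is
  independent exponential; its rate is solved by root finding so the
  expected censored fraction hits `censor_rate` (default 0.3). The real
  studies' censoring mechanism is unknowable; independence is the neutral
  choice.
* **Clinical covariates** — categories drawn from the published training
  cohort's proportions (unknowns excluded, renormalized); age ~ N(66, 9)
  rounded. Covariates are *independent of survival* by design, so tests
  can assert that only the risk score carries signal.
* **Mutations** — negative binomial (size 2) with stratum means 250/120
  for latent risk above/below the median linear predictor: reproduces the
  qualitative "high-risk has higher TMB" contrast without claiming a
  mechanism.
* **Platform shift** — `apply_monotone_distortion()` transforms each
  sample through a strictly increasing function (affine with positive
  scale; `(x − min + 1)^e`, shifted so the base stays positive on
  log-scale input; rank-to-normal-quantile mapping). Units in days
  throughout; other units convert at I/O.

A green test on this world establishes that the *pipeline machinery* is
correct and calibrated. It does not establish that real cohorts satisfy
proportional hazards, that real pair indicators are conditionally
independent, or that the published signature generalizes — the simulator
has no batch structure, no histology-expression coupling, no
tumor-purity confounding, and its null pairs are only as correlated as
full pairing makes them.

## Numerical conventions and edge cases

* Expression ties score 0 ("otherwise 0", read literally); ties also break
  the antisymmetry identity I(A|B) = 1 − I(B|A), so property tests use
  tie-free (continuous) data. Real expression matrices with many exact
  ties (e.g. zero-inflated counts) deserve jittering or filtering first.
* Genes with any missing value are dropped at load with a warning; the
  indicator of a missing comparison is undefined.
* Prevalence boundaries inclusive; screen boundary strict (p < alpha, so
  alpha = 0 empties the screen and aborts the pipeline).
* Score exactly at the cutoff → low-risk group (documented above).
* Newton convergence: relative log-likelihood change < 1e-9, 25 iteration
  cap, step halving to 1e-10; |β| > 15 flags suspected separation.
* `export_cohort()` serializes 12 significant digits; round trips agree to
  that precision, and `truth.json` carries betas exactly.
* Seeds: every stochastic operation takes an explicit integer seed;
  identical config + seed reproduces cohorts and selections byte for byte.

## Scaling choices in the shipped tests

The acceptance suite runs on one desk CPU: null calibration pools ~100
null pairs over 500 simulated cohorts (n = 120 each); the recovery
experiment uses 20 seeds at n = 500 with the LASSO repetition count
lowered from the 1000-repetition default to 10 (the >50% stability rule
is unchanged — only the frequency resolution drops). The pre-registered
calibration band for the screen's pass rate, [0.03, 0.07], is wider than
the binomial error (~±0.004) because the Wald test's finite-sample
behavior at n = 120, not Monte-Carlo noise, dominates the deviation from
the nominal 5%.

Sign agreement of refit coefficients is asserted in the literal
"10 planted among 100 independent null pairs" world. Under full pairing,
cross-pairs sharing a planted gene are strongly collinear with the true
pair, and a multivariate refit can leave a recovered pair with a
near-zero coefficient of arbitrary sign — a property of the design
matrix, not of the selection machinery; the end-to-end route is therefore
held to the recovery bound (≥ 8/10) and the constructed world to the sign
bound (10/10).

## Known limitations

* Breslow tie handling only (no Efron), no time-varying covariates, no
  competing risks, no stratified Cox.
* The time-dependent ROC estimator is the unsmoothed KM cumulative/dynamic
  form; published AUCs from smoothed estimators can differ in the second
  decimal.
* The KM-weighted sensitivity/specificity can leave [0,1] in small
  samples; values are clamped.
* Third-party immuno-genomic scores (immune/stromal scores, tumor purity,
  deconvolution fractions, dysfunction/exclusion scores) are consumed only
  as user-supplied per-sample columns through the generic association and
  correlation tests; the package never computes them.
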