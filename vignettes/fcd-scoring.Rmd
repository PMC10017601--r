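---
title: "Scoring facial canal dehiscence on ultra-high-resolution CT: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring facial canal dehiscence on ultra-high-resolution CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcdscore)
```

## The clinical problem and the score

Facial canal dehiscence (FCD) is the absence of the thin bony covering
over the facial nerve, most often in the tympanic segment, where the
canal hangs directly above the oval window. A dehiscent canal leaves the
nerve covered only by membrane, and drilling or probing near it during
middle-ear surgery risks iatrogenic facial paralysis. Conventional
multislice CT resolves the covering poorly; ultra-high-resolution CT
(0.1 mm isotropic) makes a graded reading possible.

The score implemented here grades the **lateral** and **inferior** walls
of the tympanic facial canal separately on an ordinal 0–3 rubric:

| score | appearance |
|---|---|
| 0 | no evident bony covering |
| 1 | discontinuous bony covering, linear deficiency |
| 2 | discontinuous bony covering, dotted deficiency |
| 3 | continuous bony covering |

The composite FCD score is the sum of the two wall scores (0–6). An ear
is classified *dehiscent on imaging* when its composite score falls
**strictly below** a cutoff; the validated operating point is the strict
cutoff 4, under which exactly 10 of the 16 possible wall-score pairs are
read as dehiscent. The strict (`<`) reading rather than `<=` is forced
by that count: a `<=` rule at any cutoff cannot produce 10 pairs.

Two readers score each ear independently and blinded to surgery;
discrepant wall scores are re-read jointly to a consensus
(`consensus_merge()` requires an adjudicated value exactly when the
independent reads disagree — how a panel resolves a persistent
disagreement is left to the data supplier, since no rule is prescribed
by the design). The ear, not the patient, is the unit of analysis, and
`ear_id` uniqueness is enforced.

## Agreement: kappa, its interval, and banding

Inter-observer agreement per wall is unweighted Cohen's kappa on the
4×4 cross-tab of the two independent reads. The standard error is the
large-sample formula of Fleiss, Cohen & Everitt (1969) — the one SPSS
prints — and the 95% interval is `kappa ± 1.96·se` clipped to [−1, 1].
The source study names no SE formula, only its intervals; the
Fleiss–Cohen–Everitt choice reproduces those intervals to within 0.001,
so the packaged acceptance check allows a ±0.02 margin rather than
demanding exactness. Weighted kappa and multi-rater generalizations are
deliberately out of scope.

Strength-of-agreement labels use the conventional closed bands (slight
0.00–0.20, fair 0.21–0.40, moderate 0.41–0.60, good 0.61–0.80,
excellent 0.81–1.00). Because the bands are printed to two decimals,
kappa is rounded **half-up** to two decimals before banding, so the
band edges partition without gaps (0.205 is fair, 0.204 is slight);
negative kappa is reported as `below_slight`.

## Group comparisons: the exact test and the selection rule

Per-wall score distributions are compared between surgical groups with
the Pearson chi-square test, switching to the Freeman–Halton (Fisher)
exact test **when any observed cell count is below 5**. The textbook
rule inspects *expected* counts; the observed-cell rule is implemented
because it is the stated analysis rule, and `select_and_test()` emits a
message whenever the two rules would disagree, so the deviation is
visible case by case.

The exact test enumerates every non-negative integer table with the
observed margins (recursive cell filling; the last cell of each row and
the whole last row are forced, and running-margin bounds prune the
recursion so only valid tables are visited). Table probabilities come
from the multivariate hypergeometric formula evaluated through
`lgamma`, accumulated in log space, and the two-sided p-value is the
total probability of tables no more probable than the observed one —
the probability-mass criterion. A relative tolerance of 1e−7 is applied
when comparing table probabilities so borderline ties cannot flip
membership across platforms. The enumeration count is capped
(default 1e7) with an explicit capacity error; the study's 4×2 tables
enumerate a few hundred tables in milliseconds. The study's printed
"Fisher's exact value" statistics are not reproduced: no definition for
them is derivable (they equal neither the Pearson statistic nor any
documented SPSS quantity), so only p-values are matched.

## Diagnostics: ROC, AUC, cutoff, predictive values

With surgery as the gold standard, every strict cutoff k = 0..7 yields
a confusion table (k = 7 classifies everything dehiscent, giving the
ROC its (1, 1) anchor; the printed table stops at 6). Sensitivity,
specificity and Youden's index (J = sens + spec − 1) are tabulated per
cutoff; the optimal cutoff maximizes J, with ties broken toward higher
specificity and then the lower cutoff. AUC is computed two ways and
asserted equal to 1e−10: trapezoidal integration of the ROC staircase,
and the tie-corrected rank form P(S⁺ < S⁻) + ½·P(S⁺ = S⁻) over all
positive×negative ear pairs (lower score indicates dehiscence). On the
study data the rank form is the exact fraction 296/319 = 0.928.

**Orientation.** The canonical orientation throughout the API is
*dehiscent-positive*: dehiscence is the condition sought. The study's
printed sensitivity/specificity and PPV/NPV columns are, however,
internally consistent only when *intact* is treated as the positive
class (0.82 = 9/11 and 0.93 = 27/29). Rather than guess the intended
labeling, every metric is reported under both orientations
(`sensitivity_intact_pos`, the `swapped` block of
`diagnostic_summary()`), and the packaged consistency checks pin only
orientation-invariant quantities (Youden, AUC, accuracy, raw confusion
cells). Zero-denominator metrics are returned as `NA` and listed in an
`undefined` field instead of propagating NaN.

## Reconstructing the per-ear scores from the printed rates

The per-ear composite scores behind the ROC are not published, but the
per-cutoff rate table determines them. One printed rate column is the
cumulative fraction of dehiscent-group ears below each cutoff; the
complement of the other is the cumulative fraction of intact ears below
it. Which column plays which role is resolved by **feasibility**, not
by the printed headers: for each candidate orientation the implied
cumulative counts `rate × n` are rounded to integers, and the
orientation is accepted only if every implied count reproduces its
printed rate to within 0.005 (half a unit in the last printed decimal),
is non-negative and non-decreasing in the cutoff. Exactly one
orientation survives on the study data; zero or two feasible
orientations raise an error listing both residuals. The tolerance is
deliberately a *rate-scale* half-ULP: rates printed to 2 decimals at
n = 29 can sit up to ~0.15 ears from the integer (0.72×29 = 20.88 for
the true 21), so a fixed count-scale window would reject the genuine
solution.

The reconstruction is validated three independent ways: the summed
marginal equals the separately printed whole-cohort distribution
(2, 7, 13, 7, 6, 4, 1); the implied confusion at cutoff 4 equals the
printed cells (27, 2, 2, 9); and regenerating the rate table from the
reconstructed distributions reproduces every printed rate to within
0.005. `verify_consistency()` runs all of these plus the kappa and
percentage checks and reports pass/fail per item.

`paper_cohort()` goes one step further and materializes a 40-ear
per-ear dataset that simultaneously realizes the two observer
cross-tabs, the per-group per-wall consensus margins, and the
reconstructed composite distributions. The joint pairing of lateral
with inferior scores and the placement of observer disagreements on
individual ears are **synthetic completions** — only the margins are
published — so this cohort supports end-to-end pipeline tests of every
marginal statistic, and nothing else.

## The synthetic-cohort generator

`cohort_model()` states the world the analysis assumes, with defaults
equal to the study's empirical conditions: 40 ears, prevalence 29/40,
truth-conditional wall-score vectors equal to the published per-group
proportions, observer adjacency-error rate `epsilon_obs = 0.15`,
consensus error `epsilon_consensus = 0.05`, and `probe_error = 0`
(surgery treated as ground truth; a positive value models the discussed
false-positive mechanisms such as dehiscence outside the probed
portion). The consensus error default is smaller than the observer
error because the consensus is a joint deliberate re-read; no empirical
value exists for either, and 0.15 reflects the observed near-diagonal
disagreement mass of the agreement tables.

Modeling choices, and what a green test does *not* establish:

* **Conditional independence of the walls given truth.** Only marginal
  per-wall distributions are published, so no dependence structure is
  invented. Real wall scores are plausibly correlated (shared disease,
  shared image quality); the generator cannot test robustness to that.
* **Adjacency-weighted confusion.** Misreads move to a neighboring
  ordinal category (split evenly; at the edge scores 0 and 3 the whole
  error mass goes to the single neighbor), chosen over uniform
  confusion because the rubric is ordinal and observed disagreements
  concentrate near the diagonal. Gross misreads (0 read as 3) never
  occur in the generator.
* **Both observers perturb the same latent wall score**, so their
  errors are conditionally independent given the *latent score*, not
  given truth alone. The closed-form oracle `theoretical_kappa()`
  conditions on the latent score accordingly — the outer product is
  taken per latent category, then mixed — because that is the only
  joint law consistent with the generator; conditioning on truth alone
  would understate agreement.
* The generator emulates scores, not images: lesion covariates,
  experience effects and image noise are outside its scope.

`theoretical_auc()` convolves the consensus-confused wall vectors into
truth-conditional total-score distributions and evaluates the rank AUC
exactly; `theoretical_metrics()` gives closed-form sensitivity and
specificity per cutoff. Parameter-recovery tests check the empirical
kappa and AUC at n = 20 000 against these oracles within three
Monte-Carlo standard errors, and mean sensitivity/specificity at the
model's own optimal cutoff across 20 seeds of n = 5 000 within 0.03.
These sizes keep the full suite well inside its runtime budget.

## Numerical conventions

* Percentages print to 1 decimal, statistics to 3 decimals, matching
  the precision of the source tables; all rounding of *reported* values
  is half-up (`round_half_up`), not banker's rounding.
* Exact-test probabilities live in log space end to end; the summed
  probability over all enumerated tables is checked to 1e−9 in tests.
* AUC comparisons internal to the package use 1e−10; published-value
  checks use the printed precision (±0.001 on 0.928).
* Degenerate inputs fail loudly: single-category agreement tables
  (p_expected = 1), zero margins in the chi-square, empty groups in the
  AUC, and missing adjudications all raise typed errors rather than
  returning NaN.

## Known limitations

The study cohort is small (40 ears, 11 intact), so the reconstructed
distributions — while exactly determined — carry the sampling noise of
the original data; confidence intervals for AUC (DeLong) and
decision-curve analysis are out of scope. The CLI accepts JSON
configuration only. Only two observers are supported, matching the
design; multi-rater agreement is a non-goal.
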