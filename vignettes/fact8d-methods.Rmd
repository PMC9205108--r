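---
title: "Valuing the FACT-8D: models, simulation design, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Valuing the FACT-8D: models, simulation design, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fact8d)
```

## The instrument and the scoring model

The FACT-8D describes health on eight dimensions — pain, fatigue, nausea,
problems sleeping, problems doing work, problems with support from family
and friends, sadness, and worry that health will get worse — each at five
severity levels (1 = "Not at all", the best, to 5 = "Very much", the worst).
The levels are filled in from nine FACT-G items. Five items are negatively
phrased and map directly (`level = score + 1`): GP4 (pain), GP1 (fatigue),
GP2 (nausea), GE1 (sadness), GE6 (worry). Two are positively phrased and are
reverse scored (`level = 5 - score`): GF5 ("I am sleeping well") and GF1
("I am able to work"). The support dimension uses the better of GS2 (family)
and GS3 (friends): `level = 5 - max(GS2, GS3)`.

A value set is a table of utility decrements $w_{dl} \ge 0$, one per
dimension $d$ and level $l$, with $w_{d1} = 0$. The utility of a state is
additive:

$$U = 1 - \sum_{d=1}^{8} w_{d\,l(d)},$$

so full health scores 1, and the worst describable ("PITS") state scores
$1 - \sum_d \max_l w_{dl}$, which may be negative (worse than dead, utility
0). With the packaged Canadian set the PITS utility is
`r round(pits(canadian_value_set()), 3)`; the largest single decrements are
for the worst levels of pain (0.384), nausea (0.298) and work (0.231).

Internally every level is coded 1–5. The 0–4 item codes of the FACT-G are
translated at the boundary by `map_factg_to_state()`; keeping one canonical
convention avoids off-by-one drift between the questionnaire and the value
set. Missing items are refused under the default strict policy — no
imputation is offered, including for the GS2/GS3 pair, where the package
refuses rather than guessing what "the better of the two items" means with
one item absent. Utilities are held at full precision; the 3-decimal
(decrements) and 2-decimal (utilities) conventions are applied only when
writing files.

## The valuation model

Value sets of this kind are estimated from discrete choice experiments:
panel respondents repeatedly choose between two health profiles, each a
FACT-8D state paired with a survival duration $t \in \{1, 2, 5, 10\}$ years.
Choices are modelled by a conditional logit whose systematic utility is
parameterised to fit the QALY framework:

$$V_{isj} = \alpha\, t_{isj} + \sum_{d,l} \beta_{dl}\, x_{isjdl}\, t_{isj},$$

where $x_{isjdl}$ indicates level $l$ of dimension $d$ in alternative $j$ of
choice set $s$ for respondent $i$, and $\alpha > 0$ is the utility of one
life year in full health. Every dimension dummy is multiplied by duration,
which enforces the two standard QALY restrictions: a state of zero duration
has zero utility (equivalent to dead), and the proportion of remaining life
a respondent will trade for a health improvement does not depend on the
amount of remaining life (constant proportional trade-off).

Choice probabilities are logistic in the utility difference,
$P(A) = \operatorname{logit}^{-1}(V_A - V_B)$, which presupposes i.i.d.
type-I extreme value (Gumbel) errors. We simulate with Gumbel errors for
exactly that reason: the estimator is a conditional logit, and a generator
with matching error law makes the estimator consistent for the generator's
own parameters, which is what the recovery tests rely on.

The decrements are marginal rates of substitution with duration:
$w_{dl} = -\beta_{dl} / \alpha$ — the share of remaining life a respondent
would give up to escape level $l$ of dimension $d$. `derive_value_set()`
refuses a non-positive $\alpha$, for which the anchoring is undefined.

### Estimation

`fit_clogit()` maximises the paired-logit (pseudo-)likelihood by damped
Newton–Raphson with the analytic gradient and Hessian, starting from zero
coefficients and stopping when the gradient max-norm falls below `1e-6`
(`gtol`). Survey weights multiply each respondent's log-likelihood
contribution (pseudo-maximum-likelihood, as in standard survey-weighted
conditional logit practice). The reported covariance is always the
clustered sandwich with respondents as clusters, which accounts both for
the weights and for correlation among one respondent's sixteen answers;
with one choice set per respondent it reduces to the ordinary
heteroskedasticity-robust estimator (verified numerically in the tests).
The implementation is cross-checked against `survival::clogit` (Breslow
ties, clustered robust variance), agreeing to ~1e-9 on coefficients,
robust SEs, and the log-likelihood.

`AIC = 2k - 2\,LL`. For `BIC = k \log N - 2\,LL` the sample-size convention
is not universal in the DCE literature; the package uses the number of
choice-set observations by default and exposes `bic_n` to override it.

### Monotonicity by level collapsing

An unconstrained fit can violate the logical requirement that worse levels
never carry smaller decrements, in two ways: a positive coefficient (a
worse-than-reference level apparently *raising* utility) or a reversed
adjacent pair. `detect_violations()` flags both; `constrain()` iterates
fit → detect → merge → refit until monotone:

* a positive-coefficient group adjacent to the reference is merged **into**
  the reference (coefficient fixed at 0);
* a reversed adjacent pair is merged into one shared group.

All violations found in a round are applied together; within a dimension
the mildest pair merges first, each group takes part in at most one merge
per round, and reference adjacency is tracked within the round (so two
successive positive levels collapse to the reference in a single round).
Chains that survive a round are caught after the refit. Because merging
only restricts the parameter space, the constrained log-likelihood can
never exceed the unconstrained one — an invariant asserted in the tests.

Small *negative* coefficients are deliberately **not** merged to the
reference automatically: only sign and ordering violations trigger merges.
Narratives about "negligible" coefficients are not operationalisable
without an arbitrary threshold, and published value sets in this family
keep such levels distinct. Users who want a specific published collapsing
pattern can pass it via `forced_merges` (see
`published_constrained_spec()`, which encodes the Canadian pattern: 23 free
parameters against 33 unconstrained).

The packaged Canadian fixture stores the published decrement table
verbatim. One documented discrepancy: the published pain decrements
(0.077/0.187/0.384) are not $-\beta/\alpha$ of the published pain
coefficients (which give 0.057/0.197/0.407); all other rows agree at three
decimals. The fixture follows the published value set; re-derivation from
coefficients lives in `derive_value_set()` and the two routes are compared
only on rows where they agree.

## What the synthetic cohort emulates

No respondent-level valuation data are publicly deposited, so the package
carries a generator whose defaults mirror the Canadian study conditions:

* **Cohort** — 1,582 respondents. Sex, age group and province/territory are
  filled by exact quota (largest-remainder rounding of the census margins);
  language, education and self-rated health are drawn independently at the
  *sample* composition observed in the study (78% English versus a 58%
  target, college-or-higher over-represented, poorer self-rated health), so
  the raking stage has the same work to do as in the study. Margins printed
  at two decimals are renormalised to sum to one.
* **Design** — paired profiles over the eight dimensions plus duration, 16
  choice sets per respondent, exactly five attributes differing per set
  (duration always among them by default), durations from {1, 2, 5, 10}.
  Levels are chosen by randomised level-balance search (best of 20
  candidate blocks by squared deviation of level frequencies from uniform).
  The original experimental design matrix is unpublished; the default of
  60 blocks of 16 sets follows the blocked designs used across this family
  of valuation studies, and is also a structural necessity — a single
  shared 16-set block supplies only 16 distinct difference vectors and
  leaves a 33-parameter model unidentified. `read_design_csv()` accepts an
  external design for users who have one.
* **Choices** — Bernoulli draws from the closed-form logit probability
  under homogeneous preferences (default truth: the published constrained
  coefficients). Preference heterogeneity and attribute non-attendance are
  not simulated by default: the conditional logit targets the mean
  response, and the headline pipeline matches it. A completion model drops
  a tail of sets for 81/1,582 of respondents, mirroring the study's
  inclusion rule (at least one completed set).

What the generator does **not** emulate: real panels exhibit preference
heterogeneity, within-respondent error correlation beyond shared
preferences, position and ordering effects, and non-random dropout. Passing
recovery tests therefore demonstrates the correctness of the estimation
machinery under the model's own assumptions — not that the model is
adequate for any particular real panel.

Every stage takes an explicit integer seed; the pipeline derives stage
seeds from its master seed by fixed offsets (design `seed`, cohort
`seed+1`, choices `seed+2`), so one integer reproduces a run end to end and
stages can also be reproduced in isolation.

## Survey weights

`assess_representativeness()` compares sample margins with population
targets: a goodness-of-fit $\chi^2$ (expected counts from the targets) and
a flag when any level deviates by at least 2 percentage points — the
conventional rule for deciding which variables to rake; the flagged set
(language, education, self-rated health under the default skew) is the
raking default, and callers may override it. `rake()` is classical
iterative proportional fitting on marginal targets: cycle through the
variables multiplying weights by target/current ratios until every raked
margin is within `tol = 1e-6`. One-variable raking collapses to exact
post-stratification; re-raking raked weights is a fixed point; margins of
non-raked variables may drift and are reported by `weighted_margins()`
rather than silently adjusted. No trimming is applied by default (an
optional `cap` exists). Joint (cross-tabulated) calibration targets are out
of scope. The $\chi^2$ values printed in the source study's demographic
table are not reproduction targets: whether they were computed against
rounded targets, and whether raking was marginal or joint, is not stated
there.

## Numerical and degenerate-input choices

* Optimisation starts at zero; convergence is judged by the gradient
  max-norm alone (`1e-6`). Step halving guards the rare non-concave step.
* A singular Hessian (separation, an unobserved level group, a
  rank-deficient design) is a hard error naming the likely cause, not a
  silent pseudo-inverse.
* `lr_test()` refuses fits whose data fingerprints differ, floors the
  statistic at zero, and takes the difference in free parameter counts as
  its degrees of freedom.
* Scoring refuses out-of-range item scores and (strictly) missing items;
  file-level scoring collects row errors and continues.
* The largest-remainder quota rounding errs by at most one respondent per
  level; sampling requires `n` at least the number of levels of each quota
  variable.

## Problem sizes used in the tests

Module tests run on 300 respondents and 8 design blocks, enough for every
structural and closed-form check. The end-to-end statistical checks run at
the study scale (1,582 × 16): the unconstrained fit recovers every
coefficient within 3 estimated SEs of truth. A stricter published-scale
check — every derived decrement within 0.02 of truth — is retained in the
acceptance tests at face value, but sits at roughly one standard error per
decrement at this sample size (a level-coefficient SE of ~0.007 maps to a
decrement SE of ~0.018), so with ~30 estimated cells the maximum error
typically lands at 0.025–0.04 and the check fails for purely statistical
reasons; achieving it would need roughly four times the respondents. The
3-SE criterion is the meaningful correctness guarantee.

## Limitations

* The value set machinery is specific to the 8-dimension, 5-level
  classification; other FACIT instruments and the FACT-G profile scores
  are out of scope.
* No mixed logit or latent-class estimation; the conditional logit's
  homogeneous-preference assumption is a modelling choice, not a claim
  about panels.
* Anchoring relies on the duration attribute (MRS); designs that include
  dead as an explicit alternative need different machinery.
* Interactions between dimensions are not modelled.
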