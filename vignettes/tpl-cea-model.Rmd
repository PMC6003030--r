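---
title: "The threatened-preterm-labor decision model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The threatened-preterm-labor decision model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tplcea)
```

## The decision problem

Women presenting with threatened preterm labor (TPL) — regular contractions
with intact membranes at 24–34 weeks of gestation in a singleton pregnancy —
mostly do *not* deliver within the next seven days. A diagnostic test that
identifies the minority who will deliver imminently lets clinicians
hospitalize and treat them (tocolysis, antenatal corticosteroids, in-utero
transfer) while sparing the rest an unnecessary admission. `tplcea` models
seven candidate triage strategies built on cervical length (CL) measurement,
qualitative and quantitative fetal fibronectin (fFN), cervical
interleukin-6, and a CL/RANTES/IL-10 combination, and compares them on two
payoffs per mother–child pair: expected direct medical cost (2012 euros,
French health-care system perspective) and the expected probability of a
serious neonatal adverse event (perinatal death or severe neonatal
morbidity, scored 1/0 at hospital discharge). Costs and effects are not
discounted; the horizon is under a year.

## Model structure

Each gestational-age (GA) stratum (24–27, 28–31, 32–34 weeks, entering at
weeks 25, 29 and 33 respectively) runs the same two-stage structure.

**Decision tree.** With incidence $p = 0.097$ of delivery within 7 days, a
test with sensitivity $Se$ and specificity $Sp$ splits the cohort into the
four contingency cells $p\,Se$ (true positive), $p(1-Se)$ (false negative),
$(1-p)(1-Sp)$ (false positive) and $(1-p)\,Sp$ (true negative). Positive
women are admitted (prenatal TPL admission cost) and treated; those who
deliver within 7 days deliver at the entry week with treatment-scaled
neonatal outcome probabilities. False negatives deliver at the entry week
untreated. All non-deliverers enter the weekly follow-up model, carrying a
treated flag if they tested positive.

**Weekly Markov follow-up.** States are HOME and REHOSP (transient) and
DELIVERED_PRETERM / DELIVERED_TERM (absorbing); the cycle is one gestational
week up to the 37-week horizon, at which all remaining mass delivers at
term. From HOME a woman stays with the published weekly home-follow-up
probability (0.94 / 0.938 / 0.916 by stratum), is re-admitted with a
constant weekly hazard $q$, and otherwise delivers preterm. The published
"probability of subsequent hospitalization" (0.13 / 0.17 / 0.27) is read as
the *cumulative* probability of at least one re-admission before delivery or
term — the two published rows cannot both be weekly row entries — and $q$ is
solved by root bisection so the first-admission recursion integrates to that
target. From REHOSP a woman delivers with probability
`p_deliver_given_rehosp` and otherwise returns home. Deliveries in week $w$
use the outcome probabilities and prices of the stratum containing $w$
(weeks 35–36 reuse the 32–34 values); term deliveries carry zero adverse
probability. Costs accrue with no half-cycle correction: the weekly
home-follow-up fee for each cycle begun at home, a prenatal TPL admission
fee per entry into REHOSP, the delivery admission plus the neonatal episode
(death / with-morbidity / without-morbidity mix) at preterm delivery, and a
configurable term-delivery cost at the horizon.

**Aggregation and ranking.** Stratum payoffs are combined into the 24–34
result by the GA-mix weights ("proportion of mothers" per stratum).
Strategies are then sorted by cost; simple dominance removes strategies that
cost no less and prevent no more events than another; extended dominance
iteratively removes frontier points whose incremental ratio exceeds the next
one's. ICERs are expressed in euros per additional serious adverse event and
every non-cheapest strategy also reports its ICER against the cheapest one,
the convention of the published tables.

## Free parameters and calibration

Four quantities the analysis needs are not published anywhere in the source
tables:

* the GA-mix weights (three values on the simplex);
* the treatment effect, parameterised as relative risks
  `rr_death_treated` and `rr_morbidity_treated` in (0, 1] applied to
  deliveries on treated pathways (documented starting values 0.7 / 0.7);
* the fate of re-hospitalized women, parameterised as
  `p_deliver_given_rehosp_treated` / `..._untreated` (starting values 0.5).
  Splitting this knob by pathway is deliberate: repeat tocolysis at
  re-admission is the only channel consistent with the tree structure by
  which treatment can alter delivery *timing* rather than only delivery
  outcomes.

`calibrate_parameters()` fits all six degrees of freedom by minimising the
sum of squared relative errors across the fourteen published 24–34 payoffs
(seven strategies × cost and adverse probability), with seeded multi-start
Nelder–Mead on unconstrained transforms (softmax for the weights, logit for
the probabilities). The optimum is well identified — all starts converge to
the same point — and deterministic given the seed.

### What calibration can and cannot reproduce

In this tree-plus-Markov family every payoff is strategy-independent, so a
strategy's expected cost is exactly affine in $(Se, 1-Sp)$:
$c + x\,Se + y\,(1-Sp)$. That has two consequences worth stating plainly.
First, the published cost *ordering* of the seven strategies is not
representable: the pairwise order constraints on $(x, y)$ are mutually
infeasible for every choice of the free parameters, so the calibrated model
reproduces the frontier economics only approximately and its dominated
strategies appear in a different cost order. Second, the magnitude of the
published cost gap between the combined CL/fFN strategy and the others
(≈ 1,100–1,500 €) exceeds what any feasible sensitivity slope can generate
(the largest treatment-driven neonatal cost swing, full morbidity
elimination at 24–27 weeks, yields |x| ≈ 800 €). The calibrated model
therefore matches the published adverse-event level of the combined
strategy closely (within ~4%) but sits ≈ 30% above its published cost, and
these residuals are reported, not hidden: `calibrate_parameters()` warns
when the 5% residual ceiling is exceeded and `tidy()` on the result lists
every relative error. The same structural gap propagates to the
probabilistic analysis, where the model's southwest-quadrant proportion for
S7 versus S6 at 24–27 weeks is ≈ 65% rather than the published ≈ 90%: the
model's stratum-1 cost margin between the two strategies is small relative
to the sampled cost dispersion.

## Probabilistic sensitivity analysis

Every parameter carrying a published distribution family is sampled
independently per iteration; parameters published without a distribution
(incidence, the weekly transition inputs, the weekly home-follow-up fee)
stay fixed. The published range is read as a central 95% interval, so
$\sigma = (\text{high} - \text{low})/3.92$, and each family is fitted by
method of moments with the mean pinned at the point estimate — beta from
$(\mu, \sigma)$, gamma with shape $\mu^2/\sigma^2$ and scale
$\sigma^2/\mu$, log-normal matching the mean and SD of the positive
variate. The fits preserve the base-case mean exactly (closed form, tested).
Because the source is silent on how ranges parameterise distributions, two
alternative readings are selectable (`range_rule = "se"` or `"uniform"`).
Draws are classified on the cost-effectiveness plane of each pairwise
comparison; with adverse events as the effect axis, the southwest quadrant
($\Delta E < 0$, $\Delta C < 0$) is strict dominance of the referent.
Boundary draws ($\Delta = 0$, measure-zero under the continuous fits) are
deterministically counted with the negative side and reported. The default
is 5,000 iterations with a fixed recorded seed; results are bit-identical
for a given `(params, n_iter, seed)`.

## The microsimulation generator and what it shows

`simulate_trajectories()` realises the exact probabilistic structure the
cohort model assumes at the individual level: Bernoulli true status, test
result conditioned on it, weekly Markov draws, gestational-age-dependent
outcome draws, and the same price set. It is both the package's
synthetic-data generator and its brute-force oracle: for every strategy ×
stratum cell the cohort expectations must sit within three Monte-Carlo
standard errors of a 200,000-woman simulated cohort (tested). A single
seeded RNG stream with a fixed stage-by-stage draw order makes cohorts
reproducible; reproducibility is defined for sequential execution. The
generator emulates the model, not a clinical registry: it carries no
maternal covariates, no between-woman heterogeneity in test accuracy, and
no correlation between costs and outcomes beyond what the model structure
induces — so agreement between the two engines validates the expectation
arithmetic, not the model's external validity.

## Numerical and design choices

* **Term-delivery cost.** The published cost table prices no delivery at
  term. The fixture prices it at zero (configurable `term_delivery`
  parameter per stratum): the published absolute totals are only consistent
  with term deliveries outside the costing perimeter, and because all
  strategies share term flows the choice cancels out of every incremental
  comparison.
* **Delivery admission.** The cost table carries near-duplicate rows
  "preterm labor" and "preterm labor hospitalization"; deliveries are priced
  with the latter by default (`delivery_admission_cost`, switchable).
* **Event pricing by GA at occurrence.** Later deliveries and re-admissions
  are priced (and their outcomes drawn) at the stratum of the week in which
  they happen, not the stratum of presentation; a baby delivered at 36 weeks
  costs and risks what 32–34-week babies do.
* **Entry weeks** default to the rounded stratum midpoints 25, 29, 33; the
  presentation week within a stratum is not published.
* **Death and severe morbidity** are treated as mutually exclusive and
  additive into one composite adverse probability, and the published pooled
  24–34 outcome rows are carried in the fixture but not used by the model
  (the per-stratum rows and the GA weights determine the aggregate).
* **Root solving** for the weekly re-admission hazard uses bisection to
  1e-10 on [0, 1 − p_home]; infeasible combinations (home-follow-up too
  high for the cumulative target) raise a named error rather than clipping.
* **Scenario analyses** (incidence 5% / 15%; all sensitivities and
  specificities jointly at their range bounds) hold the calibrated free
  parameters fixed; nothing suggests re-calibration per scenario, and
  freezing keeps scenario contrasts attributable to the overridden inputs.
* **Problem sizes.** The shipped tests run the full 5,000-iteration PSA,
  the 20-start calibration and 21 oracle cells of 200,000 women each —
  the same sizes the analyses use.

## Known limitations

The published S2 ICER (425,034 €) is not reproducible from the published
table's own rounded cells — the printed cost/effect pairs give 425,185 € —
so the package computes from unrounded model payoffs and documents the
gap. The calibration-residual and quadrant-proportion gaps described above
are structural properties of the declared model family, not tuning
failures; closing them would require payoffs that depend on the test
identity beyond sensitivity/specificity (for example, strategy-specific
management costs), which the source does not provide. Multiple gestations,
ruptured membranes, other high-risk maternal conditions and post-discharge
child outcomes are outside the model, as they were outside the source
analysis.
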